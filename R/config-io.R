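#' Save an experiment configuration to YAML or JSON
#'
#' Serialises a [run_config()] to a plain-text file; the format follows the
#' file extension (`.yaml`/`.yml` or `.json`). All physical quantities keep
#' their unit-suffixed key names (`pitch_um`, `group_duration_min`, ...).
#' The stuck-pixel table is not serialised (it is derived from the seed);
#' the autofluorescence matrix is stored per structure and channel.
#'
#' @param config A `cryoclear_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "cryoclear_config"))
  acq <- config$acquisition
  lst <- list(
    scale = config$scale,
    pitch_um = config$pitch_um,
    n_per_group = as.list(config$n_per_group),
    group_duration_min = as.list(config$group_duration_min),
    threshold_q = config$threshold_q,
    threshold_s = config$threshold_s,
    min_voxels = config$min_voxels,
    site_jitter_sd_mm = config$site_jitter_sd_mm,
    diffusivity_cv = config$diffusivity_cv,
    csf_flow_um_s = config$csf_flow_um_s,
    seed = config$seed,
    tracers = lapply(config$tracers, function(t) {
      list(name = t$name,
           molecular_weight_kda = t$molecular_weight_kda,
           concentration_mg_ml = t$concentration_mg_ml,
           diffusivity_um2_s = t$diffusivity_um2_s,
           csf_dispersion_um2_s = t$csf_dispersion_um2_s,
           csf_transport_rate_s = t$csf_transport_rate_s,
           channel = t$channel)
    }),
    infusion = list(
      total_volume_ul = config$infusion$total_volume_ul,
      rate_ul_min = config$infusion$rate_ul_min,
      duration_min = config$infusion$duration_min,
      site_structure = config$infusion$site_structure,
      site_offset_mm = config$infusion$site_offset_mm
    ),
    acquisition = list(
      exposure_ms = as.list(acq$exposure_ms),
      gain = acq$gain,
      noise_sd = acq$noise_sd,
      n_stuck = acq$n_stuck,
      stuck_value = acq$stuck_value,
      render_upsample = acq$render_upsample,
      autofluorescence = list(
        structure = rownames(acq$autofluorescence),
        channel = colnames(acq$autofluorescence),
        values = apply(acq$autofluorescence, 1, as.list, simplify = FALSE)
      )
    )
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("unsupported config format: use .yaml, .yml or .json")
  }
  invisible(path)
}

#' Load an experiment configuration from YAML or JSON
#'
#' Inverse of [save_run_config()]; rebuilds a full `cryoclear_config`
#' through the constructor functions, so invariants are re-validated on load.
#'
#' @param path Config path (`.yaml`, `.yml` or `.json`).
#' @param out_dir Optional output directory attached to the loaded config.
#' @return A `cryoclear_config`.
#' @export
load_run_config <- function(path, out_dir = NULL) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("unsupported config format: use .yaml, .yml or .json")
  }
  afl <- lst$acquisition$autofluorescence
  af <- default_autofluorescence()
  if (!is.null(afl)) {
    for (i in seq_along(afl$structure)) {
      af[afl$structure[[i]], unlist(afl$channel)] <-
        as.numeric(unlist(afl$values[[i]]))
    }
  }
  run_config(
    scale = lst$scale,
    pitch_um = lst$pitch_um,
    n_per_group = unlist(lst$n_per_group),
    group_duration_min = unlist(lst$group_duration_min),
    tracers = lapply(lst$tracers, function(t) {
      tracer_spec(name = t$name,
                  molecular_weight_kda = t$molecular_weight_kda,
                  concentration_mg_ml = t$concentration_mg_ml,
                  diffusivity_um2_s = t$diffusivity_um2_s,
                  csf_dispersion_um2_s = t$csf_dispersion_um2_s,
                  csf_transport_rate_s = t$csf_transport_rate_s,
                  channel = t$channel)
    }),
    infusion = infusion_spec(
      total_volume_ul = lst$infusion$total_volume_ul,
      rate_ul_min = lst$infusion$rate_ul_min,
      duration_min = lst$infusion$duration_min,
      site_structure = lst$infusion$site_structure,
      site_offset_mm = as.numeric(unlist(lst$infusion$site_offset_mm))
    ),
    acquisition = acquisition_spec(
      exposure_ms = unlist(lst$acquisition$exposure_ms),
      gain = lst$acquisition$gain,
      noise_sd = lst$acquisition$noise_sd,
      n_stuck = lst$acquisition$n_stuck,
      stuck_value = lst$acquisition$stuck_value,
      render_upsample = lst$acquisition$render_upsample,
      autofluorescence = af
    ),
    threshold_q = lst$threshold_q,
    threshold_s = lst$threshold_s,
    min_voxels = lst$min_voxels,
    site_jitter_sd_mm = lst$site_jitter_sd_mm,
    diffusivity_cv = lst$diffusivity_cv,
    csf_flow_um_s = lst$csf_flow_um_s,
    seed = lst$seed,
    out_dir = out_dir
  )
}
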