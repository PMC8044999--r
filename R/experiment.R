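#' Configuration for a full synthetic cohort experiment
#'
#' Bundles every knob of the end-to-end pipeline. The defaults reproduce the
#' reference study design at desk scale: two dextran tracers (3 kDa Texas
#' Red, 500 kDa fluorescein) co-infused into the hippocampus, a group of 3
#' mice sacrificed directly after the 10-min infusion and a group of 7 mice
#' after an additional 80-min spreading period, imaged at a 3:1 in-plane to
#' slice-thickness pitch ratio and reconstructed to an isotropic grid.
#'
#' @param scale Phantom geometric scale (default 0.5, the desk-scale mouse).
#' @param pitch_um Simulation/reconstruction voxel pitch, um.
#' @param n_per_group Named vector: mice per group.
#' @param group_duration_min Named vector: total simulated spread per group
#'   (infusion period included), minutes.
#' @param tracers List of [tracer_spec()]s.
#' @param infusion An [infusion_spec()].
#' @param acquisition An [acquisition_spec()].
#' @param threshold_q,threshold_s Percentile and safety factor of the
#'   background-threshold rule (see [estimate_threshold()]).
#' @param min_voxels Presence-call threshold, voxels.
#' @param site_jitter_sd_mm Per-mouse SD of the infusion-site jitter
#'   (full-scale mm, each axis).
#' @param diffusivity_cv Per-mouse lognormal coefficient of variation of the
#'   parenchymal diffusivity.
#' @param csf_flow_um_s Bulk SAS flow speed passed to [simulate_spread()].
#' @param seed Master seed; per-mouse seeds are derived as
#'   `seed * 1000 + mouse_counter`, so earlier mice are unchanged when the
#'   cohort grows.
#' @param out_dir Optional output directory; when given, tables, meshes and
#'   a manifest are written there.
#' @return A `cryoclear_config` list.
#' @export
run_config <- function(scale = 0.5, pitch_um = 90,
                       n_per_group = c("10min" = 3L, "10+80min" = 7L),
                       group_duration_min = c("10min" = 10, "10+80min" = 90),
                       tracers = list(tracer_spec("texas_red_3k"),
                                      tracer_spec("fluorescein_500k")),
                       infusion = infusion_spec(),
                       acquisition = acquisition_spec(),
                       threshold_q = 99.95, threshold_s = 1.1,
                       min_voxels = 2L,
                       site_jitter_sd_mm = 0.1,
                       diffusivity_cv = 0.15,
                       csf_flow_um_s = 8,
                       seed = 1L, out_dir = NULL) {
  stopifnot(all(n_per_group >= 1), all(group_duration_min > 0),
            identical(names(n_per_group), names(group_duration_min)))
  structure(list(
    scale = scale, pitch_um = pitch_um,
    n_per_group = n_per_group, group_duration_min = group_duration_min,
    tracers = tracers, infusion = infusion, acquisition = acquisition,
    threshold_q = threshold_q, threshold_s = threshold_s,
    min_voxels = as.integer(min_voxels),
    site_jitter_sd_mm = site_jitter_sd_mm,
    diffusivity_cv = diffusivity_cv,
    csf_flow_um_s = csf_flow_um_s,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "cryoclear_config")
}

#' Run the full synthetic cohort experiment
#'
#' Simulates every mouse of the configured cohort (infusion, spread, slice
#' rendering), reconstructs the volumes (stuck-pixel detection and repair,
#' isotropic block-mean rescale), calibrates one fixed threshold per channel
#' on the first mouse and reuses it for all mice, segments and quantifies
#' dispersion volumes, scores per-structure presence, and runs the
#' study-level statistics: a binary GEE of presence on group per tracer and
#' an exact Mann-Whitney U test on the dispersion volumes per tracer.
#'
#' @param config A [run_config()].
#' @param verbose Print per-mouse progress to stderr.
#' @return A `cryoclear_experiment` list: `volumes` (tibble, one row per
#'   mouse x tracer), `presence` (long tibble), `proportions`,
#'   `gee` (per-tracer results incl. errors as messages), `rank_tests`,
#'   `fold_changes`, `thresholds`, `atlas`, `config`, `manifest`.
#' @export
run_experiment <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "cryoclear_config"))
  say <- function(...) if (verbose) message(...)
  t_start <- Sys.time()

  spec <- phantom_spec(scale = config$scale, pitch_um = config$pitch_um,
                       seed = config$seed)
  say("building atlas (grid ", paste(spec$grid_shape, collapse = " x "), ")")
  atlas <- build_anatomy(spec)

  # camera defects are a property of the sensor: generated once from the
  # master seed and shared by every mouse
  acq <- config$acquisition
  if (is.null(acq$stuck_pixels) && acq$n_stuck > 0) {
    up <- acq$render_upsample
    set.seed(config$seed)
    acq$stuck_pixels <- tibble::tibble(
      row = sample.int(dim(atlas$labels)[2] * up, acq$n_stuck, replace = TRUE),
      col = sample.int(dim(atlas$labels)[3] * up, acq$n_stuck, replace = TRUE),
      value = rep(acq$stuck_value, acq$n_stuck)
    ) |> dplyr::distinct(.data$row, .data$col, .keep_all = TRUE)
  }

  groups <- names(config$n_per_group)
  mice <- tibble::tibble(
    group = rep(groups, config$n_per_group),
    mouse_id = unlist(lapply(groups, function(g) {
      sprintf("%s_m%02d", g, seq_len(config$n_per_group[[g]]))
    })),
    counter = seq_len(sum(config$n_per_group))
  )

  thresholds <- NULL
  volumes <- list(); presence <- list(); meshes <- list()
  for (mi in seq_len(nrow(mice))) {
    m <- mice[mi, ]
    mouse_seed <- config$seed * 1000L + m$counter
    say(sprintf("mouse %s (seed %d)", m$mouse_id, mouse_seed))
    set.seed(mouse_seed)
    jitter <- stats::rnorm(3, 0, config$site_jitter_sd_mm)
    dmult <- exp(stats::rnorm(1, 0, config$diffusivity_cv))
    duration <- config$group_duration_min[[m$group]]

    fields <- list()
    for (tr in config$tracers) {
      tr_m <- tr
      tr_m$diffusivity_um2_s <- tr$diffusivity_um2_s * dmult
      f0 <- simulate_infusion(atlas, config$infusion, tr_m,
                              site_jitter_mm = jitter)
      fields[[tr$name]] <- simulate_spread(
        f0, atlas, tracer = tr_m, duration_min = duration,
        csf_flow_um_s = config$csf_flow_um_s)
    }
    slices <- render_slices(fields, atlas, acq, seed = mouse_seed)

    # reconstruction: defect map from the first fluorescence channel,
    # applied to every channel
    chans <- vapply(config$tracers, function(t) t$channel, character(1))
    stuck_mask <- detect_stuck_pixels(slices, channel = chans[[1]])
    vols <- list()
    for (ch in unique(chans)) {
      repaired <- lapply(slices$channels[[ch]], repair_stuck_pixels,
                         stuck_mask = stuck_mask)
      vols[[ch]] <- rescale_isotropic(
        repaired, channel = ch,
        pixel_pitch = slices$pixel_pitch_um,
        slice_thickness = slices$slice_thickness_um)
    }
    if (is.null(thresholds)) {
      thresholds <- vapply(vols, estimate_threshold, numeric(1),
                           atlas = atlas, q = config$threshold_q,
                           s = config$threshold_s)
      say("calibrated thresholds: ",
          paste(names(thresholds), round(thresholds), collapse = ", "))
    }
    for (tr in config$tracers) {
      ch <- tr$channel
      mask <- segment_volume(vols[[ch]], thresholds[[ch]])
      volumes[[length(volumes) + 1]] <- dispersion_volume(
        mask, mouse_id = m$mouse_id, tracer = tr$name, group = m$group)
      sc <- score_presence(mask, atlas, min_voxels = config$min_voxels)
      presence[[length(presence) + 1]] <- tibble::tibble(
        mouse_id = m$mouse_id, group = m$group, tracer = tr$name,
        structure = sc$structure, present = sc$present)
      if (!is.null(config$out_dir) && any(mask$mask)) {
        meshes[[paste(m$mouse_id, tr$name, sep = "_")]] <- extract_mesh(mask)
      }
    }
  }
  volumes <- dplyr::bind_rows(volumes)
  presence <- dplyr::bind_rows(presence)
  proportions <- tabulate_proportions(presence)

  # statistics per tracer
  group_levels <- groups  # first = reference
  gee <- lapply(config$tracers, function(tr) {
    long <- presence |>
      dplyr::filter(.data$tracer == tr$name) |>
      dplyr::mutate(x = as.integer(.data$group == group_levels[2]))
    fit <- tryCatch(
      fit_gee_binary(long, y_col = "present", x_col = "x",
                     cluster_col = "mouse_id"),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(tracer = tr$name, or = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, p = NA_real_, rho = NA_real_,
                     n_iter = NA_integer_, converged = FALSE,
                     note = conditionMessage(fit))
    } else {
      tibble::tibble(tracer = tr$name, or = fit$or, ci_low = fit$ci95[1],
                     ci_high = fit$ci95[2], p = fit$p, rho = fit$rho,
                     n_iter = fit$n_iter, converged = fit$converged,
                     note = NA_character_)
    }
  }) |> dplyr::bind_rows()

  rank_tests <- lapply(config$tracers, function(tr) {
    va <- volumes$volume_mm3[volumes$tracer == tr$name &
                               volumes$group == group_levels[1]]
    vb <- volumes$volume_mm3[volumes$tracer == tr$name &
                               volumes$group == group_levels[2]]
    mw <- mann_whitney_exact(va, vb)
    tibble::tibble(tracer = tr$name, u_statistic = mw$u_statistic,
                   p = mw$p_two_sided, n1 = mw$n1, n2 = mw$n2,
                   fold_change = fold_change(va, vb))
  }) |> dplyr::bind_rows()

  manifest <- list(
    package = "cryoclear",
    seed = config$seed,
    mouse_seeds = stats::setNames(config$seed * 1000L + mice$counter,
                                  mice$mouse_id),
    scale = config$scale, pitch_um = config$pitch_um,
    n_per_group = as.list(config$n_per_group),
    group_duration_min = as.list(config$group_duration_min),
    thresholds = as.list(thresholds),
    threshold_rule = list(q = config$threshold_q, s = config$threshold_s),
    min_voxels = config$min_voxels,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )

  result <- structure(list(
    volumes = volumes, presence = presence, proportions = proportions,
    gee = gee, rank_tests = rank_tests,
    thresholds = thresholds, atlas = atlas, config = config,
    manifest = manifest
  ), class = "cryoclear_experiment")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(volumes, file.path(config$out_dir, "volumes.csv"))
    readr::write_csv(presence, file.path(config$out_dir, "presence.csv"))
    readr::write_csv(proportions, file.path(config$out_dir, "proportions.csv"))
    readr::write_csv(gee, file.path(config$out_dir, "gee_results.csv"))
    readr::write_csv(rank_tests, file.path(config$out_dir, "rank_tests.csv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(meshes) > 0) {
      mesh_dir <- file.path(config$out_dir, "meshes")
      dir.create(mesh_dir, showWarnings = FALSE)
      for (nm in names(meshes)) {
        write_mesh_ply(meshes[[nm]], file.path(mesh_dir, paste0(nm, ".ply")))
      }
    }
  }
  result
}

#' @export
print.cryoclear_experiment <- function(x, ...) {
  cat("cryoclear experiment:",
      sum(x$config$n_per_group), "mice,",
      length(x$config$tracers), "tracers\n")
  cat("thresholds:", paste(names(x$thresholds), round(x$thresholds),
                           collapse = ", "), "\n\n")
  cat("GEE (presence ~ group):\n"); print(x$gee)
  cat("\nMann-Whitney on dispersion volumes:\n"); print(x$rank_tests)
  invisible(x)
}

#' @method tidy cryoclear_experiment
#' @export
tidy.cryoclear_experiment <- function(x, ...) x$volumes

#' @method glance cryoclear_experiment
#' @export
glance.cryoclear_experiment <- function(x, ...) {
  dplyr::left_join(x$gee, x$rank_tests, by = "tracer",
                   suffix = c("_gee", "_mw"))
}
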