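#' Render cryomicrotome slice images from tracer fields
#'
#' Produces the instrument's raw output: per-slice, per-channel 16-bit
#' images, emitted thorax to nose. Each channel's intensity is
#' `gain x concentration x exposure + autofluorescence(structure, channel)`
#' plus Gaussian read noise, clipped to `[0, 65535]` and quantised to
#' integers; stuck pixels are then overwritten with their defect value.
#' Fluorescence channels image the tracer whose `channel` matches; the
#' reflection channel images autofluorescence/reflectance only. In-plane
#' pixels are `render_upsample` times finer than the simulation grid, so the
#' native 3:1 pitch ratio between in-plane pixels and slice thickness is
#' reproduced.
#'
#' @param fields Named list of `cryoclear_field`s (one per tracer), all on
#'   the same grid as `atlas`.
#' @param atlas The `cryoclear_atlas`.
#' @param acq An [acquisition_spec()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   output.
#' @return A `cryoclear_slices`: list with `channels` (named list of lists
#'   of integer matrices), `pixel_pitch_um`, `slice_thickness_um`,
#'   `stuck_pixels` (tibble `row`, `col`, `value`), `seed`.
#' @export
render_slices <- function(fields, atlas, acq = acquisition_spec(), seed = 1L) {
  stopifnot(inherits(atlas, "cryoclear_atlas"),
            inherits(acq, "cryoclear_acquisition_spec"))
  for (f in fields) {
    if (!all(dim(f$concentration) == dim(atlas$labels))) {
      stop("field and atlas grids are not congruent")
    }
  }
  d <- dim(atlas$labels)
  up <- acq$render_upsample
  nr <- d[2] * up; nc <- d[3] * up
  channels <- names(acq$exposure_ms)

  # per-channel concentration source (NULL for reflection-like channels)
  field_for_channel <- function(ch) {
    hit <- Filter(function(f) identical(f$tracer$channel, ch), fields)
    if (length(hit) == 0) NULL else hit[[1]]
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  stuck <- acq$stuck_pixels
  if (is.null(stuck) && acq$n_stuck > 0) {
    stuck <- tibble::tibble(
      row = sample.int(nr, acq$n_stuck, replace = TRUE),
      col = sample.int(nc, acq$n_stuck, replace = TRUE),
      value = rep(acq$stuck_value, acq$n_stuck)
    )
    stuck <- dplyr::distinct(stuck, .data$row, .data$col, .keep_all = TRUE)
  }

  af <- acq$autofluorescence
  labs <- atlas_labels()
  out <- stats::setNames(vector("list", length(channels)), channels)
  ones <- matrix(1, up, up)
  for (ch in channels) {
    fl <- field_for_channel(ch)
    af_lut <- numeric(max(labs$label) + 1)
    af_lut[labs$label + 1] <- af[labs$structure, ch]
    slices <- vector("list", d[1])
    for (z in seq_len(d[1])) {
      lab_plane <- atlas$labels[z, , ]
      base <- matrix(af_lut[lab_plane + 1L], d[2], d[3])
      if (!is.null(fl)) {
        base <- base + acq$gain * fl$concentration[z, , ] * acq$exposure_ms[[ch]]
      }
      img <- kronecker(base, ones)
      if (acq$noise_sd > 0) {
        img <- img + stats::rnorm(length(img), 0, acq$noise_sd)
      }
      img <- round(pmin(pmax(img, 0), 65535))
      if (!is.null(stuck) && nrow(stuck) > 0) {
        img[cbind(stuck$row, stuck$col)] <- stuck$value
      }
      storage.mode(img) <- "integer"
      slices[[z]] <- img
    }
    out[[ch]] <- slices
  }
  structure(list(
    channels = out,
    pixel_pitch_um = atlas$pitch_um / up,
    slice_thickness_um = atlas$pitch_um,
    stuck_pixels = stuck,
    seed = as.integer(seed)
  ), class = "cryoclear_slices")
}

#' @export
print.cryoclear_slices <- function(x, ...) {
  ch1 <- x$channels[[1]]
  cat(sprintf(
    "cryoclear_slices: %d slices x %d channel(s), %d x %d px, %g um in-plane / %g um thickness\n",
    length(ch1), length(x$channels), nrow(ch1[[1]]), ncol(ch1[[1]]),
    x$pixel_pitch_um, x$slice_thickness_um))
  invisible(x)
}
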