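#' Repair stuck pixels by the median of their neighbours
#'
#' Replaces each flagged pixel by the median of its non-flagged neighbours in
#' the 8-neighbourhood (edge-truncated at image borders). All other pixels
#' are returned unchanged. With an even number of neighbours the median is
#' the mean of the two central order statistics.
#'
#' @param image Numeric matrix (one slice, one channel).
#' @param stuck_mask Logical matrix of the same shape; `TRUE` marks defective
#'   pixels.
#' @return The repaired matrix.
#' @examples
#' img <- matrix(100, 3, 3); img[2, 2] <- 65535
#' m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE
#' repair_stuck_pixels(img, m)[2, 2] # 100
#' @export
repair_stuck_pixels <- function(image, stuck_mask) {
  if (!all(dim(image) == dim(stuck_mask))) {
    stop("stuck_mask shape does not match image")
  }
  if (!any(stuck_mask)) return(image)
  nr <- nrow(image); nc <- ncol(image)
  out <- image
  idx <- which(stuck_mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    nb_val <- image[ii, jj, drop = FALSE]
    nb_msk <- stuck_mask[ii, jj, drop = FALSE]
    nb_msk[which(ii == i), which(jj == j)] <- TRUE  # exclude centre
    vals <- nb_val[!nb_msk]
    if (length(vals) == 0) {
      stop("stuck pixel at (", i, ", ", j, ") has no usable neighbours")
    }
    out[i, j] <- stats::median(vals)
  }
  out
}

# Row-wise median of an n x 8 matrix via an 8-element sorting network,
# fully vectorised (19 compare-exchange stages; Batcher odd-even merge).
rowmed8 <- function(m) {
  stopifnot(ncol(m) == 8)
  cx <- function(a, b) list(pmin(m[, a], m[, b]), pmax(m[, a], m[, b]))
  net <- list(c(1,2), c(3,4), c(5,6), c(7,8),
              c(1,3), c(2,4), c(5,7), c(6,8),
              c(2,3), c(6,7),
              c(1,5), c(4,8),
              c(2,6), c(3,7),
              c(2,5), c(4,7),
              c(3,5), c(4,6),
              c(4,5))
  for (p in net) {
    s <- cx(p[1], p[2])
    m[, p[1]] <- s[[1]]; m[, p[2]] <- s[[2]]
  }
  (m[, 4] + m[, 5]) / 2
}

# Map of 8-neighbour medians for the interior of a matrix (borders NA).
neighbour_median8 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  if (nr < 3 || nc < 3) return(out)
  ci <- 2:(nr - 1); cj <- 2:(nc - 1)
  sh <- function(di, dj) as.vector(img[ci + di, cj + dj])
  nb <- cbind(sh(-1,-1), sh(-1,0), sh(-1,1),
              sh(0,-1),            sh(0,1),
              sh(1,-1),  sh(1,0),  sh(1,1))
  out[ci, cj] <- rowmed8(nb)
  out
}

#' Detect stuck pixels across a slice stack
#'
#' Flags camera-defect pixels in a slice series: a pixel is flagged when its
#' value is constant across all slices and deviates from the per-slice
#' 8-neighbour median by more than `k` times the slice's median absolute
#' deviation of that residual map in at least `frac` of the slices. Border
#' pixels (incomplete neighbourhoods) are never flagged.
#'
#' @param slices A `cryoclear_slices` object (see [render_slices()]) or a
#'   list of numeric matrices (one channel); at least 5 slices.
#' @param channel Channel name when `slices` is a `cryoclear_slices`.
#' @param k Residual threshold in MAD units (default 10).
#' @param frac Minimum fraction of slices in which the deviation must hold.
#' @return Logical matrix, `TRUE` at detected stuck pixels.
#' @export
detect_stuck_pixels <- function(slices, channel = NULL, k = 10, frac = 0.9) {
  imgs <- slice_list(slices, channel)
  if (length(imgs) < 5) stop("need at least 5 slices to detect stuck pixels")
  dims <- dim(imgs[[1]])
  arr <- vapply(imgs, identity, matrix(0, dims[1], dims[2]))
  constant <- apply(arr, c(1, 2), function(v) all(v == v[1]))
  hits <- matrix(0L, dims[1], dims[2])
  for (s in seq_along(imgs)) {
    med <- neighbour_median8(imgs[[s]])
    r <- imgs[[s]] - med
    madr <- stats::mad(r, na.rm = TRUE)
    if (madr == 0) madr <- Inf  # flat slice: nothing deviates
    dev <- !is.na(r) & abs(r) > k * madr
    hits <- hits + dev
  }
  constant & (hits >= frac * length(imgs))
}

# Accept either a cryoclear_slices object or a bare list of matrices.
slice_list <- function(slices, channel = NULL) {
  if (inherits(slices, "cryoclear_slices")) {
    if (is.null(channel)) channel <- names(slices$channels)[1]
    if (!channel %in% names(slices$channels)) {
      stop("unknown channel: ", channel)
    }
    slices$channels[[channel]]
  } else if (is.list(slices)) {
    slices
  } else {
    stop("slices must be a cryoclear_slices object or a list of matrices")
  }
}

#' Rescale a slice series to an isotropic volume
#'
#' Reduces each slice by non-overlapping block averaging so the in-plane
#' pixel pitch matches the slice thickness, then stacks the slices along the
#' cutting axis in acquisition order. This is the only resampling dialect
#' supported: the in-plane pitch must divide the target pitch by an integer
#' factor (15 um in-plane with 45 um slices gives 3x3 blocks), and the slice
#' thickness must already equal the target pitch. Block means are kept as
#' floating point; quantisation happens only on export.
#'
#' @param slices A `cryoclear_slices` object or a list of matrices.
#' @param channel Channel to reconstruct when `slices` holds several.
#' @param pixel_pitch,slice_thickness Geometry in um; taken from the slice
#'   set when available.
#' @return A `cryoclear_volume`: list with `intensities` (3D array, axis 1 =
#'   cutting axis, thorax first), `pitch_um`, `channel`, `provenance`.
#' @export
rescale_isotropic <- function(slices, channel = NULL,
                              pixel_pitch = NULL, slice_thickness = NULL) {
  imgs <- slice_list(slices, channel)
  if (inherits(slices, "cryoclear_slices")) {
    if (is.null(pixel_pitch)) pixel_pitch <- slices$pixel_pitch_um
    if (is.null(slice_thickness)) slice_thickness <- slices$slice_thickness_um
    if (is.null(channel)) channel <- names(slices$channels)[1]
  }
  if (is.null(pixel_pitch) || is.null(slice_thickness)) {
    stop("pixel_pitch and slice_thickness are required")
  }
  f <- slice_thickness / pixel_pitch
  if (abs(f - round(f)) > 1e-9) {
    stop("in-plane pitch (", pixel_pitch, " um) does not divide the target ",
         "pitch (", slice_thickness, " um); only integer block-mean ",
         "reduction is supported")
  }
  f <- as.integer(round(f))
  dims <- dim(imgs[[1]])
  if (any(dims %% f != 0)) {
    stop("slice dimensions ", dims[1], "x", dims[2],
         " are not divisible by the reduction factor ", f)
  }
  nr <- dims[1] %/% f; nc <- dims[2] %/% f
  reduce <- function(img) {
    if (f == 1L) return(img)
    # mean over f x f blocks: fold rows, then columns
    a <- array(img, dim = c(f, nr, f, nc))
    colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
  }
  planes <- lapply(imgs, reduce)
  vol <- array(0, dim = c(length(planes), nr, nc))
  for (s in seq_along(planes)) vol[s, , ] <- planes[[s]]
  structure(list(
    intensities = vol,
    pitch_um = slice_thickness,
    channel = channel %||% "unknown",
    provenance = list(
      n_slices = length(planes),
      reduction_factor = f,
      source_pixel_pitch_um = pixel_pitch
    )
  ), class = "cryoclear_volume")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cryoclear_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "cryoclear_volume: %d x %d x %d voxels at %g um (channel %s)\n",
    d[1], d[2], d[3], x$pitch_um, x$channel))
  invisible(x)
}
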