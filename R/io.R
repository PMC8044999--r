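#' Write a slice set as per-channel TIFF series
#'
#' One 16-bit TIFF per slice per channel (`<channel>/slice_0001.tif`, ...),
#' thorax to nose, plus a JSON sidecar (`acquisition.json`) recording the
#' geometry, seed and stuck-pixel table.
#'
#' @param slices A `cryoclear_slices`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sliceset <- function(slices, dir) {
  stopifnot(inherits(slices, "cryoclear_slices"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(slices$channels)) {
    chdir <- file.path(dir, ch)
    dir.create(chdir, showWarnings = FALSE)
    sl <- slices$channels[[ch]]
    for (i in seq_along(sl)) {
      tiff::writeTIFF(sl[[i]] / 65535,
                      file.path(chdir, sprintf("slice_%04d.tif", i)),
                      bits.per.sample = 16, compression = "none")
    }
  }
  sidecar <- list(
    pixel_pitch_um = slices$pixel_pitch_um,
    slice_thickness_um = slices$slice_thickness_um,
    n_slices = length(slices$channels[[1]]),
    channels = names(slices$channels),
    seed = slices$seed,
    axis_convention = "slice index increases thorax -> nose",
    stuck_pixels = slices$stuck_pixels
  )
  jsonlite::write_json(sidecar, file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a slice set written by [write_sliceset()]
#'
#' @param dir Directory holding per-channel TIFF series and the
#'   `acquisition.json` sidecar.
#' @return A `cryoclear_slices`.
#' @export
read_sliceset <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "acquisition.json"),
                                 simplifyVector = TRUE)
  channels <- stats::setNames(vector("list", length(sidecar$channels)),
                              sidecar$channels)
  for (ch in sidecar$channels) {
    files <- sort(list.files(file.path(dir, ch), pattern = "\\.tif$",
                             full.names = TRUE))
    channels[[ch]] <- lapply(files, function(f) {
      img <- round(tiff::readTIFF(f) * 65535)
      storage.mode(img) <- "integer"
      img
    })
  }
  stuck <- sidecar$stuck_pixels
  structure(list(
    channels = channels,
    pixel_pitch_um = sidecar$pixel_pitch_um,
    slice_thickness_um = sidecar$slice_thickness_um,
    stuck_pixels = if (is.null(stuck)) NULL else tibble::as_tibble(stuck),
    seed = sidecar$seed
  ), class = "cryoclear_slices")
}

#' Write a volume, label volume or mask as NIfTI
#'
#' The isotropic pitch is stored in the NIfTI `pixdim` header (mm).
#'
#' @param x A `cryoclear_volume`, `cryoclear_atlas`, `cryoclear_mask`,
#'   `cryoclear_field`, or a bare 3D array (then `pitch_um` is required).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pitch_um Voxel pitch override, um.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(x, path, pitch_um = NULL) {
  arr <- if (inherits(x, "cryoclear_volume")) x$intensities
    else if (inherits(x, "cryoclear_atlas")) x$labels
    else if (inherits(x, "cryoclear_mask")) x$mask + 0L
    else if (inherits(x, "cryoclear_field")) x$concentration
    else x
  if (is.null(pitch_um)) {
    pitch_um <- if (inherits(x, "cryoclear_atlas")) x$pitch_um
      else if (inherits(x, c("cryoclear_volume", "cryoclear_mask",
                             "cryoclear_field"))) x$pitch_um
      else stop("pitch_um is required for a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(pitch_um / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file written by [write_volume_nifti()]
#'
#' @param path NIfTI path.
#' @param channel Channel tag to attach.
#' @return A `cryoclear_volume` (intensities + pitch from the header).
#' @export
read_volume_nifti <- function(path, channel = "unknown") {
  img <- RNifti::readNifti(path)
  structure(list(
    intensities = array(as.numeric(img), dim = dim(img)),
    pitch_um = RNifti::pixdim(img)[1] * 1000,
    channel = channel,
    provenance = list(source = path)
  ), class = "cryoclear_volume")
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh A `cryoclear_mesh`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; f <- mesh$faces
  writeLines(c(
    "ply", "format ascii 1.0",
    "comment units: micrometres",
    paste("element vertex", nrow(v)),
    "property float x", "property float y", "property float z",
    paste("element face", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  ), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as ASCII STL
#'
#' @param mesh A `cryoclear_mesh`.
#' @param path Output `.stl` path.
#' @param name Solid name in the STL header.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path, name = "cryoclear") {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  chunk <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
  writeLines(chunk, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}
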