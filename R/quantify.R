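#' Calibrate a fixed segmentation threshold from tracer-free regions
#'
#' Implements the study's threshold rule: the per-channel segmentation
#' threshold is chosen from regions where tracer is known to be absent (by
#' default skull/bone, muscle, and the structures with strong endogenous
#' autofluorescence — blood vessels and nasal turbinates) so that background
#' and autofluorescence are never segmented. The threshold is the `q`-th
#' percentile of the intensities inside the background labels multiplied by
#' a safety factor `s`, and is intended to be estimated once per channel and
#' reused unchanged for every mouse in a cohort.
#'
#' @param volume A `cryoclear_volume` or a numeric 3D array.
#' @param atlas A `cryoclear_atlas` or an integer 3D array of label codes.
#' @param background_labels Structure ids defining the tracer-free
#'   calibration region.
#' @param q Percentile in \[0, 100\] (default 99.95).
#' @param s Safety factor multiplied onto the percentile (default 1.1).
#' @return A single numeric threshold (intensity units).
#' @export
estimate_threshold <- function(volume, atlas,
                               background_labels = c("bone", "muscle",
                                                     "blood_vessel",
                                                     "nasal_turbinates"),
                               q = 99.95, s = 1.1) {
  v <- if (inherits(volume, "cryoclear_volume")) volume$intensities else volume
  lab <- if (inherits(atlas, "cryoclear_atlas")) atlas$labels else atlas
  if (!all(dim(v) == dim(lab))) stop("volume and atlas grids are not congruent")
  if (length(background_labels) == 0) stop("background label set is empty")
  codes <- structure_code(background_labels)
  sel <- lab %in% codes
  if (!any(sel)) stop("background region is empty in the atlas")
  unname(stats::quantile(v[sel], q / 100, names = FALSE) * s)
}

#' Segment a volume at a fixed intensity threshold
#'
#' Pure thresholding: a voxel is in the mask exactly when its intensity is
#' greater than or equal to the threshold (voxels below the threshold are
#' excluded). No connected-component or size filtering is applied unless
#' requested.
#'
#' @param volume A `cryoclear_volume` or numeric 3D array.
#' @param threshold Intensity threshold (>= 0).
#' @param min_component Optional minimum connected-component size (6-connected
#'   voxels); `0` (default) disables component filtering.
#' @return A `cryoclear_mask`: list with `mask` (logical 3D array),
#'   `threshold`, `channel`, `pitch_um`.
#' @export
segment_volume <- function(volume, threshold, min_component = 0L) {
  v <- if (inherits(volume, "cryoclear_volume")) volume$intensities else volume
  if (threshold < 0) stop("threshold must be non-negative")
  m <- v >= threshold
  if (min_component > 0L) {
    comp <- label_components6(m)
    keep <- which(tabulate(comp[comp > 0]) >= min_component)
    m <- array(comp %in% keep, dim = dim(m))
  }
  structure(list(
    mask = m,
    threshold = threshold,
    channel = if (inherits(volume, "cryoclear_volume")) volume$channel else "unknown",
    pitch_um = if (inherits(volume, "cryoclear_volume")) volume$pitch_um else NA_real_
  ), class = "cryoclear_mask")
}

# 6-connected component labelling by iterative flood fill (queue-based).
label_components6 <- function(mask) {
  d <- dim(mask)
  comp <- array(0L, dim = d)
  n <- prod(d)
  strides <- c(1L, d[1], d[1] * d[2])
  coord_ok <- function(i, axis, step) {
    c3 <- arrayInd(i, d)
    j <- c3[, axis] + step
    j >= 1 & j <= d[axis]
  }
  lab <- 0L
  todo <- which(mask & comp == 0L)
  while (length(todo) > 0) {
    seed <- todo[1]
    lab <- lab + 1L
    frontier <- seed
    comp[seed] <- lab
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (axis in 1:3) for (step in c(-1L, 1L)) {
        ok <- coord_ok(frontier, axis, step)
        cand <- frontier[ok] + step * strides[axis]
        cand <- cand[mask[cand] & comp[cand] == 0L]
        if (length(cand)) {
          comp[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- which(mask & comp == 0L)
  }
  comp
}

#' Dispersion volume of a segmentation mask
#'
#' The study's volumetric read-out: the number of above-threshold voxels
#' multiplied by the voxel volume. At the acquisition pitch of 45 um each
#' voxel is 0.045^3 mm3.
#'
#' @param mask A `cryoclear_mask` or a logical 3D array.
#' @param pitch_um Voxel pitch in um; taken from the mask when available.
#' @param mouse_id,tracer,group Optional identifiers carried into the record.
#' @return A one-row tibble: `mouse_id`, `group`, `tracer`, `threshold`,
#'   `voxel_count`, `volume_mm3` (exactly `voxel_count * (pitch/1000)^3`).
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1, 1] <- TRUE
#' dispersion_volume(m, pitch_um = 45)$volume_mm3 # 10 * 0.045^3
#' @export
dispersion_volume <- function(mask, pitch_um = NULL, mouse_id = NA_character_,
                              tracer = NA_character_, group = NA_character_) {
  if (inherits(mask, "cryoclear_mask")) {
    if (is.null(pitch_um)) pitch_um <- mask$pitch_um
    thr <- mask$threshold
    m <- mask$mask
  } else {
    thr <- NA_real_
    m <- mask
  }
  if (is.null(pitch_um) || is.na(pitch_um)) stop("voxel pitch is required")
  count <- sum(m)
  tibble::tibble(
    mouse_id = mouse_id, group = group, tracer = tracer,
    threshold = thr,
    voxel_count = as.integer(count),
    volume_mm3 = count * (pitch_um / 1000)^3
  )
}

#' Extract a polygon mesh of a segmentation mask
#'
#' Triangle mesh of the 0.5-level isosurface of the binary mask under
#' nearest-neighbour interpolation, i.e. the boundary surface of the voxel
#' set, with vertices at voxel corners in physical um coordinates and
#' outward-oriented faces. The enclosed volume of the mesh therefore equals
#' the voxel-count volume exactly, which ties the mesh and the voxel
#' volumetry to the same object. The mesh may consist of several connected
#' components; components are watertight provided no two mask voxels touch
#' only along an edge or corner.
#'
#' @param mask A `cryoclear_mask` or logical 3D array (must be non-empty).
#' @param pitch_um Voxel pitch in um; taken from the mask when available.
#' @return A `cryoclear_mesh`: list with `vertices` (n x 3 matrix, um) and
#'   `faces` (m x 3 integer matrix of vertex indices, outward winding).
#' @export
extract_mesh <- function(mask, pitch_um = NULL) {
  if (inherits(mask, "cryoclear_mask")) {
    if (is.null(pitch_um)) pitch_um <- mask$pitch_um
    m <- mask$mask
  } else {
    m <- mask
  }
  if (is.null(pitch_um) || is.na(pitch_um)) stop("voxel pitch is required")
  if (!any(m)) stop("cannot mesh an empty mask")
  d <- dim(m)
  nxc <- d[1] + 1L; nyc <- d[2] + 1L  # corner-grid extents (axes 1, 2)
  corner_id <- function(i, j, k) i + nxc * (j + nyc * k)  # 0-based corners

  pad_shift <- function(axis, step) {
    # neighbour occupancy in direction (axis, step); FALSE outside the grid
    out <- array(FALSE, dim = d)
    if (axis == 1) {
      if (step == 1) out[1:(d[1] - 1), , ] <- m[2:d[1], , ]
      else out[2:d[1], , ] <- m[1:(d[1] - 1), , ]
    } else if (axis == 2) {
      if (step == 1) out[, 1:(d[2] - 1), ] <- m[, 2:d[2], ]
      else out[, 2:d[2], ] <- m[, 1:(d[2] - 1), ]
    } else {
      if (step == 1) out[, , 1:(d[3] - 1)] <- m[, , 2:d[3]]
      else out[, , 2:d[3]] <- m[, , 1:(d[3] - 1)]
    }
    out
  }

  quads <- list()
  for (axis in 1:3) for (step in c(-1L, 1L)) {
    boundary <- m & !pad_shift(axis, step)
    if (!any(boundary)) next
    vx <- which(boundary, arr.ind = TRUE)
    i0 <- vx[, 1] - 1L; j0 <- vx[, 2] - 1L; k0 <- vx[, 3] - 1L
    # voxel (i0, j0, k0) occupies corner cube [i0, i0+1] x [j0, j0+1] x ...
    f <- function(di, dj, dk) corner_id(i0 + di, j0 + dj, k0 + dk)
    q <- switch(paste0(axis, step),
      `1-1` = cbind(f(0,0,0), f(0,0,1), f(0,1,1), f(0,1,0)),
      `11`  = cbind(f(1,0,0), f(1,1,0), f(1,1,1), f(1,0,1)),
      `2-1` = cbind(f(0,0,0), f(1,0,0), f(1,0,1), f(0,0,1)),
      `21`  = cbind(f(0,1,0), f(0,1,1), f(1,1,1), f(1,1,0)),
      `3-1` = cbind(f(0,0,0), f(0,1,0), f(1,1,0), f(1,0,0)),
      `31`  = cbind(f(0,0,1), f(1,0,1), f(1,1,1), f(0,1,1))
    )
    quads[[length(quads) + 1L]] <- q
  }
  quads <- do.call(rbind, quads)
  used <- sort(unique(as.vector(quads)))
  remap <- match(quads, used)
  dim(remap) <- dim(quads)
  # corner id back to integer coordinates
  kk <- used %/% (nxc * nyc)
  jj <- (used - kk * nxc * nyc) %/% nxc
  ii <- used - kk * nxc * nyc - jj * nxc
  vertices <- cbind(ii, jj, kk) * pitch_um
  colnames(vertices) <- c("x1", "x2", "x3")
  faces <- rbind(remap[, c(1, 2, 3)], remap[, c(1, 3, 4)])
  structure(list(vertices = vertices, faces = faces, pitch_um = pitch_um),
            class = "cryoclear_mesh")
}

#' Enclosed volume of a closed mesh
#'
#' Signed-volume sum over faces (divergence theorem); positive for outward
#' winding. Returned in mm3.
#'
#' @param mesh A `cryoclear_mesh`.
#' @return Volume in mm3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices / 1000  # um -> mm
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cross <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
                 b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
                 b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cross)) / 6
}

#' Euler characteristic of a triangle mesh
#' @param mesh A `cryoclear_mesh`.
#' @return `V - E + F`.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(mesh$vertices) - nrow(e) + nrow(f)
}

#' Check mesh watertightness
#'
#' Every undirected edge must be shared by exactly two faces.
#' @param mesh A `cryoclear_mesh`.
#' @return `TRUE`/`FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2)
}

#' @export
print.cryoclear_mesh <- function(x, ...) {
  cat(sprintf("cryoclear_mesh: %d vertices, %d triangles (%.4f mm3 enclosed)\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}
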