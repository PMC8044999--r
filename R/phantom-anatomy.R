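#' Build the labeled anatomy volume of the phantom
#'
#' Paints the stylized primitive assembly of [default_structure_params()]
#' onto the phantom grid as an integer label volume. Primitives are painted
#' in a fixed precedence order in which later paints overwrite earlier ones;
#' in particular CSF compartments override parenchyma, so the ventricles,
#' cisterns and subarachnoid spaces are carved out of the brain. The CSF
#' compartments form a single connected system running from the hippocampus
#' border via the interpeduncular cistern and subarachnoid spaces to both
#' the nasal turbinates and the spinal nerves, and the ventricular chain
#' (lateral, third, fourth) drains into the subarachnoid space.
#'
#' @param spec A [phantom_spec()].
#' @return A `cryoclear_atlas`: list with `labels` (integer 3D array, axis 1
#'   = cutting axis thorax to nose), `pitch_um`, `scale`, `origin_mm`,
#'   `spec`.
#' @export
build_anatomy <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "cryoclear_phantom_spec"))
  sp <- spec$structure_params
  s <- spec$scale
  h <- spec$pitch_um / 1000
  d <- spec$grid_shape
  # voxel-centre coordinates, mm
  zc <- spec$origin_mm[1] + (seq_len(d[1]) - 0.5) * h
  yc <- spec$origin_mm[2] + (seq_len(d[2]) - 0.5) * h
  xc <- spec$origin_mm[3] + (seq_len(d[3]) - 0.5) * h

  lab <- array(0L, dim = d)
  code <- function(name) structure_code(name)

  # quadratic-form helpers; all primitive parameters are scaled by `s`
  field3 <- function(fz, fy, fx) {
    # outer sum of per-axis vectors -> 3D array
    outer(outer(fz, fy, `+`), fx, `+`)
  }
  ellipsoid <- function(center, semi) {
    field3(((zc - center[1] * s) / (semi[1] * s))^2,
           ((yc - center[2] * s) / (semi[2] * s))^2,
           ((xc - center[3] * s) / (semi[3] * s))^2) < 1
  }
  cyl_z <- function(zr, cy, cx, r) {
    inplane <- field3(rep(0, d[1]), ((yc - cy * s) / (r * s))^2,
                      ((xc - cx * s) / (r * s))^2) < 1
    inplane & field3(as.numeric(zc >= zr[1] * s & zc <= zr[2] * s) - 1,
                     rep(0, d[2]), rep(0, d[3])) > -1
  }
  cyl_x <- function(cz, cy, xr, r) {
    inplane <- field3(((zc - cz * s) / (r * s))^2,
                      ((yc - cy * s) / (r * s))^2, rep(0, d[3])) < 1
    inplane & field3(rep(0, d[1]), rep(0, d[2]),
                     as.numeric(xc >= xr[1] * s & xc <= xr[2] * s) - 1) > -1
  }
  box <- function(zr, yr, xr) {
    field3(as.numeric(zc >= zr[1] * s & zc <= zr[2] * s),
           as.numeric(yc >= yr[1] * s & yc <= yr[2] * s),
           as.numeric(xc >= xr[1] * s & xc <= xr[2] * s)) >= 3
  }
  paint <- function(mask, name) lab[mask] <<- code(name)

  # 1. soft-tissue envelope: skull ellipsoid + neck cylinder + nose cone
  bone_semi <- sp$brain_semi + sp$sas_thickness + sp$bone_thickness
  skull_outer <- ellipsoid(sp$brain_center, bone_semi)
  neck <- cyl_z(sp$neck_z, 0, 0, sp$neck_radius)
  nz_rel <- (zc / s - sp$nose_z[1]) / (sp$nose_z[2] - sp$nose_z[1])
  cone_r <- (sp$nose_base_radius +
               (sp$nose_tip_radius - sp$nose_base_radius) * pmin(pmax(nz_rel, 0), 1)) * s
  in_cone_z <- zc >= sp$nose_z[1] * s & zc <= sp$nose_z[2] * s
  rr <- sqrt(field3(rep(0, d[1]), yc^2, xc^2))
  cone <- sweep(rr, 1, cone_r, `<`) &
    array(rep(in_cone_z, d[2] * d[3]), dim = d)
  paint(skull_outer | neck | cone, "muscle")

  # 2-4. concentric head solids: bone, CSF mantle, brain
  paint(skull_outer, "bone")
  sas_solid <- ellipsoid(sp$brain_center, sp$brain_semi + sp$sas_thickness)
  split_rostral <- array(rep(zc >= sp$sas_split_z * s, d[2] * d[3]), dim = d)
  paint(sas_solid & split_rostral, "sas_cerebrum")
  paint(sas_solid & !split_rostral, "sas_cerebellum")
  brain <- ellipsoid(sp$brain_center, sp$brain_semi)
  paint(brain, "rest_of_brain")

  # 5. cortex: dorsal outer shell of the brain
  inner <- ellipsoid(sp$brain_center, sp$brain_semi * sp$cortex_inner_scale)
  dorsal <- field3(as.numeric(zc <= sp$cortex_max_z * s),
                   as.numeric(yc >= sp$cortex_min_y * s), rep(0, d[3])) >= 2
  paint(brain & !inner & dorsal, "cortex")

  # 6-8. deep parenchymal structures
  paint(ellipsoid(sp$striatum_center, sp$striatum_semi), "striatum")
  paint(ellipsoid(sp$olfactory_center, sp$olfactory_semi), "olfactory_bulb")
  paint(ellipsoid(sp$hippocampus_center, sp$hippocampus_semi), "hippocampus")

  # 9-12. internal CSF (overrides parenchyma)
  lvz <- sp$lateral_ventricle_center_z; lvy <- sp$lateral_ventricle_center_y
  lvx <- sp$lateral_ventricle_center_x
  paint(ellipsoid(c(lvz, lvy, lvx), sp$lateral_ventricle_semi) |
          ellipsoid(c(lvz, lvy, -lvx), sp$lateral_ventricle_semi),
        "lateral_ventricle")
  third <- box(sp$third_ventricle_box_z, sp$third_ventricle_box_y,
               c(-sp$third_ventricle_half_width, sp$third_ventricle_half_width))
  aqueduct <- cyl_z(sp$aqueduct_z, sp$aqueduct_y, 0, sp$aqueduct_radius)
  paint(third | aqueduct, "third_ventricle")
  paint(ellipsoid(sp$fourth_ventricle_center, sp$fourth_ventricle_semi),
        "fourth_ventricle")
  paint(ellipsoid(sp$ipc_center, sp$ipc_semi), "interpeduncular_cistern")

  # 13-14. nasal outflow: CSF channel through the cribriform region, then
  # the turbinate plates (painted after, so plates win the overlap)
  paint(cyl_z(sp$nasal_channel_z, 0, sp$nasal_channel_x,
              sp$nasal_channel_radius), "sas_cerebrum")
  turb <- array(FALSE, dim = d)
  for (tx in sp$turbinate_x) {
    turb <- turb | box(sp$turbinate_z, c(-2.5, 2.5),
                       c(tx - sp$turbinate_half_width,
                         tx + sp$turbinate_half_width))
  }
  paint(turb & (cone | sweep(rr, 1, cone_r + h, `<`)), "nasal_turbinates")

  # 15-17. spinal outflow: subarachnoid sleeve, cord, nerves
  sleeve <- cyl_z(sp$spinal_sas_z, sp$cord_y, 0, sp$spinal_sas_outer) &
    !cyl_z(sp$spinal_sas_z, sp$cord_y, 0, sp$cord_radius)
  paint(sleeve, "sas_spinal")
  paint(cyl_z(sp$cord_z, sp$cord_y, 0, sp$cord_radius), "spinal_cord")
  nerves <- array(FALSE, dim = d)
  for (nzp in sp$nerve_z) {
    nerves <- nerves |
      cyl_x(nzp, sp$cord_y, c(-sp$nerve_x_reach, -sp$cord_radius + 0.1),
            sp$nerve_radius) |
      cyl_x(nzp, sp$cord_y, c(sp$cord_radius - 0.1, sp$nerve_x_reach),
            sp$nerve_radius)
  }
  paint(nerves, "spinal_nerves")

  # 18. autofluorescent vessels in the neck soft tissue
  paint(cyl_z(sp$vessel_z, sp$vessel_y, sp$vessel_x, sp$vessel_radius) |
          cyl_z(sp$vessel_z, sp$vessel_y, -sp$vessel_x, sp$vessel_radius),
        "blood_vessel")

  atlas <- structure(list(
    labels = lab,
    pitch_um = spec$pitch_um,
    scale = s,
    origin_mm = spec$origin_mm,
    spec = spec
  ), class = "cryoclear_atlas")

  missing <- setdiff(scored_structures(), atlas_structures_present(atlas))
  if (length(missing) > 0) {
    stop("configuration error: structures absent from the painted atlas: ",
         paste(missing, collapse = ", "))
  }
  atlas
}

atlas_structures_present <- function(atlas) {
  labs <- atlas_labels()
  present <- sort(unique(as.vector(atlas$labels)))
  labs$structure[labs$label %in% present]
}

#' Volume of atlas structures
#'
#' @param atlas A `cryoclear_atlas`.
#' @param structures Structure ids; defaults to every painted label.
#' @return A tibble `structure`, `n_voxels`, `volume_mm3`.
#' @export
atlas_volumes <- function(atlas, structures = NULL) {
  if (is.null(structures)) structures <- atlas_structures_present(atlas)
  codes <- structure_code(structures)
  vv <- (atlas$pitch_um / 1000)^3
  counts <- vapply(codes, function(cd) sum(atlas$labels == cd), numeric(1))
  tibble::tibble(structure = structures,
                 n_voxels = as.integer(counts),
                 volume_mm3 = counts * vv)
}

#' Total brain parenchyma volume of an atlas, in mm3
#' @param atlas A `cryoclear_atlas`.
#' @export
brain_volume <- function(atlas) {
  sum(atlas_volumes(atlas, brain_structures())$volume_mm3)
}

# 6-neighbour adjacency between a mask and a label set: voxels of `mask`
# with at least one neighbour whose label is in `codes`.
adjacent_to <- function(mask, labels, codes) {
  d <- dim(mask)
  tgt <- array(labels %in% codes, dim = d)
  out <- array(FALSE, dim = d)
  out[1:(d[1]-1), , ] <- out[1:(d[1]-1), , ] | tgt[2:d[1], , ]
  out[2:d[1], , ]     <- out[2:d[1], , ]     | tgt[1:(d[1]-1), , ]
  out[, 1:(d[2]-1), ] <- out[, 1:(d[2]-1), ] | tgt[, 2:d[2], ]
  out[, 2:d[2], ]     <- out[, 2:d[2], ]     | tgt[, 1:(d[2]-1), ]
  out[, , 1:(d[3]-1)] <- out[, , 1:(d[3]-1)] | tgt[, , 2:d[3]]
  out[, , 2:d[3]]     <- out[, , 2:d[3]]     | tgt[, , 1:(d[3]-1)]
  mask & out
}

#' Check the CSF outflow connectivity contract of an atlas
#'
#' Verifies that a single 6-connected component of the CSF compartments
#' (ventricles, cisterns, subarachnoid spaces) touches the hippocampus
#' border, the nasal turbinates, and the spinal nerves — the path along
#' which tracer leaves the brain.
#'
#' @param atlas A `cryoclear_atlas`.
#' @return `TRUE`/`FALSE`.
#' @export
csf_path_connected <- function(atlas) {
  lab <- atlas$labels
  csf <- array(lab %in% structure_code(csf_structures()), dim = dim(lab))
  comp <- label_components6(csf)
  hip <- adjacent_to(csf, lab, structure_code("hippocampus"))
  nose <- adjacent_to(csf, lab, structure_code("nasal_turbinates"))
  sn <- adjacent_to(csf, lab, structure_code("spinal_nerves"))
  comps_hip <- unique(comp[hip])
  any(vapply(comps_hip, function(k) {
    any(comp[nose] == k) && any(comp[sn] == k)
  }, logical(1)))
}

#' @export
print.cryoclear_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "cryoclear_atlas: %d x %d x %d voxels at %g um (scale %.2f)\n",
    d[1], d[2], d[3], x$pitch_um, x$scale))
  cat(sprintf("  brain parenchyma: %.1f mm3\n", brain_volume(x)))
  invisible(x)
}
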