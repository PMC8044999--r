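#' Deposit an infused tracer bolus into the phantom
#'
#' Models the infusion as instantaneous filling of the extracellular space of
#' a spherical tissue region around the injection site: an infusate volume
#' `V` wets a tissue region of volume `V / ecs_fraction` (1.0 uL at an ECS
#' fraction of 0.2 wets 5.0 mm3 of tissue). Concentrations are stored as
#' bulk (tissue-homogenised) values, so the deposited bulk concentration is
#' chosen such that the grid-summed mass equals exactly
#' `total_volume x concentration`. The infused volume is scaled by the
#' phantom's `scale^3` so that scaled-down phantoms receive a geometrically
#' consistent bolus.
#'
#' @param atlas A `cryoclear_atlas`.
#' @param infusion An [infusion_spec()].
#' @param tracer A [tracer_spec()].
#' @param site_jitter_mm Optional `c(z, y, x)` perturbation of the injection
#'   site (full-scale mm), e.g. per-mouse targeting variability.
#' @return A `cryoclear_field`: list with `concentration` (3D array, mg/mL
#'   bulk), `tracer`, `pitch_um`, `time_min` (0), `mass_ug`,
#'   `absorbed_ug` (0).
#' @export
simulate_infusion <- function(atlas, infusion, tracer, site_jitter_mm = c(0, 0, 0)) {
  stopifnot(inherits(atlas, "cryoclear_atlas"),
            inherits(infusion, "cryoclear_infusion_spec"),
            inherits(tracer, "cryoclear_tracer_spec"))
  s <- atlas$scale
  h <- atlas$pitch_um / 1000
  d <- dim(atlas$labels)
  sp <- atlas$spec$structure_params
  ecs <- atlas$spec$ecs_fraction

  center_mm <- (sp[[paste0(infusion$site_structure, "_center")]] +
                  infusion$site_offset_mm + site_jitter_mm) * s
  # voxel index of the site
  idx <- round((center_mm - atlas$origin_mm) / h + 0.5)
  if (any(idx < 1) || any(idx > d)) stop("infusion site outside the grid")
  site_label <- atlas$labels[idx[1], idx[2], idx[3]]
  brain_codes <- structure_code(brain_structures())
  if (!site_label %in% brain_codes) {
    stop("infusion site lies outside the brain label (label code ",
         site_label, ")")
  }

  vol_ul <- infusion$total_volume_ul * s^3
  conc <- array(0, dim = d)
  mass_ug <- vol_ul * tracer$concentration_mg_ml  # uL x mg/mL = ug
  if (vol_ul > 0) {
    wet_mm3 <- vol_ul / ecs
    r_mm <- (3 * wet_mm3 / (4 * pi))^(1 / 3)
    zc <- atlas$origin_mm[1] + (seq_len(d[1]) - 0.5) * h
    yc <- atlas$origin_mm[2] + (seq_len(d[2]) - 0.5) * h
    xc <- atlas$origin_mm[3] + (seq_len(d[3]) - 0.5) * h
    dist2 <- outer(outer((zc - center_mm[1])^2, (yc - center_mm[2])^2, `+`),
                   (xc - center_mm[3])^2, `+`)
    inside <- dist2 < r_mm^2
    nvox <- sum(inside)
    if (nvox == 0) stop("wetted region contains no voxels at this pitch")
    # uniform bulk concentration chosen so grid summation returns the mass
    conc[inside] <- mass_ug / (nvox * h^3)  # ug / mm3 = mg/mL
  }
  structure(list(
    concentration = conc,
    tracer = tracer,
    pitch_um = atlas$pitch_um,
    time_min = 0,
    mass_ug = mass_ug,
    absorbed_ug = 0
  ), class = "cryoclear_field")
}

#' Total tracer mass on the grid, in ug
#' @param field A `cryoclear_field`.
#' @export
field_mass <- function(field) {
  h <- field$pitch_um / 1000
  sum(field$concentration) * h^3
}

# Per-voxel diffusivity map (um2/s) for a tracer on an atlas.
diffusivity_map <- function(atlas, tracer) {
  lab <- atlas$labels
  Dv <- numeric(nrow(atlas_labels()) + 1)  # indexed by label code + 1
  labs <- atlas_labels()
  Dpar <- tracer$diffusivity_um2_s
  for (i in seq_len(nrow(labs))) {
    st <- labs$structure[i]
    Dv[labs$label[i] + 1] <-
      if (st %in% c("background", "bone", "blood_vessel")) 0
      else if (labs$compartment[i] == "csf") tracer$csf_dispersion_um2_s
      else if (st == "muscle") 0.3 * Dpar
      else Dpar  # parenchyma, cord, nerves, turbinates
  }
  array(Dv[lab + 1L], dim = dim(lab))
}

# Directed CSF compartment graph: tracer is carried from the hippocampus
# border into the interpeduncular cistern, on through the subarachnoid
# spaces toward the nasal turbinates and down the spinal canal to the
# spinal nerves; the ventricular chain drains via the fourth ventricle.
csf_graph_edges <- function() {
  list(
    c("hippocampus", "interpeduncular_cistern"),
    c("interpeduncular_cistern", "sas_cerebrum"),
    c("interpeduncular_cistern", "sas_cerebellum"),
    c("sas_cerebrum", "nasal_turbinates"),
    c("sas_cerebrum", "sas_cerebellum"),
    c("sas_cerebellum", "sas_spinal"),
    c("sas_spinal", "spinal_cord"),
    c("sas_spinal", "spinal_nerves"),
    c("spinal_cord", "spinal_nerves"),
    c("lateral_ventricle", "third_ventricle"),
    c("third_ventricle", "fourth_ventricle"),
    c("fourth_ventricle", "sas_cerebellum")
  )
}

# 0-based flat indices of 6-adjacent voxel pairs (src in label A, dst in
# label B) for every edge of the compartment graph.
compartment_pairs <- function(atlas) {
  lab <- atlas$labels
  d <- dim(lab)
  strides <- c(1L, d[1], d[1] * d[2])
  src_all <- integer(0); dst_all <- integer(0)
  for (edge in csf_graph_edges()) {
    a <- structure_code(edge[1]); b <- structure_code(edge[2])
    inA <- which(lab == a)
    if (length(inA) == 0) next
    ci <- arrayInd(inA, d)
    for (axis in 1:3) for (step in c(-1L, 1L)) {
      ok <- ci[, axis] + step >= 1 & ci[, axis] + step <= d[axis]
      nb <- inA[ok] + step * strides[axis]
      hit <- lab[nb] == b
      src_all <- c(src_all, inA[ok][hit] - 1L)
      dst_all <- c(dst_all, nb[hit] - 1L)
    }
  }
  list(src = src_all, dst = dst_all)
}

# Upwind bulk-flow faces along the cutting axis within the subarachnoid
# spaces: rostral SAS drains toward the nose (+z), the cerebellar and
# spinal SAS toward the spine (-z). Returned as 0-based (src, dst) voxel
# pairs with the face Courant number v*dt/h as transfer fraction.
csf_flow_pairs <- function(atlas, flow_um_s, dt_s) {
  lab <- atlas$labels
  d <- dim(lab)
  dir_of <- c(sas_cerebrum = +1L, sas_cerebellum = -1L, sas_spinal = -1L)
  src_all <- integer(0); dst_all <- integer(0)
  for (st in names(dir_of)) {
    cd <- structure_code(st)
    inA <- which(lab == cd)
    if (length(inA) == 0) next
    ci <- arrayInd(inA, d)
    step <- dir_of[[st]]
    ok <- ci[, 1] + step >= 1 & ci[, 1] + step <= d[1]
    nb <- inA[ok] + step  # axis-1 stride is 1
    hit <- lab[nb] == cd  # drift only between voxels of the same SAS label
    src_all <- c(src_all, inA[ok][hit] - 1L)
    dst_all <- c(dst_all, nb[hit] - 1L)
  }
  frac <- flow_um_s * atlas$scale * dt_s / atlas$pitch_um
  list(src = src_all, dst = dst_all, frac = frac)
}

#' Stability bound for the explicit diffusion scheme
#'
#' Maximum stable time step `h^2 / (6 * Dmax)` of the 6-neighbour explicit
#' scheme for the fastest diffusivity present.
#'
#' @param atlas A `cryoclear_atlas`.
#' @param tracer A [tracer_spec()].
#' @return Time step bound in seconds.
#' @export
spread_dt_bound <- function(atlas, tracer) {
  dmax <- max(tracer$diffusivity_um2_s, tracer$csf_dispersion_um2_s,
              0.3 * tracer$diffusivity_um2_s)
  atlas$pitch_um^2 / (6 * dmax)
}

#' Simulate tracer spread through the phantom
#'
#' Advances a tracer field by explicit finite-difference diffusion with
#' per-compartment diffusivity (parenchymal diffusivity in brain tissue,
#' a faster effective dispersion in CSF compartments, zero in bone and
#' embedding medium) plus first-order advective transfer along the directed
#' CSF compartment graph (see the package vignette). The outer boundary is
#' closed; mass is conserved exactly unless exit-compartment absorption is
#' enabled, in which case absorbed mass is book-kept on the returned field.
#'
#' @param field A `cryoclear_field` from [simulate_infusion()].
#' @param atlas The `cryoclear_atlas` the field lives on.
#' @param tracer A [tracer_spec()]; defaults to the field's tracer.
#' @param duration_min Simulated time in minutes.
#' @param dt_s Time step in seconds; defaults to 0.9 x the stability bound.
#'   A value above the bound is an error naming the bound.
#' @param absorb_exits Enable first-order removal in the exit compartments
#'   (nasal turbinates, spinal nerves).
#' @param absorb_rate_s Absorption rate (1/s) when enabled.
#' @param csf_flow_um_s Bulk CSF flow speed along the subarachnoid spaces
#'   (um/s at full scale; scaled with the phantom). Rostral SAS drains
#'   toward the nose, cerebellar/spinal SAS toward the spinal nerves. Set 0
#'   for pure diffusion plus compartment-graph transfer.
#' @return The advanced `cryoclear_field` (time and absorbed mass updated).
#' @export
simulate_spread <- function(field, atlas, tracer = field$tracer,
                            duration_min, dt_s = NULL,
                            absorb_exits = FALSE, absorb_rate_s = 0.002,
                            csf_flow_um_s = 8) {
  stopifnot(inherits(field, "cryoclear_field"),
            inherits(atlas, "cryoclear_atlas"))
  if (!all(dim(field$concentration) == dim(atlas$labels))) {
    stop("field and atlas grids are not congruent")
  }
  if (duration_min < 0) stop("duration must be non-negative")
  bound <- spread_dt_bound(atlas, tracer)
  if (is.null(dt_s)) dt_s <- 0.9 * bound
  if (dt_s > bound + 1e-12) {
    stop("unstable time step: dt = ", signif(dt_s, 4),
         " s exceeds the explicit-scheme stability bound h^2/(6*Dmax) = ",
         signif(bound, 4), " s")
  }
  total_s <- duration_min * 60
  nsteps <- ceiling(total_s / dt_s)
  if (nsteps == 0) return(field)
  dt_s <- total_s / nsteps  # hit the requested duration exactly

  dmap <- diffusivity_map(atlas, tracer)
  pairs <- compartment_pairs(atlas)
  graph_frac <- tracer$csf_transport_rate_s * dt_s
  if (graph_frac * 6 >= 1) {
    stop("csf_transport_rate too large for this time step (would drain ",
         "source voxels): rate * dt * 6 must stay below 1")
  }
  src <- pairs$src; dst <- pairs$dst
  frac <- rep(graph_frac, length(src))
  if (csf_flow_um_s > 0) {
    flow <- csf_flow_pairs(atlas, csf_flow_um_s, dt_s)
    if (flow$frac >= 0.5) stop("CSF flow Courant number too large; reduce dt")
    src <- c(src, flow$src); dst <- c(dst, flow$dst)
    frac <- c(frac, rep(flow$frac, length(flow$src)))
  }
  res <- transport_run_cpp(
    as.numeric(field$concentration), as.numeric(dmap),
    as.integer(dim(field$concentration)),
    dt_s, atlas$pitch_um, as.integer(nsteps),
    as.integer(src), as.integer(dst), as.numeric(frac),
    if (absorb_exits) {
      as.integer(which(atlas$labels %in%
        structure_code(c("nasal_turbinates", "spinal_nerves"))) - 1L)
    } else integer(0),
    if (absorb_exits) absorb_rate_s * dt_s else 0
  )
  h <- field$pitch_um / 1000
  field$concentration <- res$conc
  field$time_min <- field$time_min + duration_min
  field$absorbed_ug <- field$absorbed_ug + res$absorbed * h^3
  field
}

#' Volume of the field above a concentration threshold, in mm3
#'
#' @param field A `cryoclear_field`.
#' @param threshold Bulk concentration threshold (mg/mL).
#' @export
field_volume_above <- function(field, threshold) {
  h <- field$pitch_um / 1000
  sum(field$concentration >= threshold) * h^3
}
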