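#' Phantom specification
#'
#' Describes the stylized labeled mouse used by the synthetic-data generator:
#' a primitive assembly (ellipsoids, slabs, cylinders, shells) laid out along
#' the cutting axis from thorax to nose. Geometry parameters are stored at
#' full scale in mm and scaled uniformly by `scale`; the default full-scale
#' assembly is calibrated so the brain parenchyma encloses 453.2 mm3 and the
#' hippocampus 25.7 mm3 (the reference volumes for the mouse strain studied),
#' and the extracellular-space fraction defaults to 0.2.
#'
#' The default rendering/simulation pitch is a desk-scale 90 um (an isotropic
#' grid coarser than the instrument's native 15 um in-plane pitch); the full
#' 15 um in-plane geometry is available by setting `pitch_um = 45` and
#' `render_upsample = 3` on a machine with memory to match.
#'
#' @param scale Uniform geometric scale factor (1 = full-size mouse).
#' @param pitch_um Isotropic voxel pitch of the simulation grid, in um.
#' @param ecs_fraction Extracellular-space volume fraction, in (0, 1).
#' @param seed Integer seed recorded with the phantom.
#' @param structure_params Named list of geometric primitives; defaults to
#'   [default_structure_params()]. Radii and lengths are in mm at full scale.
#' @param margin_mm Padding added around the assembly when sizing the grid.
#' @return A `cryoclear_phantom_spec` list.
#' @export
phantom_spec <- function(scale = 1, pitch_um = 90, ecs_fraction = 0.2,
                         seed = 1L, structure_params = default_structure_params(),
                         margin_mm = 0.4) {
  if (ecs_fraction <= 0 || ecs_fraction >= 1) {
    stop("ecs_fraction must lie strictly between 0 and 1")
  }
  if (scale <= 0 || pitch_um <= 0) stop("scale and pitch must be positive")
  validate_structure_params(structure_params)
  sp <- structure_params
  # grid extents from the envelope, scaled, plus margin
  zmax <- sp$domain_length_mm * scale + margin_mm
  half_y <- (sp$envelope_semi_y + 0.2) * scale + margin_mm
  half_x <- (sp$envelope_semi_x + 0.2) * scale + margin_mm
  h <- pitch_um / 1000
  grid_shape <- c(ceiling(zmax / h), 2 * ceiling(half_y / h) + 1,
                  2 * ceiling(half_x / h) + 1)
  structure(list(
    scale = scale,
    pitch_um = pitch_um,
    ecs_fraction = ecs_fraction,
    seed = as.integer(seed),
    structure_params = sp,
    grid_shape = as.integer(grid_shape),
    origin_mm = c(0, -ceiling(half_y / h) * h, -ceiling(half_x / h) * h)
  ), class = "cryoclear_phantom_spec")
}

validate_structure_params <- function(sp) {
  num_fields <- unlist(sp[vapply(sp, is.numeric, logical(1))])
  if (any(!is.finite(num_fields))) stop("non-finite geometry parameter")
  radii <- unlist(sp[grepl("(semi|radius|radii|width|length)", names(sp))])
  if (any(radii <= 0)) {
    stop("configuration error: degenerate geometry (zero or negative ",
         "radius/length) in structure parameters")
  }
  invisible(sp)
}

#' Default geometric primitives of the stylized mouse
#'
#' All coordinates in mm at full scale, in the phantom frame: axis 1 (`z`)
#' is the cutting axis with 0 at the thorax end increasing toward the nose;
#' axes 2 (`y`, ventral negative) and 3 (`x`, left-right) are in-plane and
#' centred on the midline. The brain lateral semi-axis is calibrated so the
#' painted parenchyma volume lands on 453.2 mm3 after the internal CSF
#' spaces are carved out.
#'
#' @return Named list of primitive parameters.
#' @export
default_structure_params <- function() {
  list(
    domain_length_mm = 24,
    envelope_semi_y = 4.9,
    envelope_semi_x = 5.5,
    # brain ellipsoid (rest_of_brain base coat)
    brain_center = c(13, 0, 0),
    brain_semi = c(6.0, 4.0, 4.64),
    # concentric solids painted before the brain: CSF mantle and skull
    sas_thickness = 0.25,
    bone_thickness = 0.30,
    sas_split_z = 11,              # rostral of this: cerebral SAS
    # cortex: outer shell of the brain, dorsal
    cortex_inner_scale = 0.80,
    cortex_min_y = -0.5,
    cortex_max_z = 17.0,
    # deep structures
    striatum_center = c(14.8, -0.6, 0), striatum_semi = c(1.1, 0.9, 1.6),
    olfactory_center = c(17.6, 0.2, 0), olfactory_semi = c(0.9, 0.8, 1.1),
    hippocampus_center = c(12, 0.3, 0), hippocampus_semi = c(2.4, 1.4, 1.96),
    # internal CSF
    lateral_ventricle_center_z = 13, lateral_ventricle_center_y = 1.2,
    lateral_ventricle_center_x = 1.2,
    lateral_ventricle_semi = c(0.9, 0.4, 1.3),
    third_ventricle_box_z = c(10.8, 13.4),
    third_ventricle_box_y = c(-2.0, -1.2),
    third_ventricle_half_width = 0.15,
    aqueduct_z = c(8.6, 10.9), aqueduct_y = -0.8, aqueduct_radius = 0.25,
    fourth_ventricle_center = c(8.6, -1.1, 0),
    fourth_ventricle_semi = c(0.6, 0.5, 0.5),
    ipc_center = c(12, -2.5, 0), ipc_semi = c(0.8, 1.5, 0.6),
    # nose
    nose_z = c(19.0, 24.0), nose_base_radius = 2.5, nose_tip_radius = 0.5,
    turbinate_z = c(19.5, 23.0), turbinate_x = c(-1.3, -0.5, 0.5, 1.3),
    turbinate_half_width = 0.15,
    nasal_channel_z = c(18.8, 20.2), nasal_channel_x = 0.35,
    nasal_channel_radius = 0.30,
    # spine
    cord_z = c(0, 7.8), cord_y = -0.6, cord_radius = 0.5,
    spinal_sas_outer = 0.85, spinal_sas_z = c(0.8, 7.8),
    nerve_z = c(2.0, 3.5, 5.0, 6.5), nerve_radius = 0.22,
    nerve_x_reach = 2.8,
    # vessels (autofluorescent, in the neck soft tissue)
    vessel_z = c(1, 8), vessel_y = 2.0, vessel_x = 1.8,
    vessel_radius = 0.25,
    # neck / thorax soft-tissue envelope
    neck_z = c(0, 8.5), neck_radius = 3.4
  )
}

#' Tracer specification
#'
#' Physical and imaging parameters of a fluorescently labeled dextran. The
#' default effective parenchymal diffusivity follows a Stokes-Einstein-style
#' `MW^(-1/3)` scaling anchored at 70 um2/s for the 3 kDa dextran (free
#' diffusivity reduced by tissue tortuosity); CSF transport is
#' size-independent and dominated by dispersion/mixing, so `csf_dispersion`
#' is an absolute coefficient shared by both tracers.
#'
#' @param name `"texas_red_3k"` or `"fluorescein_500k"`, or a custom label.
#' @param molecular_weight_kda Molecular weight in kDa.
#' @param concentration_mg_ml Infusate concentration (default 30 mg/mL).
#' @param diffusivity_um2_s Effective parenchymal diffusivity; default scales
#'   as `70 * (mw / 3)^(-1/3)`.
#' @param csf_dispersion_um2_s Effective dispersion coefficient in CSF
#'   compartments.
#' @param csf_transport_rate_s Per-boundary-pair advective transfer rate
#'   along the directed CSF compartment graph, in 1/s.
#' @param channel Imaging channel (`"red"`, `"green"`).
#' @return A `cryoclear_tracer_spec` list.
#' @export
tracer_spec <- function(name = c("texas_red_3k", "fluorescein_500k"),
                        molecular_weight_kda = NULL,
                        concentration_mg_ml = 30,
                        diffusivity_um2_s = NULL,
                        csf_dispersion_um2_s = 1500,
                        csf_transport_rate_s = 0.02,
                        channel = NULL) {
  if (is.character(name) && length(name) > 1) name <- match.arg(name)
  defaults <- list(
    texas_red_3k = list(mw = 3, channel = "red"),
    fluorescein_500k = list(mw = 500, channel = "green")
  )
  if (name %in% names(defaults)) {
    if (is.null(molecular_weight_kda)) molecular_weight_kda <- defaults[[name]]$mw
    if (is.null(channel)) channel <- defaults[[name]]$channel
  }
  if (is.null(molecular_weight_kda) || is.null(channel)) {
    stop("molecular_weight_kda and channel are required for custom tracers")
  }
  if (is.null(diffusivity_um2_s)) {
    diffusivity_um2_s <- 70 * (molecular_weight_kda / 3)^(-1 / 3)
  }
  if (diffusivity_um2_s < 0) stop("diffusivity must be non-negative")
  structure(list(
    name = name,
    molecular_weight_kda = molecular_weight_kda,
    concentration_mg_ml = concentration_mg_ml,
    diffusivity_um2_s = diffusivity_um2_s,
    csf_dispersion_um2_s = csf_dispersion_um2_s,
    csf_transport_rate_s = csf_transport_rate_s,
    channel = channel
  ), class = "cryoclear_tracer_spec")
}

#' Infusion specification
#'
#' @param total_volume_ul Infused volume in uL (default 1.0 at full scale;
#'   scaled by `scale^3` when a phantom scale is applied downstream).
#' @param rate_ul_min Pump rate in uL/min (default 0.1).
#' @param duration_min Infusion duration; must satisfy
#'   `rate * duration = total_volume`.
#' @param site_structure Target structure (default the hippocampus).
#' @param site_offset_mm Offset from the structure centroid, in mm
#'   (full scale), `c(z, y, x)`.
#' @return A `cryoclear_infusion_spec` list.
#' @export
infusion_spec <- function(total_volume_ul = 1.0, rate_ul_min = 0.1,
                          duration_min = total_volume_ul / rate_ul_min,
                          site_structure = "hippocampus",
                          site_offset_mm = c(0, 0, 0.6)) {
  if (abs(rate_ul_min * duration_min - total_volume_ul) > 1e-9) {
    stop("rate x duration must equal total_volume")
  }
  structure(list(
    total_volume_ul = total_volume_ul,
    rate_ul_min = rate_ul_min,
    duration_min = duration_min,
    site_structure = site_structure,
    site_offset_mm = site_offset_mm
  ), class = "cryoclear_infusion_spec")
}

#' Acquisition specification
#'
#' Camera and exposure model of the cryomicrotome: 16-bit intensities,
#' per-channel exposures (6000 ms for the green/fluorescein channel, 8000 ms
#' for the red/Texas Red channel, 500 ms for the reflection channel), a
#' linear gain from concentration x exposure to counts, per-structure
#' autofluorescence baselines (elevated in the short-wavelength channel for
#' nasal and vessel-like structures), additive Gaussian read noise, and
#' stuck-pixel camera defects.
#'
#' @param exposure_ms Named per-channel exposures.
#' @param gain Intensity counts per (mg/mL x ms).
#' @param noise_sd Gaussian read-noise SD in counts.
#' @param n_stuck Number of stuck (hot) pixels planted on the sensor;
#'   positions are drawn from the rendering seed, values are `stuck_value`.
#' @param stuck_value Count value of stuck pixels.
#' @param stuck_pixels Optional explicit data frame (`row`, `col`, `value`)
#'   overriding random placement.
#' @param render_upsample In-plane upsampling factor from the simulation grid
#'   to the rendered pixel grid (3 emulates 15 um pixels under 45 um slices).
#' @param autofluorescence Per-structure, per-channel baseline counts;
#'   defaults to [default_autofluorescence()].
#' @return A `cryoclear_acquisition_spec` list.
#' @export
acquisition_spec <- function(exposure_ms = c(green = 6000, red = 8000,
                                             reflection = 500),
                             gain = 6, noise_sd = 50,
                             n_stuck = 5L, stuck_value = 65535,
                             stuck_pixels = NULL,
                             render_upsample = 3L,
                             autofluorescence = default_autofluorescence()) {
  if (any(exposure_ms <= 0)) stop("exposures must be positive")
  structure(list(
    bit_depth = 16L,
    exposure_ms = exposure_ms,
    gain = gain,
    noise_sd = noise_sd,
    n_stuck = as.integer(n_stuck),
    stuck_value = stuck_value,
    stuck_pixels = stuck_pixels,
    render_upsample = as.integer(render_upsample),
    autofluorescence = autofluorescence
  ), class = "cryoclear_acquisition_spec")
}

#' Default autofluorescence baselines (counts) per structure and channel
#'
#' The short-wavelength (green) channel carries strong endogenous
#' autofluorescence in the nasal turbinates and blood vessels; the red
#' channel is comparatively clean. The reflection channel encodes tissue
#' contours.
#'
#' @return A matrix with one row per atlas structure and columns
#'   `green`, `red`, `reflection`.
#' @export
default_autofluorescence <- function() {
  lab <- atlas_labels()
  af <- matrix(0, nrow = nrow(lab), ncol = 3,
               dimnames = list(lab$structure, c("green", "red", "reflection")))
  af["background", ] <- c(30, 20, 100)
  parench <- c(brain_structures(), "spinal_cord")
  af[parench, "green"] <- 350
  af[parench, "red"] <- 150
  af[parench, "reflection"] <- 20000
  af["spinal_nerves", ] <- c(380, 160, 18000)
  af["muscle", ] <- c(300, 140, 18000)
  af["bone", ] <- c(250, 120, 25000)
  af["nasal_turbinates", ] <- c(3000, 350, 20000)
  af["blood_vessel", ] <- c(3000, 300, 18000)
  csf <- csf_structures()
  af[csf, "green"] <- 120
  af[csf, "red"] <- 80
  af[csf, "reflection"] <- 8000
  af
}
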