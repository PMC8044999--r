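test_that("full-scale anatomy hits the reference brain and hippocampus volumes", {
  atlas <- build_anatomy(phantom_spec())  # full-scale, 90 um grid
  bv <- brain_volume(atlas)
  expect_lt(abs(bv / 453.2 - 1), 0.02)
  hv <- atlas_volumes(atlas, "hippocampus")$volume_mm3
  expect_lt(abs(hv / 25.7 - 1), 0.05)

  # all 13 scored structures painted and non-empty
  vols <- atlas_volumes(atlas, scored_structures())
  expect_true(all(vols$n_voxels > 0))

  # CSF path from hippocampus border to both exit regions
  expect_true(csf_path_connected(atlas))

  # every voxel has exactly one label from the vocabulary
  expect_true(all(atlas$labels %in% atlas_labels()$label))

  # full-scale infusion: 1.0 uL at ECS 0.2 wets 5.0 mm3 +/- a voxel shell,
  # and grid summation returns exactly the infused mass of 30 ug
  f <- simulate_infusion(atlas, infusion_spec(), tracer_spec("texas_red_3k"),
                         site_jitter_mm = c(0, 0, 0))
  h <- atlas$pitch_um / 1000
  wet <- sum(f$concentration > 0) * h^3
  r <- (3 * 5 / (4 * pi))^(1 / 3)
  shell <- 4 * pi * r^2 * h
  expect_lt(abs(wet - 5.0), shell)
  expect_equal(field_mass(f), 30, tolerance = 1e-9)
})

test_that("scored-structure voxel volumes track the analytic primitive volumes", {
  atlas <- desk_atlas()
  s <- atlas$scale; h <- atlas$pitch_um / 1000
  sp <- atlas$spec$structure_params
  ell_vol <- function(semi) 4 / 3 * pi * prod(semi) * s^3
  # primitives painted late (uncarved): interpeduncular cistern, fourth
  # ventricle; tolerance is a one-voxel surface shell
  checks <- list(
    interpeduncular_cistern = sp$ipc_semi,
    fourth_ventricle = sp$fourth_ventricle_semi
  )
  for (st in names(checks)) {
    analytic <- ell_vol(checks[[st]])
    semi <- checks[[st]] * s
    # ellipsoid surface area (Thomsen approximation)
    p <- 1.6075
    area <- 4 * pi * ((semi[1]^p * semi[2]^p + semi[1]^p * semi[3]^p +
                         semi[2]^p * semi[3]^p) / 3)^(1 / p)
    measured <- atlas_volumes(atlas, st)$volume_mm3
    expect_lt(abs(measured - analytic), area * h,
              label = paste(st, "voxel-vs-analytic volume"))
  }
})

test_that("degenerate geometry is a configuration error", {
  sp <- default_structure_params()
  sp$fourth_ventricle_semi <- c(0, 0, 0)
  expect_error(phantom_spec(structure_params = sp), "degenerate")
  expect_error(phantom_spec(ecs_fraction = 0), "ecs_fraction")
  expect_error(phantom_spec(ecs_fraction = 1), "ecs_fraction")
})

test_that("infusion preconditions and degenerate volumes", {
  atlas <- mini_atlas()
  inf <- infusion_spec()
  expect_error(infusion_spec(total_volume_ul = 1, rate_ul_min = 0.1,
                             duration_min = 5),
               "rate x duration")
  # site pushed far outside the brain
  expect_error(simulate_infusion(atlas, infusion_spec(
    site_offset_mm = c(0, -12, 0)), tracer_spec("texas_red_3k")))
  # zero volume gives a zero field (rate 0 with duration 0 keeps the
  # rate-x-duration invariant)
  f0 <- simulate_infusion(atlas, infusion_spec(total_volume_ul = 0,
                                               rate_ul_min = 0,
                                               duration_min = 0),
                          tracer_spec("texas_red_3k"))
  expect_true(all(f0$concentration == 0))
})

test_that("zero diffusivity and zero transport leave the field unchanged", {
  atlas <- mini_atlas()
  tr <- tracer_spec("texas_red_3k", diffusivity_um2_s = 0,
                    csf_dispersion_um2_s = 0, csf_transport_rate_s = 0)
  f0 <- simulate_infusion(atlas, infusion_spec(), tr)
  f1 <- simulate_spread(f0, atlas, duration_min = 30, dt_s = 1,
                        csf_flow_um_s = 0)
  expect_identical(f1$concentration, f0$concentration)
})

test_that("mass is conserved on the closed domain over 90 simulated minutes", {
  atlas <- mini_atlas()
  tr <- tracer_spec("texas_red_3k")
  f0 <- simulate_infusion(atlas, infusion_spec(), tr)
  m0 <- field_mass(f0)
  f1 <- simulate_spread(f0, atlas, duration_min = 90)
  expect_lt(abs(field_mass(f1) / m0 - 1), 1e-6)
  expect_equal(f1$time_min, 90)
})

test_that("absorption book-keeping accounts for all mass", {
  atlas <- mini_atlas()
  tr <- tracer_spec("texas_red_3k")
  f0 <- simulate_infusion(atlas, infusion_spec(), tr)
  m0 <- field_mass(f0)
  f1 <- simulate_spread(f0, atlas, duration_min = 60, absorb_exits = TRUE)
  expect_gt(f1$absorbed_ug, 0)
  expect_lt(abs((field_mass(f1) + f1$absorbed_ug) / m0 - 1), 1e-6)
})

test_that("an unstable time step is refused, naming the bound", {
  atlas <- mini_atlas()
  tr <- tracer_spec("texas_red_3k")
  f0 <- simulate_infusion(atlas, infusion_spec(), tr)
  bound <- spread_dt_bound(atlas, tr)
  expect_error(simulate_spread(f0, atlas, duration_min = 1,
                               dt_s = bound * 1.5),
               "stability bound")
})

test_that("above-threshold spread volume is non-decreasing in diffusivity", {
  atlas <- mini_atlas()
  vols <- vapply(c(20, 70, 200), function(D) {
    tr <- tracer_spec("texas_red_3k", diffusivity_um2_s = D)
    f <- simulate_spread(simulate_infusion(atlas, infusion_spec(), tr),
                         atlas, tracer = tr, duration_min = 20)
    field_volume_above(f, 0.01)
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("rendering is deterministic and linear in exposure", {
  atlas <- mini_atlas()
  tr <- tracer_spec("texas_red_3k")
  f <- simulate_spread(simulate_infusion(atlas, infusion_spec(), tr),
                       atlas, duration_min = 5)
  acq <- acquisition_spec()
  s1 <- render_slices(list(texas_red_3k = f), atlas, acq, seed = 33L)
  s2 <- render_slices(list(texas_red_3k = f), atlas, acq, seed = 33L)
  expect_identical(s1$channels, s2$channels)  # bit-identical on re-run
  s3 <- render_slices(list(texas_red_3k = f), atlas, acq, seed = 34L)
  expect_false(identical(s1$channels$red, s3$channels$red))

  # zero concentration + zero autofluorescence + zero noise -> all zeros
  zero_af <- acquisition_spec(noise_sd = 0, n_stuck = 0,
                              autofluorescence = default_autofluorescence() * 0)
  empty <- f; empty$concentration[] <- 0
  sz <- render_slices(list(texas_red_3k = empty), atlas, zero_af, seed = 1L)
  expect_true(all(vapply(sz$channels$red, function(m) all(m == 0), logical(1))))

  # doubling the exposure doubles the tracer signal (below saturation)
  weak <- f; weak$concentration <- f$concentration * 1e-2
  a1 <- acquisition_spec(noise_sd = 0, n_stuck = 0,
                         autofluorescence = default_autofluorescence() * 0,
                         exposure_ms = c(red = 4000))
  a2 <- acquisition_spec(noise_sd = 0, n_stuck = 0,
                         autofluorescence = default_autofluorescence() * 0,
                         exposure_ms = c(red = 8000))
  r1 <- render_slices(list(texas_red_3k = weak), atlas, a1, seed = 1L)
  r2 <- render_slices(list(texas_red_3k = weak), atlas, a2, seed = 1L)
  m1 <- mean(unlist(r1$channels$red))
  m2 <- mean(unlist(r2$channels$red))
  expect_equal(m2 / m1, 2, tolerance = 0.01)
})

test_that("identical phantom spec and seed give identical atlases", {
  a1 <- build_anatomy(phantom_spec(scale = 0.35))
  expect_identical(a1$labels, mini_atlas()$labels)
})
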