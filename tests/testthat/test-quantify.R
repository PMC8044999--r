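# quantile oracle: type-7 interpolation computed by hand from the sorted
# sample, independent of stats::quantile
sorted_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  hpos <- (n - 1) * p + 1
  lo <- floor(hpos); hi <- ceiling(hpos)
  s[lo] + (hpos - lo) * (s[hi] - s[lo])
}

test_that("threshold calibration is percentile x safety factor of background voxels", {
  lab <- array(structure_code("rest_of_brain"), c(6, 6, 6))
  lab[1:3, , ] <- structure_code("muscle")
  lab[4, , ] <- structure_code("bone")

  # constant background value b with s = 1.1 gives exactly 1.1 b
  vol <- array(0, c(6, 6, 6)); vol[1:4, , ] <- 200
  expect_equal(estimate_threshold(vol, lab), 1.1 * 200)

  # Gaussian background: matches the hand-computed percentile to 1e-9
  set.seed(21)
  vol2 <- array(stats::rnorm(216, 300, 25), c(6, 6, 6))
  bg <- vol2[lab %in% structure_code(c("muscle", "bone"))]
  expect_equal(estimate_threshold(vol2, lab, q = 99.95, s = 1.1,
                                  background_labels = c("muscle", "bone")),
               1.1 * sorted_quantile(bg, 0.9995), tolerance = 1e-9)

  expect_error(estimate_threshold(vol, lab, background_labels = "striatum"),
               "empty")
  expect_error(estimate_threshold(vol, lab,
                                  background_labels = character(0)),
               "empty")
})

test_that("autofluorescent structures are excluded by the calibrated threshold", {
  # rendered phantom with hot nasal autofluorescence, no tracer anywhere
  atlas <- mini_atlas()
  empty <- structure(list(concentration = array(0, dim(atlas$labels)),
                          tracer = tracer_spec("fluorescein_500k"),
                          pitch_um = atlas$pitch_um, time_min = 0,
                          mass_ug = 0, absorbed_ug = 0),
                     class = "cryoclear_field")
  slices <- render_slices(list(fluorescein_500k = empty), atlas,
                          acquisition_spec(n_stuck = 0), seed = 4L)
  vol <- rescale_isotropic(slices, channel = "green")
  thr <- estimate_threshold(vol, atlas)
  mask <- segment_volume(vol, thr)
  nasal <- mask$mask[atlas$labels == structure_code("nasal_turbinates")]
  expect_equal(sum(nasal), 0L)
})

test_that("segmentation keeps exactly the voxels at or above the threshold", {
  set.seed(9)
  vol <- array(stats::runif(1000, 0, 100), c(10, 10, 10))
  thr <- 60
  k <- sum(vol >= thr)  # linear-scan oracle on the same fixture
  mask <- segment_volume(vol, thr)
  expect_equal(sum(mask$mask), k)
  expect_true(all(vol[mask$mask] >= thr))
  # boundary rule: equality is kept
  vol[1, 1, 1] <- thr
  expect_true(segment_volume(vol, thr)$mask[1, 1, 1])

  expect_true(all(segment_volume(vol + 1, 0)$mask))
  expect_false(any(segment_volume(array(0:65535, c(4, 4, 4)), 65536)$mask))
})

test_that("higher thresholds give nested masks and non-increasing volumes", {
  set.seed(10)
  vol <- array(stats::rexp(8000, 1 / 50), c(20, 20, 20))
  prev <- segment_volume(vol, 10)$mask
  for (thr in c(30, 60, 120, 250)) {
    cur <- segment_volume(vol, thr)$mask
    expect_true(all(!cur | prev))  # subset
    expect_lte(sum(cur), sum(prev))
    prev <- cur
  }
})

test_that("dispersion volume is voxel count times voxel volume, exactly", {
  m <- array(FALSE, c(10, 10, 10))
  expect_equal(dispersion_volume(m, pitch_um = 45)$volume_mm3, 0)
  m[sample(1000, 300)] <- TRUE
  m[1:10, 1, 1] <- TRUE
  d <- dispersion_volume(m, pitch_um = 45)
  expect_equal(d$volume_mm3, d$voxel_count * 0.045^3)
  m2 <- array(FALSE, c(10, 10, 10)); m2[1:10, 1:10, 1:10] <- TRUE
  expect_equal(dispersion_volume(m2, pitch_um = 45)$volume_mm3,
               1000 * 0.045^3)  # 0.091125
})

test_that("a voxelised sphere recovers the analytic volume within a voxel shell", {
  h <- 45; r_mm <- 0.5
  n <- 31
  cc <- (1:n - (n + 1) / 2) * h / 1000
  dist2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  m <- dist2 < r_mm^2
  vol <- dispersion_volume(m, pitch_um = h)$volume_mm3
  analytic <- 4 / 3 * pi * r_mm^3
  shell <- 4 * pi * r_mm^2 * (h / 1000)  # one-voxel surface shell
  expect_lt(abs(vol - analytic), shell)
})

test_that("meshes are watertight, correctly oriented, and volume-consistent", {
  # single interior voxel: topological sphere, chi = 2
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  mesh <- extract_mesh(m, pitch_um = 45)
  expect_equal(nrow(mesh$vertices), 8)
  expect_equal(nrow(mesh$faces), 12)
  expect_equal(mesh_euler_characteristic(mesh), 2)
  expect_true(mesh_is_watertight(mesh))
  expect_equal(mesh_volume(mesh), 0.045^3)

  # axis-aligned cuboid: enclosed volume is exact
  m2 <- array(FALSE, c(10, 8, 6)); m2[2:7, 2:5, 2:4] <- TRUE
  mesh2 <- extract_mesh(m2, pitch_um = 45)
  expect_true(mesh_is_watertight(mesh2))
  expect_equal(mesh_volume(mesh2), 6 * 4 * 3 * 0.045^3, tolerance = 1e-12)
  expect_equal(mesh_euler_characteristic(mesh2), 2)

  # sphere: mesh volume within 5% of the voxel-count volume
  h <- 45
  cc <- (1:21 - 11) * h / 1000
  dist2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  m3 <- dist2 < 0.4^2
  mesh3 <- extract_mesh(m3, pitch_um = h)
  vox <- dispersion_volume(m3, pitch_um = h)$volume_mm3
  expect_lt(abs(mesh_volume(mesh3) - vox) / vox, 0.05)

  expect_error(extract_mesh(array(FALSE, c(3, 3, 3)), pitch_um = 45),
               "empty")
})

test_that("optional component filtering removes small islands only when asked", {
  vol <- array(0, c(12, 12, 12))
  vol[2:6, 2:6, 2:6] <- 100   # big blob: 125 voxels
  vol[10, 10, 10] <- 100      # singleton island
  plain <- segment_volume(vol, 50)
  expect_equal(sum(plain$mask), 126L)
  filtered <- segment_volume(vol, 50, min_component = 5L)
  expect_equal(sum(filtered$mask), 125L)
})
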