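make_mask_atlas <- function() {
  # 8x8x8 toy label grid: hippocampus block, cortex block, third ventricle
  lab <- array(structure_code("rest_of_brain"), c(8, 8, 8))
  lab[1:4, 1:4, 1:4] <- structure_code("hippocampus")
  lab[5:8, 1:4, 1:4] <- structure_code("cortex")
  lab[5:8, 5:8, 1:4] <- structure_code("third_ventricle")
  lab
}

test_that("presence scoring counts mask voxels inside each label", {
  lab <- make_mask_atlas()
  m <- array(FALSE, dim(lab))
  m[2:3, 2:3, 2:3] <- TRUE  # fully inside hippocampus
  sc <- score_presence(m, lab)
  expect_equal(sc$present[sc$structure == "hippocampus"], 1L)
  expect_equal(sum(sc$present), 1L)

  expect_equal(sum(score_presence(array(FALSE, dim(lab)), lab)$present), 0L)

  # 1 voxel in cortex, 5 in the third ventricle, min_voxels = 2
  m2 <- array(FALSE, dim(lab))
  m2[5, 1, 1] <- TRUE
  m2[5:8, 5, 1] <- TRUE; m2[5, 6, 1] <- TRUE
  sc2 <- score_presence(m2, lab, min_voxels = 2L)
  expect_equal(sc2$n_voxels[sc2$structure == "cortex"], 1L)
  expect_equal(sc2$present[sc2$structure == "cortex"], 0L)
  expect_equal(sc2$n_voxels[sc2$structure == "third_ventricle"], 5L)
  expect_equal(sc2$present[sc2$structure == "third_ventricle"], 1L)
})

test_that("presence scoring is monotone in the mask", {
  lab <- make_mask_atlas()
  set.seed(5)
  m <- array(stats::runif(length(lab)) < 0.05, dim(lab))
  base <- score_presence(m, lab)
  m2 <- m
  m2[sample(which(!m), 40)] <- TRUE  # grow the mask
  grown <- score_presence(m2, lab)
  expect_true(all(grown$present >= base$present))
})

test_that("unknown structure labels are an error", {
  lab <- make_mask_atlas()
  m <- array(FALSE, dim(lab))
  expect_error(score_presence(m, lab, structures = "thalamus"),
               "unknown structure")
})

test_that("proportions are mouse means rounded to two decimals", {
  pres <- tidyr::expand_grid(
    mouse_id = sprintf("m%d", 1:7), structure = c("cortex", "hippocampus")
  ) |>
    dplyr::mutate(group = "10+80min", tracer = "texas_red_3k",
                  present = ifelse(structure == "hippocampus", 1L,
                                   as.integer(mouse_id != "m7")))
  pr <- tabulate_proportions(pres)
  expect_equal(pr$proportion[pr$structure == "cortex"], 0.86)  # 6 of 7
  expect_equal(pr$proportion[pr$structure == "hippocampus"], 1)
  # 2 of 3 and 0 of 3
  pres3 <- tibble::tibble(
    mouse_id = sprintf("m%d", 1:3), group = "10min", tracer = "t",
    structure = "cortex", present = c(1L, 1L, 0L))
  expect_equal(tabulate_proportions(pres3)$proportion, 0.67)
  pres0 <- dplyr::mutate(pres3, present = 0L)
  expect_equal(tabulate_proportions(pres0)$proportion, 0)
  # duplicates refused
  expect_error(tabulate_proportions(dplyr::bind_rows(pres3, pres3)),
               "duplicate")
})

test_that("count recovery inverts printed proportions and flags impossible cells", {
  pr <- tibble::tibble(
    structure = c("a", "b", "c"), tracer = "t",
    group = c("g3", "g7", "g3"),
    n = c(3L, 7L, 3L),
    proportion = c(0.86, 0.86, 0.14))
  ct <- counts_from_proportions(pr)
  # 0.86 with n = 7 -> 6; 0.14 with n = 3 is infeasible
  expect_equal(ct$count[2], 6L)
  expect_false(ct$inconsistent[2])
  expect_true(ct$inconsistent[3])
  expect_equal(counts_from_proportions(
    tibble::tibble(structure = "a", tracer = "t", group = "g",
                   n = 3L, proportion = 1))$count, 3L)
})

test_that("round-trip: proportions -> counts -> proportions is exact on the reference table", {
  ref <- reference_presence_proportions()
  ct <- counts_from_proportions(ref)
  ok <- !ct$inconsistent
  expect_equal(sum(!ok), 1L)  # exactly one infeasible printed cell
  back <- round(ct$count[ok] / ct$n[ok], 2)
  expect_equal(back, ct$proportion[ok])
})

test_that("count expansion builds a clustered long table with the right margins", {
  ct <- tibble::tibble(structure = c("a", "b", "a", "b"),
                       group = c("g0", "g0", "g1", "g1"),
                       count = c(1L, 2L, 3L, 0L), n = c(3L, 3L, 4L, 4L))
  long <- expand_counts_to_long(ct, group_levels = c("g0", "g1"))
  expect_equal(nrow(long), 14)
  expect_equal(sum(long$present), 6)
  expect_equal(unique(long$x[long$group == "g1"]), 1L)
  agg <- dplyr::count(long, structure, group, wt = present)
  expect_equal(agg$n, c(1, 3, 2, 0))
})
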