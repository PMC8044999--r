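#' Score per-structure tracer presence from a segmentation mask
#'
#' Deterministic replacement for observer-based presence/absence scoring: a
#' structure is scored present when at least `min_voxels` above-threshold
#' voxels fall inside its label. The default of 2 voxels prevents a single
#' noise voxel from scoring a structure.
#'
#' @param mask A `cryoclear_mask` (see [segment_volume()]) or a logical 3D
#'   array congruent with `atlas`.
#' @param atlas A `cryoclear_atlas` label volume (see [build_anatomy()]) or an
#'   integer 3D array of label codes.
#' @param min_voxels Minimum overlapping voxel count to call presence.
#' @param structures Structures to score; defaults to the 13 scored
#'   structures. Unknown names are an error.
#' @return A tibble with columns `structure`, `n_voxels` (overlap count), and
#'   `present` (0/1).
#' @export
score_presence <- function(mask, atlas, min_voxels = 2L,
                           structures = scored_structures()) {
  m <- if (inherits(mask, "cryoclear_mask")) mask$mask else mask
  lab <- if (inherits(atlas, "cryoclear_atlas")) atlas$labels else atlas
  stopifnot(is.logical(m) || all(m %in% c(0, 1)))
  if (!all(dim(m) == dim(lab))) stop("mask and atlas grids are not congruent")
  codes <- structure_code(structures)  # errors on unknown labels
  inside <- lab[m == TRUE]
  counts <- tabulate(match(inside, codes), nbins = length(codes))
  tibble::tibble(
    structure = structures,
    n_voxels = as.integer(counts),
    present = as.integer(counts >= min_voxels)
  )
}

#' Tabulate presence proportions per structure, group and tracer
#'
#' Collapses a long presence table (one record per mouse x structure x
#' tracer) into the per-cell proportion of positive mice, the layout used to
#' report multi-structure presence for a two-group, two-tracer cohort.
#'
#' @param presence A tibble with columns `mouse_id`, `group`, `tracer`,
#'   `structure`, `present` (0/1).
#' @param digits Decimals for the reported proportion (default 2).
#' @return A tibble with columns `structure`, `tracer`, `group`, `n`
#'   (mice in the cell), `n_present`, and `proportion` (rounded). Empty cells
#'   are absent from the output; an all-empty input is an error.
#' @export
tabulate_proportions <- function(presence, digits = 2) {
  req <- c("mouse_id", "group", "tracer", "structure", "present")
  if (!all(req %in% names(presence))) {
    stop("presence table must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(presence) == 0) stop("presence table is empty")
  dup <- presence |>
    dplyr::count(.data$mouse_id, .data$tracer, .data$structure) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) stop("duplicate (mouse, tracer, structure) records")
  presence |>
    dplyr::group_by(.data$structure, .data$tracer, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_present = sum(.data$present),
      proportion = round(mean(.data$present), digits),
      .groups = "drop"
    )
}

#' Recover integer positive counts from printed proportions
#'
#' Inverts 2-decimal presence proportions back to integer counts given the
#' group size: the count is the integer in `0..n` whose exact proportion is
#' nearest the printed value. Cells where even the nearest feasible count
#' deviates by more than `tol_prop` (default 0.01) are flagged as
#' inconsistent rather than silently resolved — e.g. a printed 0.14 under
#' n = 3, which no count can produce.
#'
#' @param proportions A tibble with columns `structure`, `tracer`, `group`,
#'   `proportion`, and either an `n` column or `n` supplied via the `n`
#'   argument as a named vector `c(group = n)`.
#' @param n Optional named integer vector of group sizes, used when the table
#'   has no `n` column.
#' @param tol_prop Maximum tolerated |count/n - proportion|.
#' @return The input with added columns `count` (integer) and `inconsistent`
#'   (logical flag).
#' @export
counts_from_proportions <- function(proportions, n = NULL, tol_prop = 0.01) {
  pr <- proportions
  if (!"n" %in% names(pr)) {
    if (is.null(n)) stop("supply group sizes via an `n` column or the `n` argument")
    pr$n <- unname(n[as.character(pr$group)])
    if (anyNA(pr$n)) stop("group size missing for some group")
  }
  if (any(pr$proportion < 0 | pr$proportion > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  nearest <- function(p, n) {
    cand <- 0:n
    dev <- abs(cand / n - p)
    k <- cand[which.min(dev)]
    c(k, min(dev))
  }
  hit <- t(mapply(nearest, pr$proportion, pr$n))
  pr$count <- as.integer(hit[, 1])
  pr$inconsistent <- hit[, 2] > tol_prop + 1e-12
  pr
}

#' Expand per-cell counts into a clustered long table of binary outcomes
#'
#' Builds the long (one row per mouse x structure) binary table that feeds
#' the GEE, assigning the positive outcomes of each structure to the
#' lowest-numbered mice of the group. The assignment of positives to specific
#' mice is arbitrary from a count table; it does not affect the GEE point
#' estimate (cluster-level covariate, equal cluster sizes) but does affect
#' the working correlation and robust SE.
#'
#' @param counts A tibble with columns `structure`, `group`, `count`, `n`
#'   (one tracer at a time).
#' @param group_levels Length-2 character vector giving the reference and
#'   exposed group, in that order (`x = 0` and `x = 1`).
#' @return A tibble with `mouse_id`, `group`, `x` (0/1), `structure`,
#'   `present`.
#' @export
expand_counts_to_long <- function(counts, group_levels = NULL) {
  if (is.null(group_levels)) group_levels <- sort(unique(counts$group))
  stopifnot(length(group_levels) == 2)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    gi <- match(r$group, group_levels) - 1L
    if (is.na(gi)) stop("unknown group: ", r$group)
    tibble::tibble(
      mouse_id = sprintf("%s_m%02d", r$group, seq_len(r$n)),
      group = r$group,
      x = gi,
      structure = r$structure,
      present = as.integer(seq_len(r$n) <= r$count)
    )
  })
  dplyr::bind_rows(rows)
}

#' Reference cohort presence proportions
#'
#' The per-structure presence proportions observed in the reference
#' two-tracer cryomicrotome cohort (3 mice sacrificed directly after a
#' 10-min infusion, 7 after an additional 80-min spreading period), shipped
#' as package data. These proportions are the input from which the reference
#' odds ratios are recomputed.
#'
#' @return A tibble with columns `structure`, `tracer`
#'   (`"fluorescein_500k"` / `"texas_red_3k"`), `group` (`"10min"` /
#'   `"10+80min"`), `n`, `proportion`.
#' @export
reference_presence_proportions <- function() {
  path <- system.file("extdata", "reference_presence_proportions.csv",
                      package = "cryoclear", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    structure = readr::col_character(),
                    tracer = readr::col_character(),
                    group = readr::col_character(),
                    n = readr::col_integer(),
                    proportion = readr::col_double()
                  ))
}
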