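# Shared fixtures for the suite. Everything is generated in code; the
# expensive default-cohort run is computed once per session and memoised.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale atlas shared by several tests.
desk_atlas <- function() {
  if (is.null(.fixture_env$desk_atlas)) {
    .fixture_env$desk_atlas <- build_anatomy(phantom_spec(scale = 0.5))
  }
  .fixture_env$desk_atlas
}

# Small atlas for fast transport/experiment contract tests.
mini_atlas <- function() {
  if (is.null(.fixture_env$mini_atlas)) {
    .fixture_env$mini_atlas <- build_anatomy(phantom_spec(scale = 0.35))
  }
  .fixture_env$mini_atlas
}

# Default cohort experiment (the study design at desk scale), run once.
default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- run_experiment(run_config(seed = 1L),
                                          verbose = FALSE)
  }
  .fixture_env$cohort
}

# Independent exact Mann-Whitney oracle: direct enumeration over
# assignments, computing U from pair comparisons (not ranks) and the
# doubled lower-tail p. Kept deliberately separate from the package's
# rank-based implementation.
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u1_of <- function(xs, ys) {
    sum(outer(xs, ys, `<`)) + 0.5 * sum(outer(xs, ys, `==`))
  }
  u1_obs <- u1_of(x, y)
  u_obs <- min(u1_obs, n1 * n2 - u1_obs)
  combos <- utils::combn(n1 + n2, n1)
  u1_all <- apply(combos, 2, function(idx) {
    u1_of(pooled[idx], pooled[-idx])
  })
  p1 <- mean(u1_all <= u_obs + 1e-9)
  list(u = u_obs, p = min(1, 2 * p1))
}

# Random small clustered binary tables with a cluster-level covariate and
# equal cluster sizes, avoiding separation and degenerate cells.
random_long_table <- function(seed, n_clusters_per_group = 3:5,
                              cluster_size = 4:8) {
  set.seed(seed)
  repeat {
    ng <- sample(n_clusters_per_group, 1)
    ns <- sample(cluster_size, 1)
    p0 <- stats::runif(1, 0.25, 0.75)
    p1 <- stats::runif(1, 0.25, 0.75)
    df <- dplyr::bind_rows(lapply(seq_len(2 * ng), function(i) {
      g <- as.integer(i > ng)
      tibble::tibble(
        mouse_id = sprintf("c%02d", i),
        x = g,
        present = stats::rbinom(ns, 1, if (g == 1) p1 else p0)
      )
    }))
    tab <- table(df$x, df$present)
    if (all(dim(tab) == c(2, 2)) && all(tab > 0)) return(df)
  }
}
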