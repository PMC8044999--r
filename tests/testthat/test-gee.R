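test_that("GEE point estimate equals the pooled odds ratio for cluster-level covariates", {
  for (seed in 1:10) {
    df <- random_long_table(seed)
    fit <- fit_gee_binary(df, y_col = "present", x_col = "x",
                          cluster_col = "mouse_id")
    tab <- table(factor(df$x, c(1, 0)), factor(df$present, c(1, 0)))
    oracle <- pooled_odds_ratio(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(fit$or, oracle, tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("swapping group labels inverts the odds ratio and preserves p", {
  df <- random_long_table(42)
  fit <- fit_gee_binary(df, y_col = "present", x_col = "x",
                        cluster_col = "mouse_id")
  df2 <- dplyr::mutate(df, x = 1L - x)
  fit2 <- fit_gee_binary(df2, y_col = "present", x_col = "x",
                         cluster_col = "mouse_id")
  expect_equal(fit2$or, 1 / fit$or, tolerance = 1e-8)
  expect_equal(fit2$p, fit$p, tolerance = 1e-8)
})

test_that("sandwich SE reduces to the model-based SE with singleton clusters", {
  set.seed(7)
  n <- 60
  df <- tibble::tibble(
    mouse_id = sprintf("s%03d", seq_len(n)),
    x = rep(c(0L, 1L), each = n / 2),
    present = stats::rbinom(n, 1, 0.3 + 0.3 * rep(c(0, 1), each = n / 2))
  )
  fit <- fit_gee_binary(df, y_col = "present", x_col = "x",
                        cluster_col = "mouse_id")
  expect_equal(unname(fit$se_robust), unname(fit$se_model), tolerance = 1e-8)
})

test_that("identical presence patterns in both groups give OR = 1", {
  pattern <- c(1, 1, 0, 1, 0, 0)
  df <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(mouse_id = sprintf("m%d", i),
                   x = as.integer(i > 3),
                   present = pattern)
  }))
  fit <- fit_gee_binary(df, y_col = "present", x_col = "x",
                        cluster_col = "mouse_id")
  expect_equal(fit$beta[[2]], 0, tolerance = 1e-8)
  expect_equal(fit$or, 1, tolerance = 1e-8)
})

test_that("complete separation and invalid designs are refused", {
  df <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(mouse_id = sprintf("m%d", i),
                   x = as.integer(i > 3),
                   present = if (i > 3) rep(1L, 4) else rep(c(0L, 1L), 2))
  }))
  expect_error(fit_gee_binary(df, y_col = "present", x_col = "x",
                              cluster_col = "mouse_id"),
               "separation")
  # covariate varying within a cluster
  df2 <- tibble::tibble(mouse_id = rep("m1", 4), x = c(0, 0, 1, 1),
                        present = c(0, 1, 0, 1))
  expect_error(fit_gee_binary(df2, y_col = "present", x_col = "x",
                              cluster_col = "mouse_id"),
               "within a cluster")
})

test_that("pooled odds ratio arithmetic and degenerate cells", {
  expect_equal(pooled_odds_ratio(80, 11, 23, 16), (80 * 16) / (11 * 23))
  expect_equal(pooled_odds_ratio(64, 27, 18, 21), (64 * 21) / (27 * 18))
  expect_equal(pooled_odds_ratio(1, 1, 1, 1), 1)
  expect_warning(res <- pooled_odds_ratio(5, 0, 3, 2), "undefined")
  expect_true(is.nan(res))
})

test_that("tidy and glance return well-formed tibbles", {
  df <- random_long_table(3)
  fit <- fit_gee_binary(df, y_col = "present", x_col = "x",
                        cluster_col = "mouse_id")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(tidy(fit, exponentiate = TRUE)$estimate[2], fit$or)
  gl <- glance(fit)
  expect_equal(gl$or, fit$or)
  expect_true(gl$converged)
})
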