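make_tiles <- function(n = 60) {
  tibble::tibble(
    mean = seq(1, 10, length.out = n),
    sd = sqrt(2 * seq(1, 10, length.out = n)),
    variance = 2 * seq(1, 10, length.out = n),
    cv = sqrt(2 * seq(1, 10, length.out = n)) / seq(1, 10, length.out = n),
    delta = 2
  )
}

test_that("mean-balanced sampling stratifies, filters, and reproduces", {
  set.seed(1)
  tiles <- tibble::tibble(mean = runif(1000, 0, 100), delta = 1)
  out <- mean_balanced_sample(tiles, n_strata = 10, per_stratum = 5, seed = 3)
  expect_equal(nrow(out), 50)
  expect_equal(sort(unique(out$stratum)), 1:10)
  out2 <- mean_balanced_sample(tiles, n_strata = 10, per_stratum = 5, seed = 3)
  expect_identical(out, out2)

  capped <- mean_balanced_sample(tiles, n_strata = 5, per_stratum = 3,
                                 mean_cap = 40, seed = 1)
  expect_true(all(capped$mean <= 40))

  tiles$valid <- rep(c(1, 0.5), length.out = nrow(tiles))
  filt <- mean_balanced_sample(tiles, n_strata = 5, per_stratum = 3,
                               valid_fraction_col = "valid", seed = 1)
  expect_true(all(filt$valid >= 0.75))

  sparse <- tibble::tibble(mean = c(1, 2, 99, 100), delta = 1)
  w <- capture_warnings(
    out <- mean_balanced_sample(sparse, n_strata = 10, per_stratum = 2, seed = 1)
  )
  expect_true(all(grepl("empty", w)))
  expect_equal(sort(unique(out$stratum)), c(1, 10))
})

test_that("analytic mean-form predictions follow the delta model", {
  tiles <- tibble::tibble(mean = c(1, 4), delta = 3)
  expect_equal(predict_measure_from_mean(tiles, "variance", bounds(lower = 0))$predicted,
               c(3, 12))
  expect_equal(predict_measure_from_mean(tiles, "sd", bounds(lower = 0))$predicted[2],
               sqrt(12))
  db <- tibble::tibble(mean = 50, delta = 0.1)
  expect_equal(predict_measure_from_mean(db, "variance", bounds(0, 100))$predicted,
               250)
  # cv uses the median of delta by default, sd/variance the mean
  skewed <- tibble::tibble(mean = c(2, 2, 2), delta = c(1, 1, 10))
  expect_equal(attr(predict_measure_from_mean(skewed, "cv", bounds(lower = 0)),
                    "delta_average"), "median")
  expect_equal(predict_measure_from_mean(skewed, "cv", bounds(lower = 0))$predicted,
               rep(sqrt(1 * 2) / 2, 3))
  expect_equal(predict_measure_from_mean(skewed, "variance", bounds(lower = 0))$predicted,
               rep(4 * 2, 3))
})

test_that("the null model predicts the across-tile average everywhere", {
  tiles <- tibble::tibble(mean = 1:3, sd = c(1, 2, 3))
  expect_equal(null_predict(tiles, "sd")$predicted, rep(2, 3))
  one <- tibble::tibble(mean = 1, sd = 5)
  expect_equal(null_predict(one, "sd")$predicted, 5)
})

test_that("paired t on squared errors matches hand arithmetic and is antisymmetric", {
  same <- compare_paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$t, same$p), c(0, 1))
  expect_true(same$exact_tie)

  # differences 1, 2, 3: t = 2 / (1 / sqrt(3))
  r <- compare_paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  # cross-check against the stats implementation
  tt <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(r$t, unname(tt$statistic))
  expect_equal(r$p, tt$p.value)

  swapped <- compare_paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swapped$t, -r$t)
  expect_equal(swapped$p, r$p)
})

test_that("the analytic model beats the null on mean-balanced gamma tiles", {
  prof <- sim_gamma_tiles(seed = 42)
  cmp <- bias_model_comparison(prof, bounds(lower = 0))
  expect_setequal(cmp$measure, c("sd", "variance", "cv"))
  expect_true(all(cmp$mse_analytic < cmp$mse_null))
  expect_true(all(cmp$p < 0.01))
  expect_equal(cmp$df, rep(nrow(prof) - 1, 3))
})

test_that("analytic-vs-null direction is stable across seeds", {
  wins <- vapply(1:20, function(s) {
    prof <- sim_gamma_tiles(n_tiles = 60, tile_size = 100, seed = s)
    cmp <- bias_model_comparison(prof, bounds(lower = 0))
    all(cmp$mse_analytic < cmp$mse_null)
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("equivalence test passes for delta and fails for mean-biased responses", {
  prof <- sim_gamma_tiles(n_tiles = 500, tile_size = 400, seed = 11)
  for (ref in c("sd", "variance", "cv")) {
    eq <- delta_negligibility_test(prof, ref, bounds(lower = 0))
    expect_true(eq$pass)
    expect_lt(abs(eq$delta_coef), eq$negligible_bound)
    # the reference measure itself is far outside its own negligible bound
    self <- delta_negligibility_test(prof, ref, bounds(lower = 0), response = ref)
    expect_false(self$pass)
    expect_equal(self$delta_coef, self$reference_coef)
  }
})

test_that("equivalence test rejects degenerate inputs", {
  tiles <- make_tiles()
  tiles$mean <- 5  # constant predictor
  expect_error(delta_negligibility_test(tiles, "variance", bounds(lower = 0)),
               "degenerate")
})
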