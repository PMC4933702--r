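test_that("pearson reproduces product-moment statistics", {
  # hand-checkable case; oracle: base cor.test / lm on the same vectors
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 2, 4)
  res <- pearson(x, y)
  expect_equal(res$r, 0.9233805, tolerance = 1e-6)
  expect_equal(res$r_squared, 0.8526316, tolerance = 1e-6)
  ct <- stats::cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value)
  fit <- stats::lm(y ~ x)
  expect_equal(res$slope, unname(coef(fit)[2]))
  expect_equal(res$intercept, unname(coef(fit)[1]))
})

test_that("pearson handles exact linear relations and their signs", {
  x <- 1:10
  res <- pearson(x, 2 * x + 1)
  expect_equal(res$r_squared, 1)
  expect_lt(res$p_value, 1e-12)
  expect_equal(pearson(x, -x)$r, -1)
})

test_that("pearson is symmetric and affine-invariant", {
  set.seed(4)
  x <- rnorm(20)
  y <- x + rnorm(20)
  a <- pearson(x, y)
  b <- pearson(y, x)
  expect_equal(a$r, b$r)
  expect_equal(a$p_value, b$p_value)
  shifted <- pearson(3 * x + 7, y)
  expect_equal(shifted$r, a$r)
  flipped <- pearson(-2 * x, y)
  expect_equal(flipped$r, -a$r)
})

test_that("pearson rejects degenerate input", {
  expect_error(pearson(1:4, rep(1, 4)), "zero-variance")
  expect_error(pearson(rep(2, 4), 1:4), "zero-variance")
  expect_error(pearson(1:4, 1:5), "equal length")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("tidy and glance return broom-shaped one-row tibbles", {
  res <- pearson(1:10, (1:10)^1.3)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_named(td, c("estimate", "statistic", "p.value", "parameter",
                     "slope", "intercept"))
  gl <- glance(res)
  expect_named(gl, c("r.squared", "p.value", "nobs"))
  expect_equal(gl$r.squared, res$r_squared)
  expect_equal(gl$nobs, 10L)
})

test_that("f_mp vs repeat-number correlation reproduces the reference ranges", {
  lee <- correlate_fmp_vs_ncag(40L, 53L)
  expect_equal(round(lee$r_squared, 3), 0.996)
  expect_lt(lee$p_value, 1e-13)
  expect_equal(lee$n, 14L)

  brinkman <- correlate_fmp_vs_ncag(39L, 50L)
  expect_equal(round(brinkman$r_squared, 3), 0.997)
  expect_lt(brinkman$p_value, 1e-12)

  expect_error(correlate_fmp_vs_ncag(40L, 41L), "at least 3")
  expect_error(
    correlate_fmp_vs_ncag(40L, 53L, kinetic_params(k_on = 0)),
    "zero-variance"
  )
})

test_that("onset vs f_mp correlation is strongly negative for declining data", {
  noise_free <- generate_onset_dataset(40L, 53L, noise_sd = 0,
                                       base_age = 60, slope = -3)
  res <- correlate_onset_vs_fmp(noise_free)
  expect_lt(res$r, -0.99)
  expect_lt(res$slope, 0)

  noisy <- generate_onset_dataset(40L, 53L, records_per_repeat = 1L,
                                  base_age = 60, slope = -3, noise_sd = 3,
                                  seed = 42)
  pinned <- correlate_onset_vs_fmp(noisy)
  expect_equal(pinned$r, -0.9727617, tolerance = 1e-6)
})

test_that("onset correlation validates its inputs", {
  ok <- generate_onset_dataset(40L, 45L, noise_sd = 0)
  bad_ncag <- ok
  bad_ncag$n_cag[1] <- 35L
  expect_error(correlate_onset_vs_fmp(bad_ncag), ">= 36")
  const <- ok
  const$onset_age_years <- 50
  expect_error(correlate_onset_vs_fmp(const), "zero-variance")
  expect_error(correlate_onset_vs_fmp(ok[1:2, ]), "at least 3")
  expect_error(correlate_onset_vs_fmp(tibble::tibble(n_cag = 40:45)),
               "lacks column")
})

test_that("per-repeat mean aggregation collapses replicates before correlating", {
  reps <- generate_onset_dataset(40L, 49L, records_per_repeat = 5L,
                                 noise_sd = 2, seed = 8)
  res <- correlate_onset_vs_fmp(reps, aggregate = "mean")
  expect_equal(res$n, 10L)
  manual <- dplyr::summarise(dplyr::group_by(reps, n_cag),
                             onset_age_years = mean(onset_age_years),
                             .groups = "drop")
  manual$f_mp <- fraction_misprocessed(manual$n_cag)
  expect_equal(res$r, pearson(manual$f_mp, manual$onset_age_years)$r)
})

test_that("slowdown sensitivity keeps strong correlations over the 2x-6x range", {
  scan <- sensitivity_scan(2:6, 40L, 53L)
  expect_equal(nrow(scan), 5L)
  # pinned values computed from the closed form f_mp = exp(beta (s-1) d) - 1
  expect_equal(scan$r_squared,
               c(0.9957402, 0.9832746, 0.9634858, 0.9376701, 0.9073336),
               tolerance = 1e-6)
  expect_true(all(diff(scan$r_squared) < 0)) # non-increasing in s
  expect_true(all(scan$r_squared >= 0.85))
  # s = 2 row consistent with the direct correlation
  expect_equal(scan$r_squared[1], correlate_fmp_vs_ncag(40L, 53L)$r_squared)
  # s = 1 -> f_mp identically zero -> zero-variance error propagates
  expect_error(sensitivity_scan(1, 40L, 53L), "zero-variance")
  expect_error(sensitivity_scan(c(0.5, 2)), ">= 1")
})

test_that("onset CSV reader consumes the declared dialect", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_onset_csv(generate_onset_dataset(40L, 45L, seed = 2), path)
  back <- read_onset_csv(path)
  expect_named(back, c("n_cag", "onset_age_years"))
  expect_type(back$n_cag, "integer")
})
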