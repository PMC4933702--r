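dflt <- kinetic_params()
win <- binding_window()

tau_for <- function(n, params = dflt, window = win) {
  tau_afb(build_schedule(build_construct(n), params$slowdown_s, params$tau_a),
          window)
}

test_that("tau_AFB over the default window matches the closed form", {
  expect_equal(tau_for(35L), 40)
  expect_equal(tau_for(45L), 30) # 10 fast + 10 slow codons in window
  expect_equal(tau_for(55L), 20)
  # closed form: 40 - clamp(n - 35, 0, 20) for the default window, s = 2
  for (n in 35:80) {
    expect_equal(tau_for(n), 40 - min(max(n - 35, 0), 20))
  }
})

test_that("tau_AFB errors when the window exceeds the schedule", {
  sched <- build_schedule(build_construct(1L)) # 56 codons
  expect_error(tau_afb(sched, binding_window(53, 72)), "beyond")
})

test_that("amount misprocessed is a0 exp(-k_on tau_AFB)", {
  expect_equal(amount_misprocessed(0, 0.5, a0 = 3), 3)
  expect_equal(amount_misprocessed(100, 0, a0 = 3), 3)
  expect_equal(amount_misprocessed(40, 0.0366, a0 = 1), exp(-1.464))
  expect_equal(round(amount_misprocessed(40, 0.0366), 4), 0.2313)
  # strictly decreasing in available time
  vals <- amount_misprocessed(c(10, 20, 30), 0.1)
  expect_true(all(diff(vals) < 0))
  expect_error(amount_misprocessed(-1, 0.1), "non-negative")
  expect_error(amount_misprocessed(1, -0.1), "non-negative")
})

test_that("f_mp matches direct evaluation of the relative-fraction formula", {
  expect_equal(fraction_misprocessed(35L), 0)
  expect_equal(fraction_misprocessed(40L), exp(0.183) - 1)
  expect_equal(fraction_misprocessed(40L), 0.2008144, tolerance = 1e-6)
  # plateau: all-fast window from 55 on
  expect_equal(fraction_misprocessed(60L), fraction_misprocessed(55L))
  expect_equal(fraction_misprocessed(55L), exp(0.732) - 1)
})

test_that("repeat numbers below the 35-repeat reference are rejected", {
  expect_error(fraction_misprocessed(34L), ">= 35")
  expect_error(fraction_misprocessed(c(40L, 30L)), ">= 35")
  expect_error(linearized_fraction(34L), ">= 35")
})

test_that("relative-amount ratio cancellation reproduces f_mp to machine precision", {
  for (a0 in c(1, 0.01, 537)) {
    for (n in c(36L, 40L, 47L, 55L, 70L)) {
      amp_n <- amount_misprocessed(tau_for(n), dflt$beta, a0)
      amp_ref <- amount_misprocessed(tau_for(35L), dflt$beta, a0)
      expect_equal((amp_n - amp_ref) / amp_ref, fraction_misprocessed(n),
                   tolerance = 1e-12)
    }
  }
})

test_that("f_mp is strictly increasing up to the plateau and constant above", {
  n <- 35:80
  f <- fraction_misprocessed(n)
  rising <- n >= 35 & n <= 55
  expect_true(all(diff(f[rising]) > 0))
  expect_true(all(abs(f[n >= 55] - f[n == 55]) < 1e-15))
})

test_that("widening the binding window downstream leaves f_mp unchanged", {
  # codons 73..90 are proline-region for every repeat number in 35..55, so
  # widening adds the same dwell to every tau_AFB and cancels in f_mp; the
  # reference construct is 90 codons, bounding the widening at w = 18
  base <- fraction_misprocessed(35:55)
  for (w in c(5L, 10L, 18L)) {
    wide <- binding_window(53L, 72L + w)
    expect_equal(fraction_misprocessed(35:55, window = wide), base)
  }
})

test_that("f_mp is non-decreasing in the slowdown factor and vanishes at s = 1", {
  n <- c(40L, 50L, 60L)
  expect_equal(fraction_misprocessed(n, kinetic_params(slowdown_s = 1)),
               rep(0, 3))
  prev <- rep(-Inf, 3)
  for (s in c(1, 1.5, 2, 4, 6)) {
    f <- fraction_misprocessed(n, kinetic_params(slowdown_s = s))
    expect_true(all(f >= prev))
    prev <- f
  }
})

test_that("f_mp approaches the linear form as beta shrinks", {
  n <- c(40L, 45L, 50L)
  for (beta in c(1e-3, 1e-5, 1e-7)) {
    p <- kinetic_params(k_on = beta)
    ratio <- fraction_misprocessed(n, p) / (beta * (2 - 1) * (n - 35))
    expect_equal(ratio, rep(1, 3), tolerance = 10 * beta * 20)
  }
})

test_that("linearized fraction obeys the power-series error bound", {
  expect_equal(linearized_fraction(35L), 0)
  expect_equal(linearized_fraction(40L), 0.183)
  x <- linearized_fraction(40L)
  err <- fraction_misprocessed(40L) - x
  expect_equal(err, 0.0178, tolerance = 1e-3)
  for (n in c(36L, 40L, 55L, 70L)) {
    x <- linearized_fraction(n)
    expect_lte(abs(fraction_misprocessed(n) - x), x^2 * exp(x) / 2 + 1e-15)
  }
})

test_that("misprocessing curve covers the range and satisfies its invariants", {
  cur <- misprocessing_curve(40L, 53L)
  expect_s3_class(cur, "misprocessing_curve")
  expect_equal(nrow(cur), 14L)
  expect_equal(cur$n_cag, 40:53)
  expect_true(all(diff(cur$f_mp) > 0))

  single <- misprocessing_curve(35L, 35L)
  expect_equal(nrow(single), 1L)
  expect_equal(single$f_mp, 0)

  plateau <- misprocessing_curve(55L, 60L)
  expect_equal(length(unique(plateau$f_mp)), 1L)

  expect_error(misprocessing_curve(34L, 40L), "35 <= n_cag_min")
  expect_error(misprocessing_curve(50L, 40L), "35 <= n_cag_min")
})

test_that("curve CSV export writes the data and a parameter sidecar", {
  cur <- misprocessing_curve(40L, 45L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cur, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("n_cag", "tau_afb_tau_a", "f_mp"))
  expect_equal(back$f_mp, cur$f_mp)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$beta, 0.0366)
  expect_equal(side$window_first_codon, 53L)
})

test_that("kinetic parameter validation rejects unphysical values", {
  expect_error(kinetic_params(k_on = -1), "non-negative")
  expect_error(kinetic_params(tau_a = 0), "positive")
  expect_error(kinetic_params(slowdown_s = 0.9), ">= 1")
  expect_error(binding_window(72, 53), "first_codon <= last_codon")
  expect_equal(binding_window()$width, 20L)
})
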