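params_I <- survival_params_I(1.090, 5.917, -1.879, 9.944)
params_II <- survival_params_II(1.037, 7.275, -2.296, 3.088, 30.68)

test_that("the LQ and per-DSB survival forms evaluate correctly", {
  expect_equal(lq_survival(0, 0.1, 0.01), 1)
  expect_equal(lq_survival(2, 0.1, 0.01, p = 1), exp(-0.24))
  expect_equal(lq_survival(5, 0.1, 0.01, p = 0), 1)
  expect_error(lq_survival(-1, 0.1, 0.01), ">= 0")

  expect_equal(survival_from_dsb(0, 9.944e-3), 1)
  expect_equal(survival_from_dsb(100, 9.944e-3), exp(-0.9944))
  # log-linearity
  expect_equal(survival_from_dsb(200, 9.944e-3),
               survival_from_dsb(100, 9.944e-3)^2, tolerance = 1e-12)
})

test_that("repair capacity applies the printed parameter scales", {
  expect_equal(repair_capacity(0, 1.090, 5.917, -1.879), 1.090)
  expect_equal(repair_capacity(100, 1.090, 5.917, -1.879),
               1.090 + 0.5917 - 0.1879, tolerance = 1e-12)
  expect_equal(repair_capacity(50, 2, 0, 0), 2)
})

test_that("class I survival composes repair capacity and DSB lethality", {
  expect_equal(survival_class_I(params_I, 0), 1.090)
  expect_equal(survival_class_I(params_I, 100),
               repair_capacity(100, 1.090, 5.917, -1.879) *
                 survival_from_dsb(100, 9.944e-3), tolerance = 1e-12)
  # monotone decreasing in p
  s_low <- survival_class_I(survival_params_I(1.090, 5.917, -1.879, 1), 100)
  s_high <- survival_class_I(survival_params_I(1.090, 5.917, -1.879, 50), 100)
  expect_lt(s_high, s_low)
  # negative q at extreme damage is returned, with a warning
  expect_warning(s_neg <- survival_class_I(params_I, 500), "negative")
  expect_lt(s_neg, 0)
})

test_that("class II survival matches its scalar formula and degeneracies", {
  expect_equal(survival_class_II(params_II, 0, 0), 1.037)
  direct <- repair_capacity(100, 1.037, 7.275, -2.296) *
    exp(-(3.088 * 80 + 30.68 * 20) * 1e-3)
  expect_equal(survival_class_II(params_II, 80, 20), direct,
               tolerance = 1e-12)
  # p0 = p* collapses class II onto class I
  pII_eq <- survival_params_II(1.037, 7.275, -2.296, 5, 5)
  pI_eq <- survival_params_I(1.037, 7.275, -2.296, 5)
  expect_equal(survival_class_II(pII_eq, 60, 40),
               survival_class_I(pI_eq, 100), tolerance = 1e-12)
})

test_that("both classes reduce to the pure-exponential model", {
  # k1 = k2 = 0 and q0 = 1 (and p0 = p*) recover S = exp(-p DSB)
  pI <- survival_params_I(1, 0, 0, 9.944)
  pII <- survival_params_II(1, 0, 0, 9.944, 9.944)
  dsb <- c(0, 10, 100, 400)
  expect_equal(survival_class_I(pI, dsb), survival_from_dsb(dsb, 9.944e-3),
               tolerance = 1e-12)
  expect_equal(survival_class_II(pII, 0.3 * dsb, 0.7 * dsb),
               survival_from_dsb(dsb, 9.944e-3), tolerance = 1e-12)
})

test_that("noise-free refits recover the generating parameters within 1%", {
  dI <- suppressWarnings(generate_survival_dataset(params_I, seq(0, 500, 25)))
  fI <- suppressWarnings(fit_survival_params(dI, "I", init = c(1, 1, -1, 5)))
  expect_true(fI$converged)
  expect_equal(unname(coef(fI)), c(1.090, 5.917, -1.879, 9.944),
               tolerance = 0.01)
  expect_gt(fI$r_squared, 0.9999)

  dII <- suppressWarnings(generate_survival_dataset(
    params_II, seq(0, 500, 25), a0_levels = c(0.6, 0.8)))
  fII <- suppressWarnings(fit_survival_params(dII, "II"))
  expect_true(fII$converged)
  expect_equal(unname(coef(fII)), c(1.037, 7.275, -2.296, 3.088, 30.68),
               tolerance = 0.01)
})

test_that("noisy refits stay within 15% at n = 50 points", {
  dsb <- seq(4, 396, length.out = 50)
  d <- generate_survival_dataset(params_I, dsb,
                                 noise = noise_model(cv = 0.05, seed = 12))
  f <- fit_survival_params(d, "I")
  expect_equal(coef(f)[["p"]], 9.944, tolerance = 0.15)
  expect_equal(coef(f)[["q0"]], 1.090, tolerance = 0.15)
})

test_that("a null lethality parameter is recovered as null", {
  p0 <- survival_params_I(1, 1, -0.1, 1e-9)
  d <- generate_survival_dataset(p0, seq(0, 400, 25))
  f <- fit_survival_params(d, "I")
  expect_lte(abs(coef(f)[["p"]]) * 1e-3, 1e-6)
})

test_that("survival fitting validates its design", {
  d_const <- data.frame(dsb_total = rep(100, 6),
                        survival = rep(0.5, 6))
  expect_error(fit_survival_params(d_const, "I"), "degenerate")
  d_small <- data.frame(dsb_total = c(0, 100), survival = c(1, 0.4))
  expect_error(fit_survival_params(d_small, "I"), "at least 5")
  dII_flat <- data.frame(dsb_total = seq(50, 250, 50),
                         dsb0 = 0.6 * seq(50, 250, 50),
                         dsbstar = 0.4 * seq(50, 250, 50),
                         survival = exp(-0.01 * seq(50, 250, 50)))
  expect_error(fit_survival_params(dII_flat, "II"), "variation")
})
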