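test_that("noise-free generation is a simulation passthrough", {
  topo <- mouse_topology()
  rates <- mouse_transfer_rates()
  tt <- seq(1, 96, by = 5)
  clean <- generate_biodistribution_dataset(topo, rates, injection(), tt,
                                            noise_model(cv = 0))
  A <- rate_matrix(topo, rates)
  sim <- simulate_biodistribution(A, injection(), tt)
  expect_equal(clean$values, sim$values, tolerance = 1e-12)
})

test_that("generators are pure functions of their seed", {
  topo <- mouse_topology()
  rates <- mouse_transfer_rates()
  tt <- seq(1, 96, by = 5)
  a <- generate_biodistribution_dataset(topo, rates, injection(), tt,
                                        noise_model(cv = 0.1, seed = 5))
  b <- generate_biodistribution_dataset(topo, rates, injection(), tt,
                                        noise_model(cv = 0.1, seed = 5))
  expect_identical(a$values, b$values)
  c <- generate_biodistribution_dataset(topo, rates, injection(), tt,
                                        noise_model(cv = 0.1, seed = 6))
  expect_false(identical(a$values, c$values))
})

test_that("the applied noise has the requested coefficient of variation", {
  x <- rep(1, 200)
  y <- npradbio:::apply_noise(x, noise_model(cv = 0.1, seed = 8))
  expect_gt(stats::sd(y) / mean(y), 0.08)
  expect_lt(stats::sd(y) / mean(y), 0.12)
  expect_gt(min(y), 0)
})

test_that("spectrum sampling respects bins and the peak voltage", {
  one_bin <- spectrum_histogram(20, 20.5, 1, kvp = 50)
  x <- sample_spectrum(one_bin, 100, seed = 2)
  expect_true(all(x >= 20 & x <= 20.5))

  spec <- read_spectrum(system.file("extdata",
                                    "placeholder_spectrum_50kvp.csv",
                                    package = "npradbio"))
  expect_equal(spec$kvp, 50)
  xs <- sample_spectrum(spec, 1e5, seed = 3)
  expect_lte(max(xs), 50)
  # moment check against the histogram mean
  mids <- (spec$e_low_kev + spec$e_high_kev) / 2
  mu <- sum(mids * spec$fluence) / sum(spec$fluence)
  sd_bins <- sqrt(sum(spec$fluence * (mids - mu)^2) / sum(spec$fluence))
  expect_lt(abs(mean(xs) - mu), 3 * sd_bins / sqrt(1e5) + 0.15)
  expect_error(spectrum_histogram(10, 11, 0, 50), "not all zero")
})

test_that("toy emission events conserve energy and honor null interaction", {
  ev0 <- generate_toy_emission_events(interaction_prob = 0,
                                      n_primaries = 500, seed = 4)
  a <- ev0$with_np[order(ev0$with_np$r_nm), ]
  b <- ev0$without_np[order(ev0$without_np$r_nm), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  ev <- generate_toy_emission_events(interaction_prob = 0.2,
                                     n_primaries = 500, seed = 4,
                                     background_per_primary = 0,
                                     electron_energies_kev = c(0.5, 2))
  # each interacting primary deposits its full electron energy
  per_primary <- tapply(ev$with_np$edep_ev, ev$with_np$primary_id,
                        sum) / 1000
  expect_true(all(vapply(per_primary, function(x)
    min(abs(x - c(0.5, 2))) < 1e-9, logical(1))))
  expect_match(ev$meta, "TOY")
  # reproducible
  ev2 <- generate_toy_emission_events(interaction_prob = 0.2,
                                      n_primaries = 500, seed = 4,
                                      background_per_primary = 0,
                                      electron_energies_kev = c(0.5, 2))
  expect_identical(ev$with_np, ev2$with_np)
})

test_that("toy events with no background yield fully masked DER", {
  ev <- generate_toy_emission_events(interaction_prob = 1,
                                     background_per_primary = 0,
                                     n_primaries = 50, seed = 9)
  g <- build_shell_grid(25, 10, 100)
  with_np <- score_energy_deposits(ev$with_np, g, 50)
  without_np <- score_energy_deposits(ev$without_np, g, 50)
  expect_message(der <- dose_enhancement_ratio(with_np, without_np),
                 "masked")
  expect_false(any(der$valid))
  expect_error(summarize_der(der, 10), "no valid shell")
})

test_that("backbone-hit composition matches the requested fractions", {
  h <- generate_backbone_hits(1e4, direct_fraction = 0.3, seed = 6)
  expect_equal(mean(h$kind == "direct"), 0.30, tolerance = 0.02 / 0.30)
  expect_true(all(is.finite(h$edep_ev[h$kind == "direct"])))
  expect_true(all(is.na(h$edep_ev[h$kind == "radical"])))
  h1 <- generate_backbone_hits(100, direct_fraction = 1, seed = 6)
  expect_true(all(h1$kind == "direct"))
  expect_identical(generate_backbone_hits(100, 0.5, seed = 7),
                   generate_backbone_hits(100, 0.5, seed = 7))
})

test_that("survival datasets are exact model evaluations when noise-free", {
  pI <- survival_params_I(1.090, 5.917, -1.879, 9.944)
  d <- generate_survival_dataset(pI, seq(0, 400, 50))
  expect_equal(d$survival, survival_class_I(pI, seq(0, 400, 50)))
  expect_equal(d$survival[1], 1.090)  # DSB = 0 returns q0
  # class II two-level design is identifiable
  pII <- survival_params_II(1.037, 7.275, -2.296, 3.088, 30.68)
  dII <- generate_survival_dataset(pII, seq(0, 400, 25),
                                   a0_levels = c(0.6, 0.8))
  f <- fit_survival_params(dII, "II")
  expect_true(f$converged)
  expect_equal(coef(f)[["p0"]], 3.088, tolerance = 0.01)
})
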