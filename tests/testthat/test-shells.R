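test_that("shell grids span the documented scoring geometries", {
  g1 <- build_shell_grid(25, 10, 100)    # 50 nm particle, nm range
  expect_equal(g1$boundaries[101], 1025)
  g2 <- build_shell_grid(50, 1000, 50)   # 100 nm particle, um range
  expect_equal(g2$boundaries[51], 50050)
  g3 <- build_shell_grid(0, 1, 1)
  expect_equal(g3$boundaries, c(0, 1))
  expect_error(build_shell_grid(25, 0, 10), "> 0")
  expect_error(build_shell_grid(25, 10, 0), ">= 1")
})

test_that("boundary events go to the outer shell (half-open rule)", {
  g <- build_shell_grid(25, 10, 100)
  ev <- data.frame(primary_id = 1, r_nm = 35, edep_ev = 5)  # on shell 0/1 edge
  prof <- score_energy_deposits(ev, g, 1)
  expect_equal(prof$energy_ev_per_primary[1], 0)
  expect_equal(prof$energy_ev_per_primary[2], 5)
  # inner boundary is inclusive
  ev0 <- data.frame(primary_id = 1, r_nm = 25, edep_ev = 2)
  expect_equal(score_energy_deposits(ev0, g, 1)$energy_ev_per_primary[1], 2)
})

test_that("scoring normalizes per primary and accounts for discards", {
  g <- build_shell_grid(25, 10, 100)
  ev <- data.frame(primary_id = 1:10, r_nm = rep(26, 10),
                   edep_ev = rep(5, 10))
  prof <- score_energy_deposits(ev, g, 50)
  expect_equal(prof$energy_ev_per_primary[1], 1.0)  # 50 eV / 50 primaries
  # events inside the particle or beyond the grid are counted, not lost
  ev2 <- rbind(ev, data.frame(primary_id = 11:12, r_nm = c(10, 2000),
                              edep_ev = c(7, 9)))
  prof2 <- score_energy_deposits(ev2, g, 50)
  expect_equal(unname(prof2$discarded), c(1L, 1L))
  expect_equal(prof2$discarded_energy_ev, 16)
})

test_that("vectorized binning matches a brute-force event loop", {
  set.seed(11)
  n <- 1e4
  r <- stats::runif(n, 0, 1200)
  e <- stats::rexp(n, 1 / 30)
  ev <- data.frame(primary_id = seq_len(n), r_nm = r, edep_ev = e)
  g <- build_shell_grid(25, 10, 100)
  prof <- score_energy_deposits(ev, g, 500)
  expect_equal(prof$energy_ev_per_primary,
               brute_force_bin(r, e, 25, 10, 100, 500), tolerance = 1e-12)
  # energy conservation: scored + discarded = total input
  expect_equal(sum(prof$energy_ev_per_primary) * 500 +
                 prof$discarded_energy_ev, sum(e), tolerance = 1e-12)
  # permutation invariance
  perm <- sample.int(n)
  prof_p <- score_energy_deposits(ev[perm, ], g, 500)
  expect_equal(prof_p$energy_ev_per_primary, prof$energy_ev_per_primary)
})

test_that("DER is the per-shell ratio with zero-reference masking", {
  g <- build_shell_grid(25, 10, 3)
  mk <- function(e) structure(list(grid = g, energy_ev_per_primary = e,
                                   n_primaries = 100, n_events = NA,
                                   discarded = c(inside_np = 0L,
                                                 beyond_grid = 0L),
                                   discarded_energy_ev = 0),
                              class = "radial_profile")
  # identical profiles: DER identically 1
  p <- mk(c(0.4, 0.2, 0.1))
  der_id <- dose_enhancement_ratio(p, p)
  expect_equal(der_id$ratio, rep(1, 3))
  # magnitudes like the nanometer-range first shell: 0.4 vs 7e-4
  der <- dose_enhancement_ratio(mk(c(0.4, 0.2, 0.1)),
                                mk(c(7e-4, 0.1, 0)))
  expect_equal(der$ratio[1], 0.4 / 7e-4, tolerance = 1e-12)
  expect_equal(der$ratio[1], 571.4286, tolerance = 1e-4)
  expect_false(der$valid[3])
  expect_true(is.na(der$ratio[3]))
  # grid mismatch
  q <- mk(c(1, 1, 1)); q$grid <- build_shell_grid(50, 10, 3)
  expect_error(dose_enhancement_ratio(p, q), "different shell grids")
})

test_that("the first-k DER summary is an arithmetic mean of valid shells", {
  g <- build_shell_grid(25, 10, 4)
  der <- structure(list(grid = g, ratio = c(2, 4, NA, 8),
                        valid = c(TRUE, TRUE, FALSE, TRUE)),
                   class = "der_profile")
  expect_equal(summarize_der(der, 1), 2)
  expect_equal(summarize_der(der, 2), 3)
  expect_equal(summarize_der(der, 3), 3)   # invalid shell excluded
  expect_equal(summarize_der(der, 4), mean(c(2, 4, 8)))
  der_bad <- structure(list(grid = g, ratio = rep(NA_real_, 4),
                            valid = rep(FALSE, 4)), class = "der_profile")
  expect_error(summarize_der(der_bad, 2), "no valid shell")
})
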