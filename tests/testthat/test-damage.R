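hit <- function(strand, bp, kind = "direct", e = 20, cell = 1L) {
  data.frame(cell_id = cell, strand = strand, bp_index = bp, kind = kind,
             edep_ev = if (kind == "direct") e else NA_real_)
}

test_that("the direct-break energy threshold is a sharp boundary", {
  cfg <- break_config(seed = 1)
  expect_equal(nrow(call_strand_breaks(hit(1, 100, e = 17.4), cfg)), 0L)
  expect_equal(nrow(call_strand_breaks(hit(1, 100, e = 17.5), cfg)), 1L)
})

test_that("energy accumulates per backbone position before thresholding", {
  cfg <- break_config(seed = 1)
  two <- rbind(hit(1, 100, e = 10), hit(1, 100, e = 10))
  br <- call_strand_breaks(two, cfg)
  expect_equal(nrow(br), 1L)  # cumulative 20 eV >= 17.5, single break
  # same energies on different positions stay below threshold
  apart <- rbind(hit(1, 100, e = 10), hit(1, 200, e = 10))
  expect_equal(nrow(call_strand_breaks(apart, cfg)), 0L)
  # oracle: per-position energy sums decide the break set
  set.seed(3)
  n <- 500
  hits <- data.frame(cell_id = 1L, strand = sample(1:2, n, TRUE),
                     bp_index = sample.int(50, n, TRUE), kind = "direct",
                     edep_ev = stats::rexp(n, 1 / 8))
  br2 <- call_strand_breaks(hits, cfg)
  sums <- tapply(hits$edep_ev, paste(hits$strand, hits$bp_index), sum)
  expect_equal(nrow(br2), sum(sums >= 17.5))
})

test_that("radical breaks occur at the configured probability", {
  n <- 1e5
  hits <- data.frame(cell_id = 1L, strand = 1L, bp_index = seq_len(n),
                     kind = "radical", edep_ev = NA_real_)
  br <- call_strand_breaks(hits, break_config(seed = 20))
  expect_equal(nrow(br) / n, 0.400, tolerance = 0.005 / 0.400)
  # determinism under the seed
  br2 <- call_strand_breaks(hits, break_config(seed = 20))
  expect_identical(br, br2)
  br3 <- call_strand_breaks(hits, break_config(seed = 21))
  expect_false(identical(br, br3))
})

test_that("breaks on alternate strands pair within the 10 bp window", {
  s <- pair_breaks(data.frame(strand = c(1, 2), bp_index = c(100, 110)))
  expect_equal(c(s$dsb, s$ssb), c(1L, 0L))
  s2 <- pair_breaks(data.frame(strand = c(1, 2), bp_index = c(100, 111)))
  expect_equal(c(s2$dsb, s2$ssb), c(0L, 2L))
  # same strand never pairs
  s3 <- pair_breaks(data.frame(strand = c(1, 1), bp_index = c(100, 105)))
  expect_equal(c(s3$dsb, s3$ssb), c(0L, 2L))
})

test_that("DSB complexity splits into simple and complex classes", {
  # lone opposite pair: simple
  s <- pair_breaks(data.frame(strand = c(1, 2), bp_index = c(100, 105)))
  expect_equal(c(s$dsb0, s$dsbstar), c(1L, 0L))
  # extra break inside the fragment makes it complex
  s2 <- pair_breaks(data.frame(strand = c(1, 2, 2),
                               bp_index = c(100, 105, 108)))
  expect_equal(s2$dsb, 1L)
  expect_equal(s2$dsbstar, 1L)
  expect_equal(s2$dsb0 + s2$dsbstar, s2$dsb)
  # fractions sum to one whenever DSBs exist
  expect_equal(s2$a0 + s2$astar, 1)
})

test_that("greedy pairing attains the exhaustive maximum on random
           configurations of up to 10 breaks", {
  set.seed(99)
  for (rep in 1:300) {
    m <- sample(2:10, 1)
    breaks <- data.frame(strand = sample(1:2, m, TRUE),
                         bp_index = sample.int(40, m, TRUE))
    breaks <- unique(breaks)
    s <- pair_breaks(breaks, window_bp = 10)
    oracle <- max_matching_bruteforce(breaks$strand, breaks$bp_index, 10)
    expect_equal(s$dsb, oracle)
    expect_equal(s$dsb0 + s$dsbstar, s$dsb)
    expect_equal(s$ssb + 2L * s$dsb, nrow(breaks))
  }
})

test_that("pairing respects cell boundaries", {
  br <- data.frame(cell_id = c(1, 2), strand = c(1, 2),
                   bp_index = c(100, 105))
  s <- pair_breaks(br)
  expect_equal(c(s$dsb, s$ssb), c(0L, 2L))
})

test_that("dsb_counts keeps the complexity bookkeeping consistent", {
  x <- dsb_counts(80, 20)
  expect_equal(x$dsb, 100)
  expect_equal(x$a0 + x$astar, 1)
  expect_error(dsb_counts(-1, 5), ">= 0")
})
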