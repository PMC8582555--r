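#' Multiplicative measurement-noise model
#'
#' Noise applied to synthetic time courses. Lognormal noise (the default)
#' is multiplicative with unit mean and the requested coefficient of
#' variation, matching the error structure typical of %ID/g biodistribution
#' measurements; `gaussian_cv` is `1 + cv*N(0,1)` truncated at zero.
#'
#' @param family `"lognormal"` or `"gaussian_cv"`.
#' @param cv coefficient of variation, `>= 0` (0 means noise-free).
#' @param seed integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(family = c("lognormal", "gaussian_cv"), cv = 0.1,
                        seed = 1L) {
  family <- match.arg(family)
  if (!is.finite(cv) || cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  structure(list(family = family, cv = cv, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  if (noise$cv == 0) return(values)
  set.seed(noise$seed)
  n <- length(values)
  f <- if (noise$family == "lognormal") {
    sdlog <- sqrt(log(1 + noise$cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    pmax(0, 1 + noise$cv * stats::rnorm(n))
  }
  values * f
}

#' Generate a noisy synthetic biodistribution dataset
#'
#' Simulates the whole-body model and applies multiplicative measurement
#' noise per point, emulating a radiolabel biodistribution experiment.
#' Noisy fractions are clipped at the injected amount (a measured
#' retained fraction cannot exceed the dose). Pure function of its
#' arguments and the noise seed; `cv = 0` returns the simulation
#' unchanged.
#'
#' @param topology a [compartment_topology()].
#' @param rates a [transfer_rates()] set for the topology.
#' @param protocol an [injection()] protocol.
#' @param times sample times (h).
#' @param noise a [noise_model()].
#' @return A [time_course()] in fraction units with `sd = cv * value`.
#' @export
#' @examples
#' tc <- generate_biodistribution_dataset(mouse_topology(),
#'         mouse_transfer_rates(), injection(), seq(1, 96, by = 5),
#'         noise_model(cv = 0.1, seed = 7))
generate_biodistribution_dataset <- function(topology, rates,
                                             protocol = injection(),
                                             times,
                                             noise = noise_model(cv = 0)) {
  stopifnot(inherits(noise, "noise_model"))
  A <- rate_matrix(topology, rates)
  sim <- simulate_biodistribution(A, protocol, times)
  vals <- apply_noise(sim$values, noise)
  vals <- pmin(vals, protocol$amount)
  sd <- if (noise$cv > 0) noise$cv * vals else NULL
  time_course(sim$times, vals, sd = sd, unit = "fraction")
}

#' X-ray spectrum histogram
#'
#' A binned tube spectrum: energy bin edges in keV with the relative
#' fluence per bin, tagged by the tube peak voltage. The packaged
#' placeholder spectra use 0.5 keV bins.
#'
#' @param e_low_kev,e_high_kev bin edges (keV), contiguous and increasing.
#' @param fluence relative fluence per bin, `>= 0`, not all zero.
#' @param kvp peak tube voltage (kVp); no bin may extend beyond it.
#' @return An object of class `spectrum_histogram`.
#' @export
spectrum_histogram <- function(e_low_kev, e_high_kev, fluence, kvp) {
  if (length(e_low_kev) != length(e_high_kev) ||
      length(fluence) != length(e_low_kev)) {
    stop("bin edge and fluence vectors must have equal length",
         call. = FALSE)
  }
  if (any(e_high_kev <= e_low_kev)) {
    stop("bins must have e_high > e_low", call. = FALSE)
  }
  if (any(fluence < 0) || !any(fluence > 0)) {
    stop("fluence must be >= 0 and not all zero", call. = FALSE)
  }
  if (max(e_high_kev) > kvp + 1e-9) {
    stop("spectrum extends beyond the peak voltage ", kvp, " kVp",
         call. = FALSE)
  }
  structure(list(e_low_kev = e_low_kev, e_high_kev = e_high_kev,
                 fluence = fluence, kvp = kvp),
            class = "spectrum_histogram")
}

#' Sample photon energies from a spectrum histogram
#'
#' Draws bin indices proportional to fluence and energies uniformly
#' within the chosen bin; no sampled energy can exceed the peak voltage.
#'
#' @param spec a [spectrum_histogram()].
#' @param n number of photons, `>= 1`.
#' @param seed integer seed.
#' @return Numeric vector of photon energies (keV).
#' @export
sample_spectrum <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "spectrum_histogram"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  set.seed(seed)
  bins <- sample.int(length(spec$fluence), n, replace = TRUE,
                     prob = spec$fluence)
  stats::runif(n, spec$e_low_kev[bins], spec$e_high_kev[bins])
}

#' Generate toy paired emission-event lists
#'
#' NON-PHYSICAL TOY generator that exercises the shell-scoring pipeline
#' end to end without any radiation transport. Both lists share an
#' identical uniform low-level background; the with-NP list additionally
#' contains, for each interacting primary, one secondary electron whose
#' energy is split into equal deposits placed at exponentially
#' distributed radial depths with mean range `range_coef * E^1.7` beyond
#' the particle surface. The radial kernel is a testing device shaped
#' like a decaying deposition profile, not physics.
#'
#' @param np_radius_nm nanoparticle radius (nm).
#' @param electron_energies_kev pool of secondary-electron energies (keV)
#'   sampled uniformly per interaction (e.g. from [sample_spectrum()]).
#' @param interaction_prob probability per primary of an NP interaction,
#'   in [0, 1].
#' @param n_primaries number of primary photons.
#' @param range_coef kernel coefficient `c` in the mean range
#'   `c * E_keV^1.7` (nm).
#' @param n_fragments number of equal deposits an electron is split into.
#' @param background_per_primary expected background deposits per primary.
#' @param background_edep_ev energy of one background deposit (eV).
#' @param background_rmax_nm outer radius of the uniform background.
#' @param seed integer seed.
#' @return List with data frames `with_np` and `without_np` (columns
#'   `primary_id`, `r_nm`, `edep_ev`), `n_primaries`, and a `meta` tag
#'   marking the output as a non-physical toy.
#' @export
generate_toy_emission_events <- function(np_radius_nm = 25,
                                         electron_energies_kev = c(0.25, 1, 5),
                                         interaction_prob = 0.05,
                                         n_primaries = 1000L,
                                         range_coef = 10,
                                         n_fragments = 20L,
                                         background_per_primary = 0.05,
                                         background_edep_ev = 30,
                                         background_rmax_nm = 1025,
                                         seed = 1L) {
  if (interaction_prob < 0 || interaction_prob > 1) {
    stop("'interaction_prob' must lie in [0, 1]", call. = FALSE)
  }
  n_primaries <- as.integer(n_primaries)
  set.seed(seed)
  # shared background, identical in both lists
  n_bg <- stats::rpois(1L, background_per_primary * n_primaries)
  background <- data.frame(
    primary_id = if (n_bg) sample.int(n_primaries, n_bg, replace = TRUE)
      else integer(),
    r_nm = stats::runif(n_bg, np_radius_nm, background_rmax_nm),
    edep_ev = rep(background_edep_ev, n_bg)
  )
  interacting <- which(stats::runif(n_primaries) < interaction_prob)
  np_events <- NULL
  if (length(interacting)) {
    e_kev <- sample(electron_energies_kev, length(interacting),
                    replace = TRUE)
    per <- lapply(seq_along(interacting), function(i) {
      rbar <- range_coef * e_kev[i]^1.7
      data.frame(
        primary_id = interacting[i],
        r_nm = np_radius_nm + stats::rexp(n_fragments, rate = 1 / rbar),
        edep_ev = rep(e_kev[i] * 1000 / n_fragments, n_fragments)
      )
    })
    np_events <- do.call(rbind, per)
  }
  with_np <- rbind(background, np_events)
  list(with_np = with_np[order(with_np$primary_id), , drop = FALSE],
       without_np = background,
       n_primaries = n_primaries,
       meta = "NON-PHYSICAL TOY: synthetic test events, not transport output")
}

#' Generate synthetic backbone hits
#'
#' Seeded generator of direct/radical backbone-hit records on distinct
#' base-pair positions, for exercising the strand-break calling rules.
#'
#' @param n_positions number of hit positions.
#' @param direct_fraction fraction of hits that are direct energy
#'   deposits (the rest are radical attacks), in [0, 1].
#' @param energy_sampler function(n) drawing direct-hit energies in eV
#'   (default: gamma with mean 20 eV, so a realistic share crosses the
#'   17.5 eV break threshold).
#' @param n_cells number of cells to spread hits over.
#' @param genome_bp base-pair index range.
#' @param seed integer seed.
#' @return Data frame of backbone hits (`cell_id`, `strand`, `bp_index`,
#'   `kind`, `edep_ev`).
#' @export
generate_backbone_hits <- function(n_positions, direct_fraction = 0.5,
                                   energy_sampler = function(n)
                                     stats::rgamma(n, shape = 4, rate = 0.2),
                                   n_cells = 1L, genome_bp = 1e6,
                                   seed = 1L) {
  if (direct_fraction < 0 || direct_fraction > 1) {
    stop("'direct_fraction' must lie in [0, 1]", call. = FALSE)
  }
  n_positions <- as.integer(n_positions)
  set.seed(seed)
  is_direct <- stats::runif(n_positions) < direct_fraction
  hits <- data.frame(
    cell_id = sample.int(n_cells, n_positions, replace = TRUE),
    strand = sample(1:2, n_positions, replace = TRUE),
    bp_index = sample.int(genome_bp, n_positions, replace = TRUE),
    kind = ifelse(is_direct, "direct", "radical"),
    edep_ev = NA_real_
  )
  hits$edep_ev[is_direct] <- energy_sampler(sum(is_direct))
  hits
}

#' Generate a synthetic survival dataset
#'
#' Evaluates the class I or II cell-death model over a DSB grid (and, for
#' class II, one or more simple-DSB fraction levels), optionally adding
#' lognormal noise. With `cv = 0` the values are exact model
#' evaluations.
#'
#' @param params a class I or II `survival_params` object.
#' @param dsb_grid DSB counts to evaluate.
#' @param a0_levels simple-DSB fractions (class II; one dataset per
#'   level, pooled).
#' @param noise a [noise_model()] applied multiplicatively to survival.
#' @return Data frame with columns `dsb_total`, `dsb0`, `dsbstar`,
#'   `survival`.
#' @export
#' @examples
#' generate_survival_dataset(survival_params_I(1.090, 5.917, -1.879, 9.944),
#'                           dsb_grid = seq(0, 200, 50))
generate_survival_dataset <- function(params, dsb_grid,
                                      a0_levels = NULL,
                                      noise = noise_model(cv = 0)) {
  stopifnot(inherits(params, "survival_params"),
            inherits(noise, "noise_model"))
  if (params$model == "I") {
    out <- data.frame(dsb_total = dsb_grid,
                      dsb0 = NA_real_, dsbstar = NA_real_,
                      survival = survival_class_I(params, dsb_grid))
  } else {
    if (is.null(a0_levels)) a0_levels <- c(0.6, 0.8)
    out <- do.call(rbind, lapply(a0_levels, function(a0) {
      dsb0 <- a0 * dsb_grid
      dsbstar <- (1 - a0) * dsb_grid
      data.frame(dsb_total = dsb_grid, dsb0 = dsb0, dsbstar = dsbstar,
                 survival = survival_class_II(params, dsb0, dsbstar))
    }))
  }
  out$survival <- apply_noise(out$survival, noise)
  rownames(out) <- NULL
  out
}
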