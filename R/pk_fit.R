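#' Fit transfer rates of the whole-body model to observed time courses
#'
#' Estimates a chosen subset of transfer-rate constants by weighted
#' nonlinear least squares between simulated and observed compartment
#' amounts. Rates are optimized on the log scale (so they stay positive)
#' with Levenberg-Marquardt, bounded to [1e-8, 1e4] 1/h; all other rates
#' are held fixed. Weights are `1/sd^2` when the observed time course
#' carries standard deviations, else uniform.
#'
#' Full joint fits of all 30 edges are possible but identifiability from a
#' single injection experiment is the caller's responsibility; the usual
#' use is freeing one or a few edges.
#'
#' @param observed a [time_course()] in fraction units covering at least
#'   one model compartment.
#' @param topology a [compartment_topology()].
#' @param free_edges character vector of `"donor->receptor"` keys to
#'   estimate.
#' @param rates a [transfer_rates()] covering all topology edges: fixed
#'   edges keep these values, free edges use them as initial guesses
#'   unless `init` overrides.
#' @param protocol the [injection()] protocol that produced the data.
#' @param init optional named numeric of initial guesses for the free
#'   edges (names are `"donor->receptor"` keys).
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @param sim_rtol,sim_atol solver tolerances used inside the fit;
#'   tighter than the simulation defaults so that finite-difference
#'   Jacobians of faint compartments (organ signals down at 1e-6 of the
#'   dose) are not drowned in integration noise.
#' @return An object of class `pk_fit` with the full fitted
#'   `transfer_rates`, per-edge estimates, residual norm, and a
#'   convergence flag. Non-convergence is flagged, not raised.
#' @export
#' @examples
#' topo <- mouse_topology()
#' truth <- mouse_transfer_rates()
#' A <- rate_matrix(topo, truth)
#' obs <- simulate_biodistribution(A, injection(), seq(0, 100, length.out = 51))
#' fit <- fit_transfer_rates(obs, topo, "liver->blood", truth, injection(),
#'                           init = c("liver->blood" = 1))
#' coef(fit)
fit_transfer_rates <- function(observed, topology, free_edges, rates,
                               protocol = injection(), init = NULL,
                               control = list(), sim_rtol = 1e-10,
                               sim_atol = 1e-13) {
  stopifnot(inherits(observed, "time_course"),
            inherits(topology, "compartment_topology"))
  if (!inherits(rates, "transfer_rates")) {
    rates <- transfer_rates(rates$donor, rates$receptor, rates$rate_per_h)
  }
  topo_keys <- paste(topology$edges$donor, topology$edges$receptor,
                     sep = "->")
  keys <- edge_keys(rates)
  if (!setequal(keys, topo_keys)) {
    stop("'rates' must cover exactly the topology's edges", call. = FALSE)
  }
  free_edges <- as.character(free_edges)
  if (!all(free_edges %in% topo_keys)) {
    stop("unknown free edge(s): ",
         paste(setdiff(free_edges, topo_keys), collapse = ", "),
         call. = FALSE)
  }
  obs_comps <- intersect(colnames(observed$values), topology$compartments)
  if (!length(obs_comps)) {
    stop("observed data cover no model compartment", call. = FALSE)
  }
  n_obs <- length(observed$times) * length(obs_comps)
  if (length(free_edges) > 0 && n_obs < length(free_edges)) {
    stop("under-determined fit: ", n_obs, " data points for ",
         length(free_edges), " free rates", call. = FALSE)
  }

  work <- rates
  w <- if (is.null(observed$sd)) {
    matrix(1, nrow(observed$values), length(obs_comps))
  } else {
    sd <- observed$sd[, obs_comps, drop = FALSE]
    ifelse(is.finite(sd) & sd > 0, 1 / sd^2, 1)
  }
  obs_vals <- observed$values[, obs_comps, drop = FALSE]

  simulate_for <- function(rate_vec) {
    work$rate_per_h[match(free_edges, keys)] <- rate_vec
    A <- rate_matrix(topology, work)
    sim <- simulate_biodistribution(A, protocol, observed$times,
                                    rtol = sim_rtol, atol = sim_atol)
    sim$values[, obs_comps, drop = FALSE]
  }

  if (!length(free_edges)) {
    resid <- sqrt(w) * (simulate_for(numeric(0)) - obs_vals)
    return(structure(list(rates = rates, estimates = numeric(0),
                          residual_norm = sqrt(sum(resid^2)),
                          converged = TRUE, message = "no free edges",
                          n_obs = n_obs, free_edges = character(0)),
                     class = "pk_fit"))
  }

  start <- rates$rate_per_h[match(free_edges, keys)]
  if (!is.null(init)) {
    if (is.null(names(init))) {
      if (length(init) != length(free_edges)) {
        stop("'init' must be named or match free_edges in length",
             call. = FALSE)
      }
      start <- as.numeric(init)
    } else {
      hit <- intersect(names(init), free_edges)
      start[match(hit, free_edges)] <- init[hit]
    }
  }
  start <- pmin(pmax(start, 1e-8), 1e4)

  fn <- function(theta) {
    sim <- try(simulate_for(exp(theta)), silent = TRUE)
    if (inherits(sim, "try-error")) {
      return(rep(1e6, n_obs))
    }
    as.vector(sqrt(w) * (sim - obs_vals))
  }
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12, epsfcn = 1e-8),
                                    control))
  fit <- minpack.lm::nls.lm(par = log(start), fn = fn,
                            lower = rep(log(1e-8), length(start)),
                            upper = rep(log(1e4), length(start)),
                            control = ctrl)
  est <- stats::setNames(exp(fit$par), free_edges)
  out_rates <- rates
  out_rates$rate_per_h[match(free_edges, keys)] <- est
  structure(list(rates = out_rates, estimates = est,
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4,
                 message = fit$message, n_obs = n_obs,
                 free_edges = free_edges, niter = fit$niter),
            class = "pk_fit")
}

#' @export
coef.pk_fit <- function(object, ...) object$estimates

#' @export
print.pk_fit <- function(x, ...) {
  cat("Whole-body transfer-rate fit\n")
  cat("  free edges:", if (length(x$free_edges))
    paste(x$free_edges, collapse = ", ") else "(none)", "\n")
  if (length(x$estimates)) {
    for (k in names(x$estimates)) {
      cat(sprintf("    %-32s %.6g 1/h\n", k, x$estimates[[k]]))
    }
  }
  cat(sprintf("  residual norm %.4g on %d points; %s\n", x$residual_norm,
              x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.pk_fit <- function(object, ...) {
  cat("Call: fit of", length(object$free_edges), "free transfer rate(s) on",
      object$n_obs, "observations\n")
  print(object)
  invisible(object)
}
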