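#' Cellular uptake model of antibody-conjugated nanoparticles
#'
#' Three-compartment linear model of conjugated-nanoparticle binding and
#' internalization: extracellular medium, membrane-bound, and cytoplasm.
#' Particles bind to the membrane (`k_bind`), may release back to the
#' medium (`k_release`), and are internalized into the cytoplasm
#' (`k_int`). The cytoplasm is absorbing by default; an optional
#' exocytosis edge (`k_exo`, cytoplasm to medium) can be enabled.
#'
#' @param k_bind,k_release,k_int,k_exo non-negative rate constants (1/h).
#' @return An object of class `uptake_model`.
#' @export
#' @examples
#' uptake_model(k_bind = 0.8, k_release = 0.1, k_int = 0.3)
uptake_model <- function(k_bind = 0, k_release = 0, k_int = 0, k_exo = 0) {
  k <- c(k_bind = k_bind, k_release = k_release, k_int = k_int,
         k_exo = k_exo)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("uptake rate constants must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(k), class = "uptake_model")
}

#' @export
print.uptake_model <- function(x, ...) {
  cat(sprintf(
    "Cellular uptake model (1/h): bind %.4g, release %.4g, int %.4g%s\n",
    x$k_bind, x$k_release, x$k_int,
    if (x$k_exo > 0) sprintf(", exo %.4g", x$k_exo) else ""))
  invisible(x)
}

uptake_rate_matrix <- function(model) {
  comps <- c("medium", "membrane", "cytoplasm")
  A <- matrix(0, 3, 3, dimnames = list(comps, comps))
  A["membrane", "medium"] <- model$k_bind
  A["medium", "membrane"] <- model$k_release
  A["cytoplasm", "membrane"] <- model$k_int
  A["medium", "cytoplasm"] <- model$k_exo
  diag(A) <- -colSums(A)
  A
}

#' Simulate the cellular uptake time course
#'
#' Integrates the linear three-compartment system from an all-in-medium
#' initial condition. In the default closed system the total amount over
#' medium + membrane + cytoplasm is conserved; with
#' `infinite_bath = TRUE` the medium is held constant at its initial
#' value (high-volume incubation) and only membrane and cytoplasm evolve.
#'
#' @param model an [uptake_model()].
#' @param medium0 initial amount in the medium (arbitrary but consistent
#'   concentration units).
#' @param times sorted non-negative sample times (h).
#' @param infinite_bath hold the medium concentration constant.
#' @return A [time_course()] with compartments `medium`, `membrane`,
#'   `cytoplasm` in arbitrary units.
#' @export
#' @examples
#' m <- uptake_model(k_bind = 0.8, k_release = 0.1, k_int = 0.3)
#' simulate_uptake(m, 1, c(1, 3, 6, 12, 24))
simulate_uptake <- function(model, medium0 = 1, times,
                            infinite_bath = FALSE) {
  stopifnot(inherits(model, "uptake_model"))
  if (!is.finite(medium0) || medium0 < 0) {
    stop("'medium0' must be finite and >= 0", call. = FALSE)
  }
  if (infinite_bath) {
    A <- uptake_rate_matrix(model)
    A["medium", ] <- 0  # clamp the bath: no depletion, no return flux
    x0 <- c(medium = medium0, membrane = 0, cytoplasm = 0)
    vals <- solve_linear_system(A, x0, times)
  } else {
    A <- uptake_rate_matrix(model)
    x0 <- c(medium = medium0, membrane = 0, cytoplasm = 0)
    vals <- solve_linear_system(A, x0, times)
  }
  vals[vals < 0 & vals > -1e-9] <- 0
  time_course(times, vals, unit = "arbitrary")
}

#' Fit cellular uptake rates to an observed time course
#'
#' Least-squares estimation of the binding, release, and internalization
#' rate constants (optionally exocytosis) from measured compartment
#' amounts, e.g. membrane and cytoplasm signals at the 1/3/6/12/24 h
#' design. Rates are optimized on the log scale so they remain positive.
#'
#' @param observed a [time_course()] whose compartments are a subset of
#'   `medium`, `membrane`, `cytoplasm`; at least 3 sample times.
#' @param init an [uptake_model()] giving initial guesses (and the fixed
#'   values of rates not in `free`).
#' @param medium0 initial medium amount used in the simulations.
#' @param free which rate constants to estimate.
#' @param infinite_bath passed to [simulate_uptake()].
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `uptake_fit` with the fitted
#'   `uptake_model`, residual norm, and convergence flag.
#' @export
#' @examples
#' truth <- uptake_model(0.8, 0.1, 0.3)
#' obs <- simulate_uptake(truth, 1, c(1, 3, 6, 12, 24))
#' fit <- fit_uptake_rates(obs, uptake_model(0.5, 0.5, 0.5))
#' coef(fit)
fit_uptake_rates <- function(observed, init = uptake_model(0.5, 0.5, 0.5),
                             medium0 = NULL,
                             free = c("k_bind", "k_release", "k_int"),
                             infinite_bath = FALSE, control = list()) {
  stopifnot(inherits(observed, "time_course"),
            inherits(init, "uptake_model"))
  free <- match.arg(free, c("k_bind", "k_release", "k_int", "k_exo"),
                    several.ok = TRUE)
  comps <- intersect(colnames(observed$values),
                     c("medium", "membrane", "cytoplasm"))
  if (!length(comps)) {
    stop("observed data cover no uptake compartment", call. = FALSE)
  }
  if (length(observed$times) < 3) {
    stop("need at least 3 sample times", call. = FALSE)
  }
  n_obs <- length(observed$times) * length(comps)
  if (n_obs < length(free)) {
    stop("under-determined fit: ", n_obs, " points for ", length(free),
         " free rates", call. = FALSE)
  }
  if (is.null(medium0)) {
    # total amount is conserved, so the bolus equals the largest observed
    # total when the medium is observed; otherwise default to 1
    medium0 <- if ("medium" %in% comps) max(rowSums(
      observed$values[, comps, drop = FALSE])) else 1
  }
  obs_vals <- observed$values[, comps, drop = FALSE]
  pars0 <- unlist(init[c("k_bind", "k_release", "k_int", "k_exo")])
  fn <- function(theta) {
    p <- pars0
    p[free] <- exp(theta)
    sim <- simulate_uptake(do.call(uptake_model, as.list(p)), medium0,
                           observed$times, infinite_bath = infinite_bath)
    as.vector(sim$values[, comps, drop = FALSE] - obs_vals)
  }
  start <- pmin(pmax(pars0[free], 1e-6), 1e4)
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 300, ftol = 1e-14,
                                         ptol = 1e-14), control))
  fit <- minpack.lm::nls.lm(par = log(start), fn = fn,
                            lower = rep(log(1e-8), length(free)),
                            upper = rep(log(1e4), length(free)),
                            control = ctrl)
  p <- pars0
  p[free] <- exp(fit$par)
  structure(list(model = do.call(uptake_model, as.list(p)),
                 estimates = stats::setNames(exp(fit$par), free),
                 residual_norm = sqrt(sum(fit$fvec^2)),
                 converged = fit$info %in% 1:4, message = fit$message,
                 n_obs = n_obs),
            class = "uptake_fit")
}

#' @export
coef.uptake_fit <- function(object, ...) object$estimates

#' @export
print.uptake_fit <- function(x, ...) {
  cat("Cellular uptake fit:",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$model)
  cat(sprintf("  residual norm %.4g on %d points\n", x$residual_norm,
              x$n_obs))
  invisible(x)
}
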