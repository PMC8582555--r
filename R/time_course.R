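#' Time-course container
#'
#' Amounts per compartment at sampled times. `values` is a times-by-
#' compartments matrix; the unit tag records whether values are fractions
#' of the injected amount (`"fraction"`), percent injected dose per gram
#' (`"pct_id_per_g"`), or arbitrary concentration units (`"arbitrary"`).
#'
#' @param times strictly increasing sample times (h), all `>= 0`.
#' @param values numeric matrix, `length(times)` rows, one column per
#'   compartment (column names required).
#' @param sd optional matrix of per-point standard deviations, same shape.
#' @param unit one of `"fraction"`, `"pct_id_per_g"`, `"arbitrary"`.
#' @return An object of class `time_course`.
#' @export
time_course <- function(times, values, sd = NULL,
                        unit = c("fraction", "pct_id_per_g", "arbitrary")) {
  unit <- match.arg(unit)
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("'values' must have compartment column names", call. = FALSE)
  }
  if (length(times) != nrow(values)) {
    stop("length(times) must equal nrow(values)", call. = FALSE)
  }
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("'times' must be strictly increasing and >= 0", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("all values must be finite", call. = FALSE)
  }
  if (unit == "fraction" && any(values > 1 + 1e-6)) {
    stop("fraction-unit values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(sd)) {
    sd <- as.matrix(sd)
    if (!identical(dim(sd), dim(values))) {
      stop("'sd' must match the shape of 'values'", call. = FALSE)
    }
    dimnames(sd) <- dimnames(values)
  }
  structure(list(times = times, values = values, sd = sd, unit = unit),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("Time course:", length(x$times), "times x", ncol(x$values),
      "compartments [", x$unit, "]\n")
  cat("  t in [", min(x$times), ",", max(x$times), "] h;  compartments:",
      paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.time_course <- function(x, ...) {
  comps <- colnames(x$values)
  out <- data.frame(
    time_h = rep(x$times, times = length(comps)),
    compartment = rep(comps, each = length(x$times)),
    value = as.vector(x$values),
    stringsAsFactors = FALSE
  )
  out$sd <- if (is.null(x$sd)) NA_real_ else as.vector(x$sd)
  out
}

#' Injection protocol
#'
#' Describes the bolus administered at time zero. Intravenous injections
#' target the blood compartment, intratumoral injections the tumor; the
#' amount is dimensionless with 1.0 meaning 100% of the injected dose.
#'
#' @param mode `"intratumoral"` or `"intravenous"`.
#' @param amount injected amount, `> 0` (default 1.0).
#' @return An object of class `injection_protocol` with elements `mode`,
#'   `compartment`, `amount`.
#' @export
#' @examples
#' injection("intravenous")
injection <- function(mode = c("intratumoral", "intravenous"), amount = 1.0) {
  mode <- match.arg(mode)
  if (!is.finite(amount) || amount <= 0) {
    stop("injected amount must be > 0", call. = FALSE)
  }
  structure(list(mode = mode,
                 compartment = switch(mode, intravenous = "blood",
                                      intratumoral = "tumor"),
                 amount = amount),
            class = "injection_protocol")
}

# Shared linear-compartment integrator. Constant coefficient matrix A, bolus
# x0; stiff solver because rates span ~1e-5 to ~900 1/h.
solve_linear_system <- function(A, x0, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(x0) == nrow(A))
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  tt <- times
  prepend0 <- length(tt) == 0L || tt[1L] > 0
  if (prepend0) tt <- c(0, tt)
  deriv <- function(t, x, parms) list(as.vector(parms %*% x))
  jac <- function(t, x, parms) parms
  sol <- deSolve::ode(y = x0, times = tt, func = deriv, parms = A,
                      method = "lsoda", jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1L] < 0) {
    stop("ODE integration failed (istate ",
         attr(sol, "istate")[1L], "); check rates and times", call. = FALSE)
  }
  out <- unname(sol[, -1L, drop = FALSE])
  if (prepend0) out <- out[-1L, , drop = FALSE]
  colnames(out) <- rownames(A)
  out
}

#' Simulate whole-body biodistribution
#'
#' Integrates `dx/dt = A x` from a single bolus, returning the amount in
#' every compartment (including the excretion sink) at the requested
#' times as fractions of the injected amount. Total amount is conserved
#' because the rate matrix columns sum to zero.
#'
#' @param A rate matrix from [rate_matrix()].
#' @param protocol an [injection()] protocol; its target compartment must
#'   exist in `A`.
#' @param times sorted, non-negative sample times (h).
#' @param rtol,atol solver tolerances (defaults 1e-8 / 1e-10; the rate
#'   spread makes the system stiff).
#' @return A [time_course()] in fraction units.
#' @export
#' @examples
#' topo <- mouse_topology()
#' A <- rate_matrix(topo, mouse_transfer_rates())
#' tc <- simulate_biodistribution(A, injection("intratumoral"),
#'                                times = seq(0, 24, by = 1))
#' rowSums(tc$values)  # all 1
simulate_biodistribution <- function(A, protocol, times,
                                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "injection_protocol"))
  comps <- rownames(A)
  if (!protocol$compartment %in% comps) {
    stop("injection target '", protocol$compartment,
         "' is not a model compartment", call. = FALSE)
  }
  x0 <- stats::setNames(numeric(length(comps)), comps)
  x0[protocol$compartment] <- protocol$amount
  vals <- solve_linear_system(A, x0, times, rtol = rtol, atol = atol)
  vals[vals < 0 & vals > -1e-9] <- 0
  time_course(times, pmin(vals, protocol$amount * (1 + 1e-9)) /
                protocol$amount, unit = "fraction")
}

#' Nominal organ masses for a 21 g laboratory mouse
#'
#' A convenience mass table (grams) for converting fractional retention to
#' percent injected dose per gram. These are nominal textbook-style organ
#' masses for a 21 g mouse, not measured values from any specific animal
#' or study; replace them with measured masses for real analyses.
#'
#' @return Named numeric vector of organ masses in grams.
#' @export
default_mouse_organ_masses <- function() {
  c(blood = 1.5, tumor = 0.5, liver = 1.1, spleen = 0.10, kidneys = 0.32,
    colon = 0.30, stomach = 0.25, lungs = 0.16, small_intestine = 1.1,
    muscle = 8.0, bone = 2.1, skin = 3.2, brain = 0.42, heart = 0.14)
}

#' Convert a fractional time course to %ID/g
#'
#' `value = 100 * fraction / mass_g`, the standard biodistribution unit of
#' percent injected dose per gram of tissue. Compartments with no supplied
#' mass (e.g. the excretion sink) are dropped with a warning.
#'
#' @param tc a [time_course()] in fraction units.
#' @param organ_masses named numeric vector of organ masses (g), all `> 0`.
#' @return A [time_course()] tagged `pct_id_per_g`.
#' @seealso [from_percent_id_per_gram()] for the inverse.
#' @export
to_percent_id_per_gram <- function(tc,
                                   organ_masses = default_mouse_organ_masses()) {
  stopifnot(inherits(tc, "time_course"))
  if (tc$unit != "fraction") {
    stop("input time course must be in fraction units", call. = FALSE)
  }
  if (any(!is.finite(organ_masses)) || any(organ_masses <= 0)) {
    stop("organ masses must be finite and > 0", call. = FALSE)
  }
  comps <- colnames(tc$values)
  keep <- comps[comps %in% names(organ_masses)]
  dropped <- setdiff(comps, keep)
  if (length(dropped)) {
    warning("dropping compartment(s) without a mass: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (!length(keep)) stop("no compartment has a supplied mass", call. = FALSE)
  scale <- 100 / organ_masses[keep]
  vals <- sweep(tc$values[, keep, drop = FALSE], 2L, scale, `*`)
  sd <- if (is.null(tc$sd)) NULL else
    sweep(tc$sd[, keep, drop = FALSE], 2L, scale, `*`)
  time_course(tc$times, vals, sd = sd, unit = "pct_id_per_g")
}

#' Convert a %ID/g time course back to fractions
#'
#' @inheritParams to_percent_id_per_gram
#' @export
from_percent_id_per_gram <- function(tc,
                                     organ_masses = default_mouse_organ_masses()) {
  stopifnot(inherits(tc, "time_course"))
  if (tc$unit != "pct_id_per_g") {
    stop("input time course must be in %ID/g units", call. = FALSE)
  }
  comps <- colnames(tc$values)
  if (!all(comps %in% names(organ_masses))) {
    stop("missing mass for: ",
         paste(setdiff(comps, names(organ_masses)), collapse = ", "),
         call. = FALSE)
  }
  scale <- organ_masses[comps] / 100
  vals <- sweep(tc$values, 2L, scale, `*`)
  sd <- if (is.null(tc$sd)) NULL else sweep(tc$sd, 2L, scale, `*`)
  time_course(tc$times, vals, sd = sd, unit = "fraction")
}
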