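#' Linear-quadratic survival with a per-DSB lethality factor
#'
#' The DSB-interpreted linear-quadratic model
#' `S = exp(-p * (alpha*D + beta*D^2))`, where `alpha*D + beta*D^2` is the
#' expected number of double strand breaks at dose `D` and `p` the average
#' probability that one DSB kills the cell.
#'
#' @param dose absorbed dose in Gy, `>= 0` (vectorized).
#' @param alpha linear DSB-yield coefficient (1/Gy).
#' @param beta quadratic DSB-yield coefficient (1/Gy^2).
#' @param p per-DSB cell-death probability (natural scale).
#' @return Survival fraction(s) in (0, 1].
#' @export
#' @examples
#' lq_survival(2, alpha = 0.1, beta = 0.01)  # exp(-0.24)
lq_survival <- function(dose, alpha, beta, p = 1) {
  if (any(!is.finite(dose)) || any(dose < 0)) {
    stop("'dose' must be finite and >= 0", call. = FALSE)
  }
  if (any(c(alpha, beta, p) < 0)) {
    stop("alpha, beta, p must be >= 0", call. = FALSE)
  }
  exp(-p * (alpha * dose + beta * dose^2))
}

#' Survival from a DSB count
#'
#' `S = exp(-p * DSB)`: dose is replaced by the number of double strand
#' breaks produced in the cell.
#'
#' @param dsb DSB count(s), `>= 0`.
#' @param p per-DSB cell-death probability (natural scale, e.g. 9.944e-3).
#' @return Survival fraction(s).
#' @export
survival_from_dsb <- function(dsb, p) {
  if (any(!is.finite(dsb)) || any(dsb < 0)) {
    stop("'dsb' must be finite and >= 0", call. = FALSE)
  }
  if (any(p < 0)) stop("'p' must be >= 0", call. = FALSE)
  exp(-p * dsb)
}

#' Cell-death model parameters (class I)
#'
#' Parameters of the class I DSB-complexity survival model
#' `S = (q0 + k1*DSB + k2*DSB^2) * exp(-p*DSB)`. `k1`, `k2`, and `p` are
#' entered on their conventional printed scales (`1e-3`, `1e-5`, `1e-3`)
#' so published values can be typed verbatim; the evaluation functions
#' rescale internally.
#'
#' @param q0 repair-capacity intercept (dimensionless, `> 0`).
#' @param k1 repair-capacity slope, units 1e-3 per DSB.
#' @param k2 repair-capacity curvature, units 1e-5 per DSB^2 (typically
#'   negative: repair capacity falls at high damage loads).
#' @param p per-DSB death probability, units 1e-3 per DSB.
#' @return An object of class `survival_params` with `model = "I"`.
#' @export
#' @examples
#' survival_params_I(1.090, 5.917, -1.879, 9.944)
survival_params_I <- function(q0, k1, k2, p) {
  if (!is.finite(q0) || q0 <= 0) stop("'q0' must be > 0", call. = FALSE)
  structure(list(model = "I", q0 = q0, k1 = k1, k2 = k2, p = p),
            class = "survival_params")
}

#' Cell-death model parameters (class II)
#'
#' Class II splits the lethality by DSB complexity:
#' `S = (q0 + k1*DSB + k2*DSB^2) * exp(-p0*DSB_0 - pstar*DSB_*)` with
#' `DSB = DSB_0 + DSB_*`. Scales as in [survival_params_I()]; `p0` and
#' `pstar` are in units of 1e-3 per simple/complex DSB.
#'
#' @inheritParams survival_params_I
#' @param p0 death probability per simple DSB, units 1e-3.
#' @param pstar death probability per complex DSB, units 1e-3.
#' @return An object of class `survival_params` with `model = "II"`.
#' @export
#' @examples
#' survival_params_II(1.037, 7.275, -2.296, 3.088, 30.68)
survival_params_II <- function(q0, k1, k2, p0, pstar) {
  if (!is.finite(q0) || q0 <= 0) stop("'q0' must be > 0", call. = FALSE)
  structure(list(model = "II", q0 = q0, k1 = k1, k2 = k2, p0 = p0,
                 pstar = pstar),
            class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat("Cell-death model class", x$model, "\n")
  cat(sprintf("  q0 = %.4g, k1 = %.4g e-3, k2 = %.4g e-5\n",
              x$q0, x$k1, x$k2))
  if (x$model == "I") {
    cat(sprintf("  p = %.4g e-3 per DSB\n", x$p))
  } else {
    cat(sprintf("  p0 = %.4g e-3 per DSB_0, p* = %.4g e-3 per DSB_*\n",
                x$p0, x$pstar))
  }
  invisible(x)
}

#' Repair capacity polynomial
#'
#' `q(DSB) = q0 + k1*1e-3*DSB + k2*1e-5*DSB^2`, the cell's tolerance of
#' DSB damage; with negative `k2` it declines, and eventually turns
#' negative, at high damage loads.
#'
#' @param dsb DSB count(s), `>= 0`.
#' @param q0 intercept.
#' @param k1 slope on the 1e-3 scale.
#' @param k2 curvature on the 1e-5 scale.
#' @return q value(s).
#' @export
#' @examples
#' repair_capacity(100, 1.090, 5.917, -1.879)  # 1.090 + 0.5917 - 0.1879
repair_capacity <- function(dsb, q0, k1, k2) {
  if (any(!is.finite(dsb)) || any(dsb < 0)) {
    stop("'dsb' must be finite and >= 0", call. = FALSE)
  }
  q0 + k1 * 1e-3 * dsb + k2 * 1e-5 * dsb^2
}

#' Class I cell survival
#'
#' `S = q(DSB) * exp(-p * DSB)` with `q` from [repair_capacity()]. No
#' clamping is applied: with `q0 > 1` the survival exceeds 1 at very low
#' damage, and with negative `k2` the value can turn negative at very
#' high damage; a warning is emitted for negative q.
#'
#' @param params a [survival_params_I()] object.
#' @param dsb DSB count(s), `>= 0`.
#' @return Survival fraction(s).
#' @export
survival_class_I <- function(params, dsb) {
  stopifnot(inherits(params, "survival_params"), params$model == "I")
  q <- repair_capacity(dsb, params$q0, params$k1, params$k2)
  if (any(q < 0)) {
    warning("repair capacity q is negative at DSB >= ",
            min(dsb[q < 0]), "; survival returned as the negative product",
            call. = FALSE)
  }
  q * exp(-params$p * 1e-3 * dsb)
}

#' Class II cell survival
#'
#' `S = q(DSB_0 + DSB_*) * exp(-p0*DSB_0 - pstar*DSB_*)`.
#'
#' @param params a [survival_params_II()] object.
#' @param dsb0 simple-DSB count(s), `>= 0`.
#' @param dsbstar complex-DSB count(s), `>= 0`.
#' @return Survival fraction(s).
#' @export
survival_class_II <- function(params, dsb0, dsbstar) {
  stopifnot(inherits(params, "survival_params"), params$model == "II")
  if (any(!is.finite(dsb0)) || any(dsb0 < 0) ||
      any(!is.finite(dsbstar)) || any(dsbstar < 0)) {
    stop("DSB counts must be finite and >= 0", call. = FALSE)
  }
  dsb <- dsb0 + dsbstar
  q <- repair_capacity(dsb, params$q0, params$k1, params$k2)
  if (any(q < 0)) {
    warning("repair capacity q is negative at DSB >= ",
            min(dsb[q < 0]), "; survival returned as the negative product",
            call. = FALSE)
  }
  q * exp(-(params$p0 * dsb0 + params$pstar * dsbstar) * 1e-3)
}

#' Fit the class I or II cell-death model to survival data
#'
#' Least-squares fit on log-survival (uniform weights): survival spans
#' decades, so the log scale balances the low- and high-damage points.
#' Data points with non-positive survival (possible when the generating
#' model's q polynomial turns negative) are dropped with a warning, as
#' they have no log. R-squared is reported on the log scale.
#'
#' @param data data frame with columns `dsb_total`, `survival`, and for
#'   class II also `dsb0`, `dsbstar`; at least 5 points spanning a DSB
#'   range (class II additionally needs variation in the simple-DSB
#'   fraction).
#' @param model `"I"` or `"II"`.
#' @param init numeric initial guesses on the printed scales:
#'   `c(q0, k1, k2, p)` for class I, `c(q0, k1, k2, p0, pstar)` for
#'   class II. The default is a log-linear pre-fit with `k1 = k2 = 0`,
#'   which lands near the global optimum.
#' @param control list passed to [minpack.lm::nls.lm.control()].
#' @return An object of class `survival_fit` with the fitted
#'   `survival_params`, log-scale `r_squared`, and convergence flag.
#' @export
#' @examples
#' truth <- survival_params_I(1.090, 5.917, -1.879, 9.944)
#' d <- generate_survival_dataset(truth, dsb_grid = seq(0, 400, 25))
#' fit <- fit_survival_params(d, "I")
#' coef(fit)
fit_survival_params <- function(data, model = c("I", "II"),
                                init = NULL, control = list()) {
  model <- match.arg(model)
  data <- as.data.frame(data)
  if (!all(c("dsb_total", "survival") %in% names(data))) {
    stop("data need columns dsb_total, survival", call. = FALSE)
  }
  if (model == "II" && !all(c("dsb0", "dsbstar") %in% names(data))) {
    stop("class II data need columns dsb0, dsbstar", call. = FALSE)
  }
  bad <- !is.finite(data$survival) | data$survival <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with non-positive survival dropped ",
            "from the log-scale fit", call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) < 5) {
    stop("need at least 5 usable data points", call. = FALSE)
  }
  if (diff(range(data$dsb_total)) <= 0) {
    stop("degenerate design: DSB values are constant", call. = FALSE)
  }
  if (model == "II") {
    a0 <- ifelse(data$dsb_total > 0, data$dsb0 / data$dsb_total, NA)
    if (diff(range(a0, na.rm = TRUE)) < 1e-6) {
      stop("class II fit needs variation in the simple-DSB fraction a0",
           call. = FALSE)
    }
  }
  log_obs <- log(data$survival)
  if (is.null(init)) {
    # with k1 = k2 = 0 the model is log-linear in (log q0, p...): a
    # linear pre-fit gives a starting point close to the global optimum
    X <- if (model == "I") {
      cbind(1, -data$dsb_total * 1e-3)
    } else {
      cbind(1, -data$dsb0 * 1e-3, -data$dsbstar * 1e-3)
    }
    b <- qr.solve(X, log_obs)
    init <- c(exp(b[1L]), 0, 0, b[-1L])
  }
  model_log <- function(par) {
    q <- repair_capacity(data$dsb_total, par[1L], par[2L], par[3L])
    lin <- if (model == "I") {
      par[4L] * 1e-3 * data$dsb_total
    } else {
      (par[4L] * data$dsb0 + par[5L] * data$dsbstar) * 1e-3
    }
    # smooth first-order extension of log(q) below q_min keeps the
    # objective differentiable when an iterate drives q non-positive
    q_min <- 1e-4
    log_q <- ifelse(q > q_min, log(pmax(q, q_min)),
                    log(q_min) + (q - q_min) / q_min)
    log_q - lin
  }
  fn <- function(par) model_log(par) - log_obs
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  utils::modifyList(list(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14), control))
  fit <- minpack.lm::nls.lm(par = init, fn = fn, control = ctrl)
  par <- fit$par
  params <- if (model == "I") {
    survival_params_I(par[1L], par[2L], par[3L], par[4L])
  } else {
    survival_params_II(par[1L], par[2L], par[3L], par[4L], par[5L])
  }
  ss_res <- sum(fit$fvec^2)
  ss_tot <- sum((log_obs - mean(log_obs))^2)
  structure(list(params = params,
                 r_squared = 1 - ss_res / ss_tot,
                 residual_norm = sqrt(ss_res),
                 converged = fit$info %in% 1:4,
                 message = fit$message, n_obs = nrow(data), model = model),
            class = "survival_fit")
}

#' @export
coef.survival_fit <- function(object, ...) {
  p <- object$params
  if (p$model == "I") {
    c(q0 = p$q0, k1 = p$k1, k2 = p$k2, p = p$p)
  } else {
    c(q0 = p$q0, k1 = p$k1, k2 = p$k2, p0 = p$p0, pstar = p$pstar)
  }
}

#' @export
print.survival_fit <- function(x, ...) {
  cat("Cell-death model fit,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$params)
  cat(sprintf("  R^2 (log scale) = %.4f on %d points\n", x$r_squared,
              x$n_obs))
  invisible(x)
}
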