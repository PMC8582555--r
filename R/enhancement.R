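#' DSB damage enhancement factor
#'
#' `EF_DSB = DSB_G / DSB_NG`: the ratio of mean DSBs per source particle
#' with the nanoparticle present to without.
#'
#' @param dsb_g mean DSB count with nanoparticle.
#' @param dsb_ng mean DSB count without nanoparticle, `> 0`.
#' @return The enhancement factor (vectorized).
#' @export
#' @examples
#' ef_dsb(55, 50)  # 1.1
ef_dsb <- function(dsb_g, dsb_ng) {
  if (any(!is.finite(dsb_ng)) || any(dsb_ng <= 0)) {
    stop("'dsb_ng' must be > 0", call. = FALSE)
  }
  if (any(!is.finite(dsb_g)) || any(dsb_g < 0)) {
    stop("'dsb_g' must be finite and >= 0", call. = FALSE)
  }
  dsb_g / dsb_ng
}

#' Survival-fraction enhancement factor (direct)
#'
#' `EF_SF = S_NG / S_G`: survival without nanoparticle over survival
#' with. Note the inversion relative to [ef_dsb()] - enhancement kills
#' more cells, so lower `S_G` means a larger factor.
#'
#' @param s_ng survival fraction without nanoparticle.
#' @param s_g survival fraction with nanoparticle, `> 0`.
#' @return The enhancement factor.
#' @export
#' @examples
#' ef_sf_direct(0.5, 0.25)  # 2
ef_sf_direct <- function(s_ng, s_g) {
  if (any(!is.finite(s_g)) || any(s_g <= 0)) {
    stop("'s_g' must be > 0", call. = FALSE)
  }
  s_ng / s_g
}

#' Predicted survival enhancement from DSB enhancement (class I)
#'
#' `EF_SF = exp(p * DSB_NG * (EF_DSB - 1))`, the survival enhancement
#' implied by the class I model when the repair-capacity factor q is
#' treated as common to both conditions and cancels.
#'
#' @param params a [survival_params_I()] object (p on the 1e-3 scale).
#' @param dsb_ng mean DSB count without nanoparticle, `>= 0`.
#' @param ef_dsb DSB enhancement factor, `> 0`.
#' @return Predicted `EF_SF`.
#' @export
ef_sf_predicted_I <- function(params, dsb_ng, ef_dsb) {
  stopifnot(inherits(params, "survival_params"), params$model == "I")
  if (any(dsb_ng < 0)) stop("'dsb_ng' must be >= 0", call. = FALSE)
  if (any(ef_dsb <= 0)) stop("'ef_dsb' must be > 0", call. = FALSE)
  exp(params$p * 1e-3 * dsb_ng * (ef_dsb - 1))
}

#' Predicted survival enhancement from DSB enhancement (class II)
#'
#' `EF_SF = exp((p0*a0 + pstar*astar) * DSB_NG * (EF_DSB - 1))`, with
#' `a0`/`astar` the simple/complex DSB fractions (summing to 1).
#'
#' @param params a [survival_params_II()] object.
#' @param a0 fraction of simple DSBs.
#' @param astar fraction of complex DSBs (default `1 - a0`).
#' @inheritParams ef_sf_predicted_I
#' @return Predicted `EF_SF`.
#' @export
ef_sf_predicted_II <- function(params, dsb_ng, ef_dsb, a0,
                               astar = 1 - a0) {
  stopifnot(inherits(params, "survival_params"), params$model == "II")
  if (any(abs(a0 + astar - 1) > 1e-9)) {
    stop("DSB fractions must satisfy a0 + astar = 1", call. = FALSE)
  }
  if (any(a0 < 0) || any(astar < 0)) {
    stop("DSB fractions must be >= 0", call. = FALSE)
  }
  if (any(dsb_ng < 0)) stop("'dsb_ng' must be >= 0", call. = FALSE)
  if (any(ef_dsb <= 0)) stop("'ef_dsb' must be > 0", call. = FALSE)
  exp((params$p0 * a0 + params$pstar * astar) * 1e-3 * dsb_ng *
        (ef_dsb - 1))
}

#' Consistency check of the predicted vs exact survival enhancement
#'
#' The closed-form predictions drop the repair-capacity ratio
#' `q(DSB_NG)/q(DSB_G)`, which is only exact when q is constant. This
#' report computes both the prediction and the exact model ratio
#' (q included) side by side so the approximation error is visible.
#'
#' @param params a class I or II `survival_params` object.
#' @param dsb_ng mean DSB count without nanoparticle.
#' @param ef_dsb DSB enhancement factor.
#' @param a0 simple-DSB fraction (class II only; assumed equal in both
#'   conditions).
#' @return A list with `predicted`, `exact`, and the dropped `q_ratio`
#'   (`exact = predicted * q_ratio`).
#' @export
ef_consistency <- function(params, dsb_ng, ef_dsb, a0 = NULL) {
  stopifnot(inherits(params, "survival_params"))
  dsb_g <- ef_dsb * dsb_ng
  if (params$model == "I") {
    predicted <- ef_sf_predicted_I(params, dsb_ng, ef_dsb)
    s_ng <- survival_class_I(params, dsb_ng)
    s_g <- survival_class_I(params, dsb_g)
  } else {
    if (is.null(a0)) stop("class II needs 'a0'", call. = FALSE)
    predicted <- ef_sf_predicted_II(params, dsb_ng, ef_dsb, a0)
    s_ng <- survival_class_II(params, a0 * dsb_ng, (1 - a0) * dsb_ng)
    s_g <- survival_class_II(params, a0 * dsb_g, (1 - a0) * dsb_g)
  }
  exact <- s_ng / s_g
  q_ratio <- repair_capacity(dsb_ng, params$q0, params$k1, params$k2) /
    repair_capacity(dsb_g, params$q0, params$k1, params$k2)
  list(predicted = predicted, exact = exact, q_ratio = q_ratio)
}
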