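#' Tumor radius predicted by the analytical model
#'
#' The mean radiological radius follows the piecewise law
#' \deqn{R(t) = R_0 + v t \quad (t < 0)}
#' \deqn{R(t) = R_0 + v t - k (1 - e^{-t/\tau}) \quad (t \ge 0)}
#' Before radiotherapy the tumor grows linearly at its asymptotic speed;
#' from t = 0 an exponentially fading death term of amplitude `k` and
#' characteristic time `tau` is superposed. The curve is continuous at
#' t = 0 and, when `k/(tau v) > 1`, has a single post-treatment minimum.
#'
#' @param params A [model_params()] object (or coercible numeric of length 4).
#' @param t Numeric vector of times in years relative to the start of
#'   radiotherapy.
#'
#' @return Numeric vector of radii in mm, one per time.
#' @examples
#' p <- model_params(17.95, 0.50, 7.29, 1.98)
#' radius_at(p, c(-1, 0, 1, 4))
#' @export
radius_at <- function(params, t) {
  p <- as_model_params(params)
  t <- as.numeric(t)
  r <- p[["R0"]] + p[["v"]] * t
  pos <- t >= 0
  if (any(pos))
    r[pos] <- r[pos] - p[["k"]] * (1 - exp(-t[pos] / p[["tau"]]))
  r
}

# Closed-form regrowth time, vectorized over parameter columns. NA_real_
# encodes the no-shrinkage sentinel (radius never decreases after RT).
tmin_formula <- function(v, k, tau) {
  if (any(tau <= 0) || any(v <= 0))
    stop("regrowth time requires tau > 0 and v > 0", call. = FALSE)
  ratio <- k / (tau * v)
  ifelse(ratio >= 1, tau * log(pmax(ratio, 1)), NA_real_)
}

#' Regrowth time of the modeled tumor
#'
#' Time after radiotherapy at which the modeled radius reaches its minimum
#' and regrowth starts: \eqn{t_{min} = \tau \ln(k/(\tau v))}, defined when
#' the collapse initially outruns growth (`k/(tau v) >= 1`). When
#' `k/(tau v) < 1` the radius never decreases and `NA` is returned as a
#' no-shrinkage sentinel; downstream Monte-Carlo summaries count and
#' exclude such replicates.
#'
#' @param x A [model_params()] object, a [param_ensemble()] (one value per
#'   row), or a numeric vector of length 4.
#' @param ... Unused.
#'
#' @return Regrowth time(s) in years; `NA_real_` where the model predicts
#'   no shrinkage.
#' @examples
#' regrowth_time(model_params(17.95, 0.50, 7.29, 1.98)) # about 3.95 yr
#' @export
regrowth_time <- function(x, ...) UseMethod("regrowth_time")

#' @export
regrowth_time.model_params <- function(x, ...) {
  tmin_formula(x[["v"]], x[["k"]], x[["tau"]])
}

#' @export
regrowth_time.param_ensemble <- function(x, ...) {
  tmin_formula(x$v, x$k, x$tau)
}

#' @export
regrowth_time.default <- function(x, ...) {
  regrowth_time(as_model_params(x))
}

#' Initial collapse speed after radiotherapy
#'
#' The speed at which the radius shrinks immediately after radiotherapy,
#' \eqn{v_d = k/\tau} (mm/yr), the linear coefficient of the death term in
#' the small-time expansion of the model.
#'
#' @inheritParams regrowth_time
#' @return Collapse speed(s) in mm/yr.
#' @examples
#' collapse_speed(model_params(17.95, 0.50, 7.29, 1.98))
#' @export
collapse_speed <- function(x, ...) UseMethod("collapse_speed")

#' @export
collapse_speed.model_params <- function(x, ...) x[["k"]] / x[["tau"]]

#' @export
collapse_speed.param_ensemble <- function(x, ...) x$k / x$tau

#' @export
collapse_speed.default <- function(x, ...) collapse_speed(as_model_params(x))

#' Small-time quadratic expansion of the radius model
#'
#' Expanding the model just after radiotherapy gives
#' \deqn{R(t) = R_0 + (v - v_d) t + \epsilon t^2/2 + O(t^3)}
#' with collapse speed \eqn{v_d = k/\tau} and curvature
#' \eqn{\epsilon = v_d/\tau}. The net slope `v - v_d` is what sparse early
#' measurements constrain best; the curvature carries the information
#' about `tau` and is invisible for slow responders measured shortly
#' after treatment.
#'
#' @param params A [model_params()] object (or coercible).
#' @return Named numeric vector `(constant, slope, curvature)` in
#'   (mm, mm/yr, mm/yr^2).
#' @examples
#' taylor_coefficients(model_params(17.95, 0.50, 7.29, 1.98))
#' @export
taylor_coefficients <- function(params) {
  p <- as_model_params(params)
  vd <- p[["k"]] / p[["tau"]]
  c(constant = p[["R0"]], slope = p[["v"]] - vd, curvature = vd / p[["tau"]])
}
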