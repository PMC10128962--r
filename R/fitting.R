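#' Chi-square goodness of fit of a follow-up
#'
#' Sum of squared, error-normalized residuals between the measured radii
#' and the model curve:
#' \deqn{\chi^2 = \sum_i [R_i - R(t_i)]^2 / \sigma_i^2}
#' with a common measurement error `sigma` (1 mm by default).
#'
#' @param params A [model_params()] object (or coercible).
#' @param fu A [follow_up()].
#' @return Non-negative scalar; 0 iff the model interpolates every point.
#' @export
chi2 <- function(params, fu) {
  stopifnot(inherits(fu, "follow_up"))
  if (length(fu$t) < 1L) stop("empty follow-up", call. = FALSE)
  sum(((fu$R - radius_at(params, fu$t)) / fu$sigma)^2)
}

#' Quadratic constraint penalty from an ensemble prior
#'
#' Projects the parameters onto the decorrelated basis, `X = T p`, and
#' scores their departure from the ensemble statistics:
#' \deqn{\chi^2_{cons} = \sum_{i=1}^{4} [(x_i - \mu_i)/\sigma_i]^2.}
#' Added to [chi2()], this acts as a Bayesian prior encoding the parameter
#' correlations observed across fitted patients, and makes fits with as
#' few as 3 points technically solvable.
#'
#' @param params A [model_params()] object (or coercible).
#' @param prior A [build_prior()] object.
#' @return Non-negative scalar.
#' @export
chi2_constraint <- function(params, prior) {
  stopifnot(inherits(prior, "constraint_prior"))
  p <- as.numeric(as_model_params(params))
  x <- drop(prior$T %*% p)
  sum(((x - prior$mu) / prior$sigma)^2)
}

# Residual vector for least-squares fitting: data residuals (R_i - R(t_i))/sigma,
# optionally followed by prior residuals (T p - mu)/sigma_prior. The summed
# squares equal chi2 (+ chi2_constraint).
fit_residuals <- function(par, fu, prior = NULL) {
  r <- (fu$R - radius_model_raw(par, fu$t)) / fu$sigma
  if (!is.null(prior)) {
    x <- drop(prior$T %*% par)
    r <- c(r, (x - prior$mu) / prior$sigma)
  }
  r
}

# Unchecked model evaluation on a bare numeric (R0, v, k, tau); the optimizer
# may probe the box boundary where the classed constructor would be too strict.
radius_model_raw <- function(par, t) {
  r <- par[1L] + par[2L] * t
  pos <- t >= 0
  if (any(pos)) r[pos] <- r[pos] - par[3L] * (1 - exp(-t[pos] / par[4L]))
  r
}

# Analytic Jacobian of fit_residuals with respect to (R0, v, k, tau).
fit_jacobian <- function(par, fu, prior = NULL) {
  t <- fu$t
  k <- par[3L]; tau <- par[4L]
  pos <- t >= 0
  e <- exp(-pmax(t, 0) / tau)
  dR <- cbind(rep(1, length(t)),
              t,
              ifelse(pos, -(1 - e), 0),
              ifelse(pos, k * t * e / tau^2, 0))
  J <- -dR / fu$sigma
  if (!is.null(prior)) J <- rbind(J, prior$T / prior$sigma)
  J
}

# Deterministic multi-start grid: R0 anchored at the radius nearest t = 0;
# v over the clinical range; (k, tau) paired as a shallow/fast and a
# deep/slow decay. Starts are clamped into the bounds.
fit_starts <- function(fu, bounds) {
  R0s <- fu$R[which.min(abs(fu$t))]
  starts <- list()
  for (v0 in c(0.5, 1, 2, 4))
    for (kt in list(c(0.25 * R0s, 0.3), c(0.75 * R0s, 1.5)))
      starts[[length(starts) + 1L]] <- c(R0 = R0s, v = v0, k = kt[1L],
                                         tau = kt[2L])
  lapply(starts, function(s) pmin(pmax(s, bounds$lower), bounds$upper))
}

# Shared engine behind fit_plain / fit_constrained.
fit_engine <- function(fu, prior, bounds, mode) {
  starts <- fit_starts(fu, bounds)
  results <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    results[[i]] <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = starts[[i]],
                         lower = bounds$lower, upper = bounds$upper,
                         fn = fit_residuals, jac = fit_jacobian,
                         fu = fu, prior = prior,
                         control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
  }
  ok <- !vapply(results, is.null, logical(1L))
  if (!any(ok)) {
    cond <- structure(
      class = c("gliomaRT_nonconvergence", "error", "condition"),
      list(message = sprintf("all %d starts failed for patient %s",
                             length(starts), fu$patient_id),
           call = sys.call(-1), best = NULL))
    stop(cond)
  }
  results <- results[ok]
  obj <- vapply(results, stats::deviance, numeric(1L))
  # tie-break: among objectives within 1e-9 of the best, smallest tau wins
  near <- which(obj <= min(obj) + 1e-9)
  taus <- vapply(results[near], function(r) r$par[["tau"]], numeric(1L))
  best <- results[[near[which.min(taus)]]]
  structure(list(params = as_model_params(best$par),
                 objective_value = stats::deviance(best),
                 mode = mode,
                 converged = best$info %in% 1:4,
                 n_points = length(fu$t)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mode = %s, n = %d, objective = %.4g, converged = %s\n",
              x$mode, x$n_points, x$objective_value, x$converged))
  print(x$params)
  tm <- regrowth_time(x$params)
  cat(sprintf("  regrowth time: %s\n",
              if (is.na(tm)) "no shrinkage" else sprintf("%.2f yr", tm)))
  invisible(x)
}

#' Unconstrained (plain chi-square) fit of a follow-up
#'
#' Minimizes [chi2()] over the parameter box using Levenberg-Marquardt
#' least squares from a deterministic grid of 8 starting points, guarding
#' against the ridge that couples `k` and `tau` on sparse data. Requires a
#' reasonably informative follow-up (at least 4 points covering both
#' sides of the radiotherapy date); use [fit_constrained()] for sparser
#' series.
#'
#' @param fu A [follow_up()] with >= 4 points spanning t <= 0 and t > 0.
#' @param bounds A [fit_bounds()] object; [default_bounds()] by default.
#' @return An object of class `"fit_result"`: list with elements `params`
#'   ([model_params()]), `objective_value`, `mode`, `converged`,
#'   `n_points`.
#' @examples
#' p <- model_params(17.95, 0.50, 7.29, 1.98)
#' fu <- follow_up("p0", seq(-2, 8, length.out = 12),
#'                 radius_at(p, seq(-2, 8, length.out = 12)))
#' fit_plain(fu)
#' @export
fit_plain <- function(fu, bounds = default_bounds()) {
  stopifnot(inherits(fu, "follow_up"), inherits(bounds, "fit_bounds"))
  if (length(fu$t) < 4L)
    stop("fit_plain needs at least 4 points; use fit_constrained for sparser follow-ups",
         call. = FALSE)
  if (!any(fu$t <= 0) || !any(fu$t > 0))
    stop("fit_plain needs points on both sides of the radiotherapy date",
         call. = FALSE)
  fit_engine(fu, prior = NULL, bounds = bounds, mode = "plain")
}

#' Constrained fit using the ensemble prior
#'
#' Minimizes the penalized objective [chi2()] + [chi2_constraint()]. The
#' prior supplies 4 extra quadratic pseudo-observations, so the problem is
#' solvable even with 3 measurements; on rich follow-ups the data term
#' dominates and the estimates coincide with [fit_plain()].
#'
#' @param fu A [follow_up()] with >= 1 point.
#' @param prior A [build_prior()] object.
#' @param bounds A [fit_bounds()] object.
#' @return A `"fit_result"`, as [fit_plain()].
#' @export
fit_constrained <- function(fu, prior, bounds = default_bounds()) {
  stopifnot(inherits(fu, "follow_up"), inherits(prior, "constraint_prior"),
            inherits(bounds, "fit_bounds"))
  fit_engine(fu, prior = prior, bounds = bounds, mode = "constrained")
}

#' Loose-constraint regrowth-time estimator from pre/post slopes
#'
#' Fits the continuous piecewise-linear skeleton of the model,
#' `R0 + v t` for t <= 0 and `R0 + (v - v_d) t` for t > 0, by ordinary
#' least squares in the three unknowns `(R0, v, v_d)` with a shared
#' intercept at t = 0, then converts the collapse speed through the
#' empirical power law \eqn{t_{min} = a / v_d^{\,b}}. Only the
#' best-constrained (linear) information in the data is used, which
#' removes the prior's pull towards its mean at the price of a larger
#' variance.
#'
#' @param fu A [follow_up()] with >= 2 points at t <= 0 and >= 2 at t > 0.
#' @param powerlaw Numeric `c(a, b)` of the power law (see
#'   [fit_powerlaw()]); `a` in yr (mm/yr)^b, `b` dimensionless.
#' @return A list of class `"loose_fit"`: `t_min` (years), `R0`, `v`,
#'   `v_d` (the fitted slopes, mm and mm/yr).
#' @export
fit_loose <- function(fu, powerlaw) {
  stopifnot(inherits(fu, "follow_up"))
  powerlaw <- as.numeric(powerlaw)
  if (length(powerlaw) != 2L || any(!is.finite(powerlaw)) || powerlaw[1L] <= 0)
    stop("powerlaw must be c(a, b) with a > 0", call. = FALSE)
  pre <- fu$t <= 0
  if (sum(pre) < 2L || sum(!pre) < 2L)
    stop("fit_loose needs >= 2 points before and >= 2 after radiotherapy",
         call. = FALSE)
  X <- cbind(1, fu$t, -pmax(fu$t, 0))
  beta <- stats::lm.fit(X, fu$R)$coefficients
  vd <- beta[[3L]]
  if (!is.finite(vd) || vd <= 0) {
    cond <- structure(
      class = c("gliomaRT_no_collapse", "error", "condition"),
      list(message = sprintf("fitted collapse speed is not positive (v_d = %.3g mm/yr): tumor not shrinking, no regrowth-time prediction",
                             vd),
           call = sys.call(-1)))
    stop(cond)
  }
  structure(list(t_min = powerlaw[1L] / vd^powerlaw[2L],
                 R0 = beta[[1L]], v = beta[[2L]], v_d = vd),
            class = "loose_fit")
}

#' @export
print.loose_fit <- function(x, ...) {
  cat(sprintf("<loose_fit> v = %.3g mm/yr, v_d = %.3g mm/yr -> t_min = %.2f yr\n",
              x$v, x$v_d, x$t_min))
  invisible(x)
}
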