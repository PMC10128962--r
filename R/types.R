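#' Model parameters of the tumor-radius model
#'
#' Bundles the four free parameters of the analytical radius model:
#' the radius at the start of radiotherapy (`R0`, mm), the asymptotic
#' radial growth speed (`v`, mm/yr), the amplitude of the
#' radiotherapy-induced decay (`k`, mm) and its characteristic time
#' (`tau`, yr).
#'
#' @param R0 Radius at t = 0 (start of radiotherapy), in mm. Must be > 0.
#' @param v Asymptotic radial speed in mm/yr. Must be > 0.
#' @param k Decay amplitude in mm. Must be >= 0.
#' @param tau Decay characteristic time in years. Must be > 0.
#'
#' @return A named numeric vector of class `"model_params"` with elements
#'   `R0`, `v`, `k`, `tau`.
#' @examples
#' model_params(R0 = 17.95, v = 0.50, k = 7.29, tau = 1.98)
#' @export
model_params <- function(R0, v, k, tau) {
  p <- c(R0 = as.numeric(R0), v = as.numeric(v),
         k = as.numeric(k), tau = as.numeric(tau))
  if (anyNA(p) || any(!is.finite(p)))
    stop("model parameters must be finite numbers", call. = FALSE)
  if (p[["R0"]] <= 0) stop("R0 must be > 0", call. = FALSE)
  if (p[["v"]] <= 0) stop("v must be > 0", call. = FALSE)
  if (p[["k"]] < 0) stop("k must be >= 0", call. = FALSE)
  if (p[["tau"]] <= 0) stop("tau must be > 0", call. = FALSE)
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> R0 = %.4g mm, v = %.4g mm/yr, k = %.4g mm, tau = %.4g yr\n",
              x[["R0"]], x[["v"]], x[["k"]], x[["tau"]]))
  invisible(x)
}

# Coerce a model_params, named/unnamed numeric of length 4, or list to the
# canonical classed vector. Internal.
as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x)) x <- unlist(x)
  if (!is.numeric(x) || length(x) != 4L)
    stop("expected a model_params object or a numeric vector of length 4",
         call. = FALSE)
  nm <- names(x)
  if (!is.null(nm) && all(c("R0", "v", "k", "tau") %in% nm))
    x <- x[c("R0", "v", "k", "tau")]
  model_params(x[[1L]], x[[2L]], x[[3L]], x[[4L]])
}

#' One patient's longitudinal radius follow-up
#'
#' A follow-up is an ordered series of mean radiological tumor-radius
#' measurements. Times are expressed in years relative to the start of
#' radiotherapy (t = 0), radii in mm. The measurement error, estimated
#' radiologically, defaults to 1 mm and is shared across time points.
#'
#' @param patient_id Opaque patient identifier (coerced to character).
#' @param t Numeric vector of measurement times in years relative to the
#'   start of radiotherapy. Must be strictly increasing.
#' @param R Numeric vector of measured mean radii in mm; all > 0.
#' @param sigma Measurement standard deviation in mm (default 1).
#'
#' @return An object of class `"follow_up"`: a list with elements
#'   `patient_id`, `t`, `R`, `sigma`.
#' @examples
#' follow_up("p1", t = c(-1, 0, 0.5, 1.5), R = c(19, 20, 18.2, 17.9))
#' @export
follow_up <- function(patient_id, t, R, sigma = 1.0) {
  t <- as.numeric(t); R <- as.numeric(R)
  if (length(t) < 1L) stop("a follow-up needs at least one measurement",
                           call. = FALSE)
  if (length(t) != length(R))
    stop("times and radii must have equal length", call. = FALSE)
  if (anyNA(t) || anyNA(R) || any(!is.finite(c(t, R))))
    stop("times and radii must be finite", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop(sprintf("times must be strictly increasing (patient %s)",
                 as.character(patient_id)[1L]), call. = FALSE)
  if (any(R <= 0))
    stop(sprintf("all radii must be > 0 (patient %s)",
                 as.character(patient_id)[1L]), call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number (mm)", call. = FALSE)
  structure(list(patient_id = as.character(patient_id)[1L],
                 t = t, R = R, sigma = as.numeric(sigma)),
            class = "follow_up")
}

#' @export
print.follow_up <- function(x, ...) {
  cat(sprintf("<follow_up> patient %s: %d measurements, t in [%.2f, %.2f] yr, sigma = %g mm\n",
              x$patient_id, length(x$t), min(x$t), max(x$t), x$sigma))
  invisible(x)
}

#' An ensemble of fitted model parameters across patients
#'
#' Collects per-patient best-fit parameter sets into a data frame, the raw
#' material for the statistical constraint prior. An optional `tmin` column
#' carries each entry's regrowth time in years.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param R0,v,k,tau Numeric vectors of per-patient parameters (see
#'   [model_params()] for units).
#' @param tmin Optional numeric vector of regrowth times in years.
#'
#' @return A data frame of class `"param_ensemble"` with one row per patient.
#' @export
param_ensemble <- function(patient_id, R0, v, k, tau, tmin = NULL) {
  patient_id <- as.character(patient_id)
  n <- length(patient_id)
  if (n < 2L) stop("an ensemble needs at least 2 entries", call. = FALSE)
  if (anyDuplicated(patient_id))
    stop("patient ids must be unique", call. = FALSE)
  lens <- lengths(list(R0, v, k, tau))
  if (any(lens != n)) stop("parameter columns must match the number of ids",
                           call. = FALSE)
  # validate each row through the scalar constructor
  for (i in seq_len(n)) model_params(R0[i], v[i], k[i], tau[i])
  d <- data.frame(patient_id = patient_id, R0 = as.numeric(R0),
                  v = as.numeric(v), k = as.numeric(k),
                  tau = as.numeric(tau), stringsAsFactors = FALSE)
  if (!is.null(tmin)) {
    if (length(tmin) != n) stop("tmin must match the number of ids",
                                call. = FALSE)
    d$tmin <- as.numeric(tmin)
  }
  class(d) <- c("param_ensemble", "data.frame")
  d
}

# Extract one row of an ensemble as model_params. Internal.
ensemble_params <- function(ens, i) {
  model_params(ens$R0[i], ens$v[i], ens$k[i], ens$tau[i])
}

# 4 x n parameter matrix (columns R0, v, k, tau). Internal.
ensemble_matrix <- function(ens) {
  as.matrix(as.data.frame(ens)[, c("R0", "v", "k", "tau")])
}

#' Box bounds for the model parameters
#'
#' Bounds used by the fitting routines. Defaults keep all parameters
#' strictly positive and restrict the asymptotic radial speed to the
#' clinically observed range 0.5--4 mm/yr; the remaining caps are loose.
#'
#' @param lower,upper Named numeric vectors with elements `R0`, `v`, `k`,
#'   `tau` (units as in [model_params()]).
#'
#' @return An object of class `"fit_bounds"`.
#' @examples
#' default_bounds()
#' @export
fit_bounds <- function(lower, upper) {
  nm <- c("R0", "v", "k", "tau")
  lower <- lower[nm]; upper <- upper[nm]
  if (anyNA(lower) || anyNA(upper))
    stop("bounds must name all of R0, v, k, tau", call. = FALSE)
  if (any(lower < 0)) stop("lower bounds must be >= 0", call. = FALSE)
  if (any(lower >= upper))
    stop("lower bounds must be strictly below upper bounds", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "fit_bounds")
}

#' @rdname fit_bounds
#' @export
default_bounds <- function() {
  fit_bounds(lower = c(R0 = 1e-6, v = 0.5, k = 1e-6, tau = 1e-6),
             upper = c(R0 = 100, v = 4, k = 100, tau = 20))
}

#' @export
print.fit_bounds <- function(x, ...) {
  cat("<fit_bounds>\n")
  print(rbind(lower = x$lower, upper = x$upper))
  invisible(x)
}

#' @export
`[.param_ensemble` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c("patient_id", "R0", "v", "k", "tau") %in% names(out)))
    class(out) <- c("param_ensemble", "data.frame")
  out
}
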