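#' Measurement design for virtual-patient studies
#'
#' The times at which the radius of a virtual patient is "measured" and
#' the Gaussian noise added to each measurement. The two designs studied
#' most are MRIs at \[-6, 0, +3\] months around radiotherapy and the same
#' with an extra point at 12 months.
#'
#' @param times Strictly increasing measurement times in years relative to
#'   the start of radiotherapy.
#' @param sigma Measurement noise standard deviation in mm (>= 0; 0 means
#'   noiseless).
#' @return An object of class `"measurement_design"`.
#' @examples
#' measurement_design(c(-6, 0, 3) / 12) # the early 3-MRI schedule
#' @export
measurement_design <- function(times, sigma = 1.0) {
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times))
    stop("times must be a non-empty numeric vector", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a single number >= 0", call. = FALSE)
  structure(list(times = times, sigma = as.numeric(sigma)),
            class = "measurement_design")
}

#' Simulate noisy radius measurements from a known model
#'
#' Evaluates the model at the design times and adds i.i.d. Gaussian noise
#' of standard deviation `design$sigma`.
#'
#' @param truth A [model_params()] object, the generating "true" model.
#' @param design A [measurement_design()].
#' @param seed Optional integer; when given, the draw is reproducible.
#' @param patient_id Identifier for the returned follow-up.
#' @return A [follow_up()]. Its `sigma` is the design noise (or 1 mm when
#'   the design is noiseless, so chi-square weights stay defined).
#' @export
simulate_measurements <- function(truth, design, seed = NULL,
                                  patient_id = "virtual") {
  stopifnot(inherits(design, "measurement_design"))
  truth <- as_model_params(truth)
  if (!is.null(seed)) set.seed(seed)
  R <- radius_at(truth, design$times) +
    stats::rnorm(length(design$times), 0, design$sigma)
  follow_up(patient_id, design$times, R,
            sigma = if (design$sigma > 0) design$sigma else 1.0)
}

# One replicate's t_min estimate, NA on any failure (degenerate replicate).
mc_one <- function(times, R, fu_sigma, estimator) {
  tryCatch({
    fu <- follow_up("mc", times, R, sigma = fu_sigma)
    estimator(fu)
  }, error = function(e) NA_real_)
}

# Shared Monte-Carlo loop. Noise is drawn as one stream and reshaped
# row-wise, so replicate i consumes a fixed block of the stream and
# enlarging n_reps leaves earlier replicates unchanged.
mc_engine <- function(truth, design, estimator, n_reps, seed) {
  truth <- as_model_params(truth)
  if (n_reps < 100L)
    stop("n_reps must be >= 100 for a stable distribution", call. = FALSE)
  nt <- length(design$times)
  set.seed(seed)
  eps <- matrix(stats::rnorm(n_reps * nt, 0, design$sigma),
                nrow = n_reps, byrow = TRUE)
  base <- radius_at(truth, design$times)
  fu_sigma <- if (design$sigma > 0) design$sigma else 1.0
  est <- vapply(seq_len(n_reps), function(i)
    mc_one(design$times, base + eps[i, ], fu_sigma, estimator), numeric(1L))
  finite <- est[is.finite(est)]
  n_deg <- n_reps - length(finite)
  if (n_deg > n_reps / 2) {
    cond <- structure(
      class = c("gliomaRT_unstable_prediction", "error", "condition"),
      list(message = sprintf("unstable prediction: %d of %d replicates degenerate",
                             n_deg, n_reps),
           call = sys.call(-1),
           samples = finite, n_degenerate = n_deg))
    stop(cond)
  }
  structure(list(samples = finite,
                 mean = mean(finite),
                 interval = stats::quantile(finite, c(0.05, 0.95),
                                            names = FALSE),
                 n_reps = n_reps,
                 n_degenerate = n_deg,
                 seed = seed),
            class = "prediction_distribution")
}

#' @export
print.prediction_distribution <- function(x, ...) {
  cat(sprintf("<prediction_distribution> %d replicates (%d degenerate)\n",
              x$n_reps, x$n_degenerate))
  cat(sprintf("  t_min: mean %.2f yr, [5%%, 95%%] = [%.2f, %.2f] yr\n",
              x$mean, x$interval[1L], x$interval[2L]))
  invisible(x)
}

#' Monte-Carlo regrowth-time prediction with the constrained fit
#'
#' Repeatedly simulates noisy measurements of a known "true" model at the
#' design times, fits each virtual follow-up with the constrained
#' objective, and collects the resulting regrowth-time estimates. The
#' summary is the mean and the empirical \[0.05, 0.95\] percentile
#' interval of the finite estimates; replicates that fail to fit or
#' predict no shrinkage are counted as degenerate and excluded.
#'
#' @param truth A [model_params()] object used as ground truth.
#' @param design A [measurement_design()].
#' @param prior A [build_prior()] object used by [fit_constrained()].
#' @param n_reps Number of replicates (>= 100; a few hundred suffices for
#'   a stable distribution).
#' @param seed Integer RNG seed; identical seeds give bit-identical
#'   results.
#' @param bounds A [fit_bounds()] object.
#' @return An object of class `"prediction_distribution"`: `samples`,
#'   `mean`, `interval`, `n_reps`, `n_degenerate`, `seed`.
#' @export
mc_predict <- function(truth, design, prior, n_reps = 1000L, seed = 1L,
                       bounds = default_bounds()) {
  stopifnot(inherits(design, "measurement_design"),
            inherits(prior, "constraint_prior"))
  mc_engine(truth, design,
            estimator = function(fu)
              regrowth_time(fit_constrained(fu, prior, bounds)$params),
            n_reps = n_reps, seed = seed)
}

#' Monte-Carlo prediction with the loose-constraint estimator
#'
#' As [mc_predict()], but each replicate is fitted with the slope-based
#' [fit_loose()] estimator and the collapse-speed power law. Replicates
#' whose fitted collapse speed is not positive carry no prediction and
#' are counted as degenerate.
#'
#' @inheritParams mc_predict
#' @param powerlaw Numeric `c(a, b)` as in [fit_loose()].
#' @return A `"prediction_distribution"`.
#' @export
mc_predict_loose <- function(truth, design, powerlaw, n_reps = 1000L,
                             seed = 1L) {
  stopifnot(inherits(design, "measurement_design"))
  if (sum(design$times <= 0) < 2L || sum(design$times > 0) < 2L)
    stop("the loose estimator needs >= 2 pre- and >= 2 post-radiotherapy times",
         call. = FALSE)
  mc_engine(truth, design,
            estimator = function(fu) fit_loose(fu, powerlaw)$t_min,
            n_reps = n_reps, seed = seed)
}

#' Cohort-wide Monte-Carlo study over an ensemble of true models
#'
#' Treats every ensemble row as a virtual patient's ground truth and runs
#' a Monte-Carlo prediction for each, returning one summary row per
#' patient. Per-patient seeds are derived deterministically from `seed`,
#' so the study is fully reproducible.
#'
#' @param ens A [param_ensemble()] of true models.
#' @param design A [measurement_design()].
#' @param prior A [build_prior()] object (required for
#'   `method = "constrained"`).
#' @param n_reps Replicates per patient.
#' @param seed Integer base seed.
#' @param method `"constrained"` (default) or `"loose"`.
#' @param powerlaw Power law `c(a, b)` for `method = "loose"`; defaults to
#'   the prior's attached law when present.
#' @param bounds A [fit_bounds()] object.
#' @return A data frame with columns `patient_id`, `truth_tmin_yr`,
#'   `mean_tmin_yr`, `p05_yr`, `p95_yr`, `n_degenerate`, `seed`. Patients
#'   whose prediction is unstable (> 50% degenerate replicates) get `NA`
#'   summaries.
#' @export
cohort_study <- function(ens, design, prior = NULL, n_reps = 1000L,
                         seed = 1L, method = c("constrained", "loose"),
                         powerlaw = NULL, bounds = default_bounds()) {
  stopifnot(inherits(ens, "param_ensemble"),
            inherits(design, "measurement_design"))
  method <- match.arg(method)
  if (method == "constrained" && !inherits(prior, "constraint_prior"))
    stop("method = 'constrained' needs a prior", call. = FALSE)
  if (method == "loose" && is.null(powerlaw)) {
    if (!is.null(prior$powerlaw)) powerlaw <- prior$powerlaw
    else stop("method = 'loose' needs a power law", call. = FALSE)
  }
  n <- nrow(ens)
  out <- data.frame(patient_id = ens$patient_id,
                    truth_tmin_yr = regrowth_time(ens),
                    mean_tmin_yr = NA_real_, p05_yr = NA_real_,
                    p95_yr = NA_real_, n_degenerate = NA_integer_,
                    seed = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seed_i <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    out$seed[i] <- seed_i
    pd <- tryCatch({
      truth <- ensemble_params(ens, i)
      if (method == "constrained")
        mc_predict(truth, design, prior, n_reps = n_reps, seed = seed_i,
                   bounds = bounds)
      else
        mc_predict_loose(truth, design, powerlaw, n_reps = n_reps,
                         seed = seed_i)
    }, gliomaRT_unstable_prediction = function(e) e)
    if (inherits(pd, "prediction_distribution")) {
      out$mean_tmin_yr[i] <- pd$mean
      out$p05_yr[i] <- pd$interval[1L]
      out$p95_yr[i] <- pd$interval[2L]
      out$n_degenerate[i] <- pd$n_degenerate
    } else {
      out$n_degenerate[i] <- pd$n_degenerate
    }
  }
  out
}

#' Truncated-follow-up validation of the early prediction
#'
#' Emulates the clinical situation at the date of the first MRI after
#' radiotherapy: the constrained fit sees only the pre-treatment points
#' plus the first post-treatment one, and its regrowth-time estimate is
#' compared with the plain fit on the complete follow-up. When the
#' patient belongs to the ensemble, the prior is rebuilt without them
#' (leave-one-out) so training and test data stay separate.
#'
#' @param fu A [follow_up()] with >= 2 points at t <= 0, >= 1 at t > 0,
#'   and >= 5 points overall.
#' @param ens A [param_ensemble()] from which the prior is built.
#' @param bounds A [fit_bounds()] object.
#' @return Named numeric `c(t_min_truncated, t_min_full)` in years.
#' @export
validate_truncated <- function(fu, ens, bounds = default_bounds()) {
  stopifnot(inherits(fu, "follow_up"), inherits(ens, "param_ensemble"))
  pre <- fu$t <= 0
  if (sum(pre) < 2L || sum(!pre) < 1L || length(fu$t) < 5L)
    stop("validation needs >= 2 pre-RT points, >= 1 post-RT point and >= 5 points total",
         call. = FALSE)
  prior <- if (fu$patient_id %in% ens$patient_id)
    leave_one_out_prior(ens, fu$patient_id)
  else build_prior(ens)
  keep <- pre
  keep[which(!pre)[1L]] <- TRUE        # first point just after RT
  fu_tr <- follow_up(fu$patient_id, fu$t[keep], fu$R[keep], sigma = fu$sigma)
  full <- fit_plain(fu, bounds)
  trunc <- fit_constrained(fu_tr, prior, bounds)
  c(t_min_truncated = regrowth_time(trunc$params),
    t_min_full = regrowth_time(full$params))
}
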