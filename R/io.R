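#' Reference ensemble of fitted low-grade-glioma patients
#'
#' Best-fit model parameters for the packaged reference cohort: 20
#' low-grade-glioma patients with high-quality radius follow-ups (at
#' least 9 time points spanning both sides of radiotherapy), each fitted
#' with the 4-parameter radius model. The `tmin` column carries the
#' regrowth time derived from the fit, rounded like the parameters to two
#' decimals. This ensemble is the training material for the constraint
#' prior and serves as the set of virtual-patient truths in the
#' Monte-Carlo studies.
#'
#' @return A [param_ensemble()] with 20 rows and a `tmin` column; a fresh
#'   copy on every call.
#' @examples
#' ens <- reference_ensemble()
#' nrow(ens)
#' @export
reference_ensemble <- function() {
  param_ensemble(
    patient_id = as.character(0:19),
    R0   = c(17.95, 29.03, 24.56, 16.86, 25.40, 28.72, 27.00, 23.26, 15.83,
             31.60, 26.45, 14.67, 41.20, 16.64, 20.21, 19.33, 23.61, 32.68,
             35.02, 28.06),
    v    = c(0.50, 1.33, 3.24, 0.96, 1.11, 1.37, 1.99, 1.23, 2.45, 1.13,
             4.00, 1.54, 4.00, 3.59, 1.30, 0.70, 3.37, 0.72, 2.19, 0.52),
    k    = c(7.29, 10.49, 17.69, 13.28, 5.20, 10.78, 17.00, 5.92, 6.84,
             8.35, 16.15, 4.66, 30.74, 13.83, 14.84, 7.80, 23.15, 7.30,
             15.32, 10.16),
    tau  = c(1.98, 0.19, 1.40, 1.57, 0.10, 0.47, 2.39, 1.18, 0.45, 0.38,
             0.45, 0.32, 1.83, 1.06, 3.64, 0.81, 2.28, 0.43, 0.99, 1.29),
    tmin = c(3.95, 0.72, 1.91, 3.42, 0.39, 1.33, 3.04, 1.66, 0.82, 1.12,
             0.98, 0.72, 2.63, 1.37, 4.16, 2.11, 2.51, 1.36, 1.93, 3.52))
}

#' Read follow-ups from a delimited text file
#'
#' Expects a comma-separated file with a header containing at least the
#' columns `patient_id`, `time_years` (or `time_months`) and `radius_mm`.
#' Rows are grouped by patient and sorted by time; each group must then
#' satisfy the follow-up invariants (strictly increasing times, positive
#' radii).
#'
#' @param path Path to the CSV file.
#' @param sigma Measurement error in mm applied to every follow-up.
#' @param time_unit `"years"` (default) or `"months"`; months are
#'   converted on read (1 month = 1/12 year). A `time_months` column
#'   implies months.
#' @return A named list of [follow_up()] objects, one per patient.
#' @export
read_followups <- function(path, sigma = 1.0,
                           time_unit = c("years", "months")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("time_years", "time_months"), names(d))[1L]
  if (!all(c("patient_id", "radius_mm") %in% names(d)) || is.na(tcol))
    stop("header must provide patient_id, time_years (or time_months) and radius_mm",
         call. = FALSE)
  if (tcol == "time_months") time_unit <- "months"
  tt <- suppressWarnings(as.numeric(d[[tcol]]))
  rr <- suppressWarnings(as.numeric(d$radius_mm))
  bad <- which(!is.finite(tt) | !is.finite(rr))
  if (length(bad))
    stop(sprintf("malformed row(s) at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path), call. = FALSE)
  if (time_unit == "months") tt <- tt / 12
  out <- list()
  for (id in unique(as.character(d$patient_id))) {
    sel <- as.character(d$patient_id) == id
    o <- order(tt[sel])
    out[[id]] <- follow_up(id, tt[sel][o], rr[sel][o], sigma = sigma)
  }
  out
}

#' Write follow-ups to a delimited text file
#'
#' Inverse of [read_followups()]: writes columns `patient_id`,
#' `time_years`, `radius_mm` with full double precision, so the
#' write/read round trip is lossless.
#'
#' @param fus A [follow_up()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_followups <- function(fus, path) {
  if (inherits(fus, "follow_up")) fus <- list(fus)
  rows <- do.call(rbind, lapply(fus, function(fu)
    data.frame(patient_id = fu$patient_id,
               time_years = fu$t, radius_mm = fu$R,
               stringsAsFactors = FALSE)))
  utils::write.csv(format(rows, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Draw a virtual patient from the constraint prior
#'
#' Samples the decorrelated components independently,
#' \eqn{x_i \sim N(\mu_i, \sigma_i^2)}, maps back to parameter space via
#' \eqn{p = T^\top X}, and rejects draws that leave the parameter box
#' (notably `v` outside 0.5--4 mm/yr or non-positive parameters).
#'
#' @param prior A [build_prior()] object.
#' @param bounds A [fit_bounds()] object used as the acceptance region.
#' @param max_attempts Rejection budget before failing.
#' @return A [model_params()] object.
#' @export
sample_virtual_patient <- function(prior, bounds = default_bounds(),
                                   max_attempts = 1000L) {
  stopifnot(inherits(prior, "constraint_prior"),
            inherits(bounds, "fit_bounds"))
  for (i in seq_len(max_attempts)) {
    x <- stats::rnorm(4L, prior$mu, prior$sigma)
    p <- drop(t(prior$T) %*% x)
    if (all(p >= bounds$lower) && all(p <= bounds$upper))
      return(model_params(p[1L], p[2L], p[3L], p[4L]))
  }
  stop(sprintf("no draw satisfied the bounds after %d attempts",
               max_attempts), call. = FALSE)
}

#' Sampling schedule for synthetic follow-ups
#'
#' Describes how synthetic follow-up times are laid out: either an
#' explicit time list, or counts and spans for the pre- and
#' post-radiotherapy phases from which times are drawn uniformly. The
#' defaults emulate the reference cohort's sampling: 2--10 pre-treatment
#' MRIs within up to 3 years before radiotherapy and 5--20 post-treatment
#' MRIs spanning 1--8 years.
#'
#' @param times Optional explicit time vector (years); overrides the rest.
#' @param n_pre,n_post Integer range `c(min, max)` of point counts per
#'   phase.
#' @param pre_span,post_span Range `c(min, max)` in years of the phase
#'   span actually drawn per patient.
#' @param sigma Measurement noise SD in mm.
#' @return An object of class `"schedule_spec"`.
#' @export
schedule_spec <- function(times = NULL, n_pre = c(2L, 10L),
                          pre_span = c(0.5, 3), n_post = c(5L, 20L),
                          post_span = c(1, 8), sigma = 1.0) {
  if (!is.null(times)) {
    times <- as.numeric(times)
    if (is.unsorted(times, strictly = TRUE))
      stop("explicit times must be strictly increasing", call. = FALSE)
  }
  chk <- function(x, what) {
    if (length(x) != 2L || any(x < 0) || x[1L] > x[2L])
      stop(sprintf("%s must be an increasing range of non-negative values",
                   what), call. = FALSE)
    x
  }
  structure(list(times = times,
                 n_pre = as.integer(chk(n_pre, "n_pre")),
                 pre_span = chk(pre_span, "pre_span"),
                 n_post = as.integer(chk(n_post, "n_post")),
                 post_span = chk(post_span, "post_span"),
                 sigma = as.numeric(sigma)),
            class = "schedule_spec")
}

#' Generate one synthetic follow-up
#'
#' Draws measurement times per the schedule (or takes them verbatim),
#' evaluates the model and adds Gaussian noise. Draws that would produce
#' a non-positive radius are redrawn (up to 100 times per point); the
#' count of redraws is attached as attribute `"n_redrawn"`.
#'
#' @param params A [model_params()] object, the generating truth.
#' @param schedule A [schedule_spec()].
#' @param seed Optional integer seed.
#' @param patient_id Identifier for the returned follow-up.
#' @return A [follow_up()].
#' @export
generate_followup <- function(params, schedule = schedule_spec(),
                              seed = NULL, patient_id = "synthetic") {
  stopifnot(inherits(schedule, "schedule_spec"))
  params <- as_model_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(schedule$times)) {
    tt <- schedule$times
  } else {
    n_pre <- sample(schedule$n_pre[1L]:schedule$n_pre[2L], 1L)
    n_post <- sample(schedule$n_post[1L]:schedule$n_post[2L], 1L)
    span_pre <- stats::runif(1L, schedule$pre_span[1L], schedule$pre_span[2L])
    span_post <- stats::runif(1L, schedule$post_span[1L],
                              schedule$post_span[2L])
    tt <- sort(c(-stats::runif(n_pre, 0, span_pre),
                 stats::runif(n_post, 1e-3, span_post)))
    while (anyDuplicated(tt)) tt <- sort(tt + stats::runif(length(tt), 0, 1e-9))
  }
  base <- radius_at(params, tt)
  R <- base + stats::rnorm(length(tt), 0, schedule$sigma)
  n_redrawn <- 0L
  for (j in which(R <= 0)) {
    for (a in 1:100) {
      R[j] <- base[j] + stats::rnorm(1L, 0, schedule$sigma)
      n_redrawn <- n_redrawn + 1L
      if (R[j] > 0) break
    }
    if (R[j] <= 0)
      stop("could not draw a positive radius; model radius too close to zero",
           call. = FALSE)
  }
  fu <- follow_up(patient_id, tt, R,
                  sigma = if (schedule$sigma > 0) schedule$sigma else 1.0)
  attr(fu, "n_redrawn") <- n_redrawn
  fu
}

#' Write a cohort-study table to CSV
#'
#' @param study A data frame as returned by [cohort_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  utils::write.csv(study, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
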