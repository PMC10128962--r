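#' Pearson correlations of the fitted parameters across patients
#'
#' The correlation structure of the best-fit parameters over an ensemble
#' of patients. The off-diagonal structure (notably the strong `v`--`k`
#' correlation linking pre- and post-treatment behaviour) is what the
#' constraint prior encodes.
#'
#' @param ens A [param_ensemble()] with >= 3 entries.
#' @return Symmetric 4 x 4 correlation matrix with unit diagonal, rows and
#'   columns named `R0`, `v`, `k`, `tau`.
#' @export
pearson_correlations <- function(ens) {
  stopifnot(inherits(ens, "param_ensemble"))
  if (nrow(ens) < 3L) stop("need >= 3 ensemble entries", call. = FALSE)
  stats::cor(ensemble_matrix(ens))
}

#' Build the decorrelated Gaussian constraint prior from an ensemble
#'
#' Diagonalizes the sample covariance of the raw parameter vectors
#' `p = (R0, v, k, tau)` across patients. The eigenvector rows form an
#' orthogonal transform `T` such that the components of `X = T p` are
#' mutually uncorrelated over the ensemble; each component is then
#' summarized by its sample mean and standard deviation `(mu_i, sigma_i)`,
#' the maximum-likelihood Gaussian fit. Rows of `T` are ordered by
#' decreasing eigenvalue, with signs fixed so each row's
#' largest-magnitude entry is positive.
#'
#' The covariance is taken over raw, unstandardized parameters: the
#' transform is applied to `p` directly in [chi2_constraint()], so the
#' leading components are dominated by the mm-scaled quantities `R0` and
#' `k` with the largest variance.
#'
#' @param ens A [param_ensemble()] with >= 5 entries.
#' @param powerlaw If `TRUE`, also attach the [fit_powerlaw()] law fitted
#'   on the same ensemble.
#' @return An object of class `"constraint_prior"`: list with the 4 x 4
#'   orthogonal matrix `T`, numeric `mu` and `sigma` (length 4),
#'   `source_ids`, and optionally `powerlaw = c(a, b)`.
#' @examples
#' prior <- build_prior(reference_ensemble())
#' round(prior$T, 2)
#' @export
build_prior <- function(ens, powerlaw = FALSE) {
  stopifnot(inherits(ens, "param_ensemble"))
  if (nrow(ens) < 5L) stop("need >= 5 ensemble entries", call. = FALSE)
  P <- ensemble_matrix(ens)
  C <- stats::cov(P)
  e <- eigen(C, symmetric = TRUE)      # eigenvalues in decreasing order
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("degenerate ensemble: covariance is numerically rank-deficient",
         call. = FALSE)
  Tm <- t(e$vectors)                   # rows = eigenvectors
  for (i in 1:4) {
    j <- which.max(abs(Tm[i, ]))
    if (Tm[i, j] < 0) Tm[i, ] <- -Tm[i, ]
  }
  dimnames(Tm) <- list(paste0("x", 1:4), c("R0", "v", "k", "tau"))
  X <- P %*% t(Tm)
  prior <- structure(list(T = Tm,
                          mu = colMeans(X),
                          sigma = apply(X, 2L, stats::sd),
                          source_ids = ens$patient_id,
                          powerlaw = NULL),
                     class = "constraint_prior")
  if (isTRUE(powerlaw)) prior$powerlaw <- fit_powerlaw(ens)
  prior
}

#' @export
print.constraint_prior <- function(x, ...) {
  cat(sprintf("<constraint_prior> built from %d patients\n",
              length(x$source_ids)))
  cat("T (rows = decorrelated components):\n")
  print(round(x$T, 3))
  print(rbind(mu = x$mu, sigma = x$sigma))
  if (!is.null(x$powerlaw))
    cat(sprintf("power law: t_min = %.3g / v_d^%.3g\n",
                x$powerlaw[["a"]], x$powerlaw[["b"]]))
  invisible(x)
}

#' Leave-one-out variant of the constraint prior
#'
#' Rebuilds the prior with one patient excluded, so that validating a
#' prediction on that patient does not mix training and test data.
#'
#' @param ens A [param_ensemble()].
#' @param excluded A patient id present in `ens`; >= 5 entries must remain.
#' @inheritParams build_prior
#' @return A `"constraint_prior"`, as [build_prior()].
#' @export
leave_one_out_prior <- function(ens, excluded, powerlaw = FALSE) {
  stopifnot(inherits(ens, "param_ensemble"))
  excluded <- as.character(excluded)[1L]
  if (!excluded %in% ens$patient_id)
    stop(sprintf("patient '%s' is not in the ensemble", excluded),
         call. = FALSE)
  keep <- ens$patient_id != excluded
  sub <- as.data.frame(ens)[keep, , drop = FALSE]
  build_prior(param_ensemble(sub$patient_id, sub$R0, sub$v, sub$k, sub$tau,
                             tmin = sub$tmin),
              powerlaw = powerlaw)
}

#' Empirical power law between collapse speed and regrowth time
#'
#' Across fitted patients the collapse speed `v_d = k/tau` and the
#' regrowth time are strongly (and non-trivially) correlated. This fits
#' \eqn{t_{min} = a / v_d^{\,b}} by nonlinear least squares on the linear
#' scale (Levenberg-Marquardt, started from the log-log ordinary
#' least-squares estimate). The law is the backbone of the
#' loose-constraint estimator ([fit_loose()]).
#'
#' @param ens A [param_ensemble()]. Uses the `tmin` column when present,
#'   otherwise recomputes [regrowth_time()] per row. Entries with
#'   non-finite regrowth time are skipped with a warning.
#' @return Named numeric `c(a, b)`; `a` in yr (mm/yr)^b.
#' @examples
#' fit_powerlaw(reference_ensemble()) # about c(a = 9.0, b = 0.61)
#' @export
fit_powerlaw <- function(ens) {
  stopifnot(inherits(ens, "param_ensemble"))
  vd <- ens$k / ens$tau
  tm <- if (!is.null(ens$tmin)) ens$tmin else regrowth_time(ens)
  keep <- is.finite(tm) & tm > 0 & vd > 0
  if (any(!keep))
    warning(sprintf("skipping %d entries without a finite regrowth time",
                    sum(!keep)))
  vd <- vd[keep]; tm <- tm[keep]
  if (length(vd) < 3L)
    stop("need >= 3 usable entries to fit the power law", call. = FALSE)
  if (stats::sd(log(vd)) < 1e-12)
    stop("collapse speeds are all equal: the power-law exponent is not identifiable",
         call. = FALSE)
  ols <- stats::lm.fit(cbind(1, log(vd)), log(tm))$coefficients
  start <- c(a = exp(ols[[1L]]), b = -ols[[2L]])
  res <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) tm - p[[1L]] / vd^p[[2L]],
    jac = function(p) cbind(-vd^(-p[[2L]]),
                            p[[1L]] * vd^(-p[[2L]]) * log(vd)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  c(a = res$par[[1L]], b = res$par[[2L]])
}

#' Read and write a constraint prior as JSON
#'
#' Serializes the transform, component statistics, source ids and optional
#' power law to a structured text file. The round trip is lossless at 15
#' significant digits.
#'
#' @param prior A `"constraint_prior"`.
#' @param path File path.
#' @return `write_prior` returns `path` invisibly; `read_prior` returns a
#'   `"constraint_prior"`.
#' @export
write_prior <- function(prior, path) {
  stopifnot(inherits(prior, "constraint_prior"))
  obj <- list(T = lapply(1:4, function(i) unname(prior$T[i, ])),
              mu = unname(prior$mu),
              sigma = unname(prior$sigma),
              source_ids = prior$source_ids)
  if (!is.null(prior$powerlaw))
    obj$powerlaw <- list(a = unname(prior$powerlaw[["a"]]),
                         b = unname(prior$powerlaw[["b"]]))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_prior
#' @export
read_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Tm <- obj$T
  if (is.list(Tm)) Tm <- do.call(rbind, lapply(Tm, as.numeric))
  Tm <- matrix(as.numeric(Tm), 4L, 4L,
               dimnames = list(paste0("x", 1:4), c("R0", "v", "k", "tau")))
  if (max(abs(Tm %*% t(Tm) - diag(4))) > 1e-8)
    stop("prior transform is not orthogonal", call. = FALSE)
  sigma <- as.numeric(obj$sigma)
  if (any(sigma <= 0)) stop("prior sigma must be positive", call. = FALSE)
  prior <- structure(list(T = Tm,
                          mu = stats::setNames(as.numeric(obj$mu),
                                               paste0("x", 1:4)),
                          sigma = stats::setNames(sigma, paste0("x", 1:4)),
                          source_ids = as.character(obj$source_ids),
                          powerlaw = NULL),
                     class = "constraint_prior")
  if (!is.null(obj$powerlaw))
    prior$powerlaw <- c(a = as.numeric(obj$powerlaw$a),
                        b = as.numeric(obj$powerlaw$b))
  prior
}
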