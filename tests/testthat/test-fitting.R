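test_that("chi2 equals the error-normalized sum of squared residuals", {
  p <- model_params(24.56, 3.24, 17.69, 1.40)

  # interpolating data scores zero
  fu0 <- noiseless_fu(p, c(-1, 0, 0.5, 2, 4))
  expect_equal(chi2(p, fu0), 0)

  # a single point off by exactly sigma scores one
  fu1 <- follow_up("x", 0.5, radius_at(p, 0.5) + 1, sigma = 1)
  expect_equal(chi2(p, fu1), 1)
  fu2 <- follow_up("x", 0.5, radius_at(p, 0.5) + 0.7, sigma = 0.7)
  expect_equal(chi2(p, fu2), 1)

  # term-by-term brute-force oracle on a 5-point follow-up
  set.seed(21)
  tt <- c(-1.2, -0.3, 0.4, 1.1, 2.8)
  R <- radius_at(p, tt) + rnorm(5)
  fu <- follow_up("x", tt, R, sigma = 1.3)
  acc <- 0
  for (i in 1:5) acc <- acc + (R[i] - radius_at(p, tt[i]))^2 / 1.3^2
  expect_equal(chi2(p, fu), acc)
})

test_that("constraint penalty scores the decorrelated departure from the ensemble", {
  prior <- build_prior(reference_ensemble())

  # parameters whose transform hits the component means exactly
  p_mu <- drop(t(prior$T) %*% prior$mu)
  expect_equal(chi2_constraint(p_mu, prior), 0, tolerance = 1e-12)

  # one standard deviation away in every component scores 4
  p_ms <- drop(t(prior$T) %*% (prior$mu + prior$sigma))
  expect_equal(chi2_constraint(p_ms, prior), 4, tolerance = 1e-10)

  # brute-force matrix-multiply-then-sum oracle on random parameters
  set.seed(8)
  for (r in 1:10) {
    p <- c(runif(1, 5, 50), runif(1, 0.5, 4), runif(1, 0.5, 40), runif(1, 0.05, 5))
    acc <- 0
    for (i in 1:4) {
      xi <- sum(prior$T[i, ] * p)
      acc <- acc + ((xi - prior$mu[[i]]) / prior$sigma[[i]])^2
    }
    expect_equal(chi2_constraint(p, prior), acc)
  }
})

test_that("plain fit recovers generating parameters from noiseless data", {
  p <- model_params(17.95, 0.50, 7.29, 1.98)
  tt <- seq(-2, 8, length.out = 12)
  f <- fit_plain(noiseless_fu(p, tt))
  expect_true(f$converged)
  expect_equal(as.numeric(f$params), as.numeric(p), tolerance = 1e-3)
  expect_lt(f$objective_value, 1e-10)

  # returned objective is no worse than any multi-start initial point
  b <- default_bounds()
  fu <- noiseless_fu(p, tt)
  R0s <- fu$R[which.min(abs(fu$t))]
  for (v0 in c(0.5, 1, 2, 4))
    for (kt in list(c(0.25 * R0s, 0.3), c(0.75 * R0s, 1.5))) {
      start <- pmin(pmax(c(R0s, v0, kt[1], kt[2]), b$lower), b$upper)
      expect_lte(f$objective_value, chi2(start, fu))
    }
})

test_that("a growth slope outside the clinical range clamps v to the bound", {
  # data generated with v = 5 mm/yr; fitted v must sit at the 4 mm/yr cap
  p_fast <- model_params(25, 5, 10, 1)
  f <- fit_plain(noiseless_fu(p_fast, seq(-3, 5, length.out = 10)))
  expect_equal(f$params[["v"]], 4)
})

test_that("plain fit rejects follow-ups it cannot identify", {
  p <- model_params(20, 1, 8, 1)
  expect_error(fit_plain(noiseless_fu(p, c(-1, 0, 1))), "at least 4")
  expect_error(fit_plain(noiseless_fu(p, c(1, 2, 3, 4))), "both sides")
})

test_that("regrowth-time recovery from noisy 12-point follow-ups is accurate", {
  ens <- reference_ensemble()
  set.seed(11)
  errs <- vapply(1:50, function(i) {
    r <- ((i - 1) %% 20) + 1
    tr <- model_params(ens$R0[r], ens$v[r], ens$k[r], ens$tau[r])
    tt <- seq(-2, 8, length.out = 12)
    fu <- follow_up("s", tt, pmax(radius_at(tr, tt) + rnorm(12), 0.1))
    abs(regrowth_time(fit_plain(fu)$params) - regrowth_time(tr))
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.3)
})

test_that("constrained fit solves 3-point follow-ups and is pulled to the prior for slow responders", {
  ens <- reference_ensemble()
  prior <- build_prior(ens)
  # slow responder measured at [-6, 0, +3] months: t_min information is absent
  # and the estimate settles near the ensemble's typical ~2 yr regrowth time
  p0 <- ref_params("0") # true t_min 3.95 yr
  fu <- noiseless_fu(p0, c(-0.5, 0, 0.25))
  f <- fit_constrained(fu, prior)
  tm <- regrowth_time(f$params)
  expect_true(f$converged)
  expect_gt(tm, 1.5)
  expect_lt(tm, 2.5)
})

test_that("an uninformative prior reduces the constrained fit to the plain fit", {
  ens <- reference_ensemble()
  prior <- build_prior(ens)
  prior$sigma[] <- 1e8
  p <- ref_params("18")
  fu <- noiseless_fu(p, rich_times)
  f_pl <- fit_plain(fu)
  f_co <- fit_constrained(fu, prior)
  expect_equal(as.numeric(f_co$params), as.numeric(f_pl$params),
               tolerance = 1e-5)
})

test_that("on rich data the constraint is near-neutral, and its residual pull shrinks as it is weakened", {
  ens <- reference_ensemble()
  prior <- build_prior(ens)
  shifts <- vapply(1:20, function(r) {
    tr <- model_params(ens$R0[r], ens$v[r], ens$k[r], ens$tau[r])
    fu <- noiseless_fu(tr, rich_times)
    abs(regrowth_time(fit_plain(fu)$params) -
          regrowth_time(fit_constrained(fu, prior)$params))
  }, numeric(1))
  # typical patients are essentially untouched by the constraint...
  expect_lt(median(shifts), 0.05)
  # ...and the pull on the worst-case (ensemble-outlier) patient weakens with
  # the prior: scaling every component SD by 10 must shrink the shift
  worst <- which.max(shifts)
  weak <- prior; weak$sigma <- prior$sigma * 10
  tr <- model_params(ens$R0[worst], ens$v[worst], ens$k[worst], ens$tau[worst])
  fu <- noiseless_fu(tr, rich_times)
  shift_weak <- abs(regrowth_time(fit_plain(fu)$params) -
                      regrowth_time(fit_constrained(fu, weak)$params))
  expect_lt(shift_weak, shifts[worst])
})

test_that("loose estimator converts fitted collapse speed through the power law", {
  # exact piecewise-linear data, v_d = 1 mm/yr: any b gives t_min = a
  mk_linear <- function(R0, v, vd, tt) {
    follow_up("x", tt, R0 + v * tt - vd * pmax(tt, 0))
  }
  tt <- c(-1, -0.5, 0.5, 1, 2)
  lf1 <- fit_loose(mk_linear(20, 1.5, 1, tt), powerlaw = c(9.0, 0.61))
  expect_equal(lf1$v_d, 1, tolerance = 1e-10)
  expect_equal(lf1$t_min, 9.0, tolerance = 1e-9)

  # v_d = 4: independent calculator evaluation of a / v_d^b
  lf4 <- fit_loose(mk_linear(20, 1.5, 4, tt), powerlaw = c(9.0, 0.61))
  expect_equal(lf4$t_min, 9.0 / exp(0.61 * log(4)), tolerance = 1e-9)

  # growing data has no collapse and therefore no prediction
  expect_error(fit_loose(mk_linear(20, 1.5, -0.5, tt), c(9.0, 0.61)),
               class = "gliomaRT_no_collapse")

  # needs two points on each side of the radiotherapy date
  expect_error(fit_loose(mk_linear(20, 1.5, 1, c(-1, 0.5, 1, 2)), c(9.0, 0.61)),
               "2 points before")
})

test_that("piecewise-linear collapse speed approximates k/tau on the 4-MRI design", {
  # noiseless [-6, 0, 3, 12]-month measurements of the slow responder with
  # tau = 3.64 yr; the linear skeleton underestimates v_d = k/tau = 4.08 mm/yr
  # by ~15% (the exponential is curved over the 12-month lever arm)
  p14 <- ref_params("14")
  fu <- noiseless_fu(p14, c(-6, 0, 3, 12) / 12)
  lf <- fit_loose(fu, powerlaw = c(9.0, 0.61))
  vd_true <- collapse_speed(p14)
  expect_lt(abs(lf$v_d - vd_true) / vd_true, 0.16)
})
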