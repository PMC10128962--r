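# Shared fixtures: everything is built in code at test time.

# Parameter row of the packaged reference cohort by patient id.
ref_params <- function(id) {
  ens <- reference_ensemble()
  i <- match(as.character(id), ens$patient_id)
  model_params(ens$R0[i], ens$v[i], ens$k[i], ens$tau[i])
}

# Noiseless follow-up sampled from a model curve.
noiseless_fu <- function(params, times, id = "synthetic") {
  follow_up(id, times, radius_at(params, times))
}

# A well-spread 15-point design covering both sides of radiotherapy and the
# post-treatment minimum of every reference patient.
rich_times <- c(-2, -1.2, -0.6, 0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4.5, 6, 8)

# Random valid parameter sets whose radius curve has a post-RT minimum
# (k/(tau v) > 1), for property-style checks.
random_shrinking_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    R0 <- stats::runif(1, 10, 45)
    v <- stats::runif(1, 0.5, 4)
    tau <- stats::runif(1, 0.1, 4)
    ratio <- exp(stats::runif(1, log(1.05), log(15)))
    k <- min(ratio * tau * v, 95)
    model_params(R0, v, k, tau)
  })
}
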