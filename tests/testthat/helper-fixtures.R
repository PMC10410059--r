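# Shared fixtures, built in code at load time.

# moderate mixed cohort for model-level tests
fixture_sim <- simulate_cohort(sim_config(n_nc = 60, n_cy = 45, n_tm = 60,
                                          seed = 11L))
fixture_prepared <- suppressWarnings(assemble(fixture_sim$cohort))

# independent truncated-power restricted-cubic-spline oracle
oracle_rcs <- function(x, knots) {
  k <- length(knots)
  pp <- function(u) ifelse(u > 0, u^3, 0)
  tk <- knots[k]; tk1 <- knots[k - 1]
  out <- cbind(x)
  for (j in 1:(k - 2)) {
    tj <- knots[j]
    col <- pp(x - tj) -
      pp(x - tk1) * (tk - tj) / (tk - tk1) +
      pp(x - tk) * (tk1 - tj) / (tk - tk1)
    out <- cbind(out, col / (tk - knots[1])^2)
  }
  unname(out)
}

# brute-force step-up FDR oracle: smallest level at which each hypothesis
# is rejected by the step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# linear-truth simulation config: TM departs from NC linearly over the whole
# EYO range so a linear LMEM is correctly specified, CY equals NC
linear_truth_config <- function(seed, n_nc = 10L, n_cy = 200L, n_tm = 200L,
                                tm_delta = -3, sigma_family = 0.5,
                                sigma_subject = 0.6, sigma_resid = 1) {
  sim_config(
    n_nc = n_nc, n_cy = n_cy, n_tm = n_tm,
    family_size_probs = c(`4` = 1), icv_sd = 0,
    outcomes = list(hv = list(
      level = 10, slope = -0.1, carrier_hinge = -24.9, carrier_delta = 0,
      tm_divergence = -25, tm_delta = tm_delta, ramp_power = 1,
      ramp_scale = 25, sigma_family = sigma_family,
      sigma_subject = sigma_subject, sigma_resid = sigma_resid,
      range = c(-1e6, 1e6))),
    seed = seed)
}

# ramp-divergence config: TM-CY gap is a linear ramp starting at
# `divergence` and reaching `delta` residual SDs at EYO 0
ramp_divergence_config <- function(seed, delta = 1, divergence = -10,
                                   n_cy = 200L, n_tm = 200L,
                                   sigma_family = 0.3, sigma_subject = 0.5) {
  sim_config(
    n_nc = 10L, n_cy = n_cy, n_tm = n_tm,
    family_size_probs = c(`4` = 1), icv_sd = 0,
    outcomes = list(hv = list(
      level = 0, slope = 0, carrier_hinge = -24.9, carrier_delta = 0,
      tm_divergence = divergence, tm_delta = delta, ramp_power = 1,
      ramp_scale = -divergence, sigma_family = sigma_family,
      sigma_subject = sigma_subject,
      sigma_resid = 1, range = c(-1e6, 1e6))),
    seed = seed)
}
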