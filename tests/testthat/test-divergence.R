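fit_fix <- fit_eyo_lmem(fixture_prepared, "mmse")

test_that("posterior draws are reproducible and agree with the ML fit", {
  p1 <- posterior_draws(fit_fix, n_draws = 2000, seed = 7)
  p2 <- posterior_draws(fit_fix, n_draws = 2000, seed = 7)
  expect_identical(p1$draws, p2$draws)
  p3 <- posterior_draws(fit_fix, n_draws = 2000, seed = 8)
  expect_false(identical(p1$draws, p3$draws))
  # posterior means within 0.1 SE of the ML estimates
  pm <- colMeans(posterior_draws(fit_fix, n_draws = 20000, seed = 7)$draws)
  expect_true(all(abs(pm - fit_fix$beta) / fit_fix$se < 0.1))
  # diagnostics attached for every parameter
  expect_equal(nrow(p1$diagnostics), length(fit_fix$beta))
  expect_true(all(p1$diagnostics$rhat < 1.05, na.rm = TRUE))
  expect_true(all(p1$diagnostics$ess > 200, na.rm = TRUE))
})

test_that("prior-predictive mode reproduces the prior moments", {
  pp <- posterior_draws(fit_fix, n_draws = 20000, seed = 5, prior_only = TRUE)
  prior_sd <- 10 * fit_fix$outcome_sd
  mc_se <- prior_sd / sqrt(20000)
  expect_true(all(abs(colMeans(pp$draws)) < 4 * mc_se))
  expect_true(all(abs(apply(pp$draws, 2, stats::sd) / prior_sd - 1) < 0.05))
})

test_that("difference curves cancel covariates and match brute-force evaluation", {
  post <- posterior_draws(fit_fix, n_draws = 500, seed = 3)
  dc1 <- difference_curves(post)
  dc2 <- difference_curves(post, covariates = list(visit_age = 70,
                                                   education = 8, sex = "M",
                                                   apoe4 = "carrier"))
  expect_equal(dc1$diff_draws, dc2$diff_draws, tolerance = 1e-9)
  # brute-force oracle: assemble each group's linear predictor from the
  # coefficients and the truncated-power basis directly
  g <- dc1$eyo_grid
  basis <- oracle_rcs(g, fit_fix$knots)
  for (k in c(1, 250)) {
    b <- post$draws[k, ]
    oracle <- b[".groupTM"] - b[".groupCY"] +
      basis[, 1] * (b["eyo1:.groupTM"] - b["eyo1:.groupCY"]) +
      basis[, 2] * (b["eyo2:.groupTM"] - b["eyo2:.groupCY"])
    expect_equal(unname(dc1$diff_draws[k, ]), unname(oracle),
                 tolerance = 1e-9)
  }
  # zeroing all group coefficients zeroes every difference
  post0 <- post
  post0$draws[, grep("group", colnames(post0$draws))] <- 0
  expect_true(all(difference_curves(post0)$diff_draws == 0))
  expect_error(difference_curves(post, eyo_grid = c(-40, 0)), "support")
})

test_that("divergence point logic follows the persistence rule", {
  grid <- seq(-20, 10, by = 0.5)
  mk <- function(draws) structure(list(eyo_grid = grid, diff_draws = draws,
                                       groups = c("TM", "CY"), seed = 1),
                                  class = "eyo_diffcurves")
  # all-zero differences: no divergence
  res0 <- suppressWarnings(divergence_point(mk(matrix(0, 500, length(grid)))))
  expect_true(is.na(res0$divergence_eyo))
  # difference jumps to a constant far above the posterior spread at g = -5
  set.seed(71)
  noise <- matrix(stats::rnorm(500 * length(grid), 0, 0.01), 500)
  jump <- outer(rep(1, 500), ifelse(grid >= -5, 5, 0))
  res1 <- suppressWarnings(divergence_point(mk(noise + jump)))
  expect_equal(res1$divergence_eyo, -5)
  # a transient excursion before a persistent one is skipped
  trans <- jump
  trans[, grid > -15 & grid < -14] <- 5
  res2 <- suppressWarnings(divergence_point(mk(noise + trans)))
  expect_equal(res2$divergence_eyo, -5)
  # raising the credible level never moves the divergence earlier
  drift <- noise * 50 + outer(rep(1, 500), pmax(grid + 5, 0) * 0.2)
  r90 <- suppressWarnings(divergence_point(mk(drift), level = 0.90))
  r99 <- suppressWarnings(divergence_point(mk(drift), level = 0.99))
  if (!is.na(r90$divergence_eyo) && !is.na(r99$divergence_eyo))
    expect_gte(r99$divergence_eyo, r90$divergence_eyo)
  expect_error(divergence_point(mk(noise), level = 1.2), "level")
  expect_error(divergence_point(mk(noise[1:50, ])), "100 draws")
})

test_that("divergence recovery on a strongly separated synthetic cohort", {
  cfg <- ramp_divergence_config(seed = 83, delta = 2.5, divergence = -10)
  d <- suppressWarnings(assemble(simulate_cohort(cfg)$cohort))
  res <- divergence_analysis(d, "hv", n_draws = 2000, seed = 83)
  expect_false(is.na(res$divergence_eyo))
  expect_lt(abs(res$divergence_eyo - (-10)), 3)
  # grid refinement: halving the step moves the estimate at most one step
  fit <- attr(res, "fit")
  post <- posterior_draws(fit, n_draws = 2000, seed = 83)
  r_fine <- divergence_point(difference_curves(post, step = 0.05))
  expect_lt(abs(r_fine$divergence_eyo - res$divergence_eyo), 0.1 + 1e-9)
})
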