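test_that("zero family variance and balanced design reduce to OLS", {
  cfg <- sim_config(n_nc = 80, n_cy = 80, n_tm = 80,
                    family_size_probs = c(`1` = 1),
                    visit_probs = c(`1` = 1),
                    outcomes = list(mmse = list(sigma_family = 0,
                                                sigma_subject = 0)),
                    seed = 41)
  d <- suppressWarnings(assemble(simulate_cohort(cfg)$cohort))
  f <- fit_eyo_lmem(d, "mmse", eyo_form = "linear")
  # normal-equations oracle on an independently built design
  dd <- d[stats::complete.cases(d[, c("mmse", "eyo", "sex", "apoe4",
                                      "visit_age", "education")]), ]
  X <- stats::model.matrix(~ sex + apoe4 + visit_age + education + eyo +
                             group + eyo:group, dd)
  beta_ols <- drop(solve(crossprod(X), crossprod(X, dd$mmse)))
  # with one observation per family the covariance is exchangeable-free and
  # the GLS estimator coincides with OLS whatever the variance split
  expect_lt(max(abs(unname(f$beta) - unname(beta_ols))), 1e-6)
})

test_that("a constant outcome gives a pure-intercept fit", {
  d <- fixture_prepared
  d$mmse <- 17.5
  f <- suppressWarnings(fit_eyo_lmem(d, "mmse", eyo_form = "linear"))
  expect_equal(unname(f$beta["(Intercept)"]), 17.5, tolerance = 1e-6)
  expect_lt(max(abs(f$beta[names(f$beta) != "(Intercept)"])), 1e-6)
  expect_lt(f$var_family + f$var_resid, 1e-6)
})

test_that("parameters are recovered from model-generated data", {
  cfg <- linear_truth_config(seed = 43, n_nc = 120, n_cy = 120, n_tm = 120,
                             tm_delta = -3)
  d <- suppressWarnings(assemble(simulate_cohort(cfg)$cohort))
  f <- fit_eyo_lmem(d, "hv", eyo_form = "linear")
  truth <- c("(Intercept)" = 10, sexM = 0, apoe4carrier = 0, visit_age = 0,
             eyo1 = -0.1, ".groupCY" = 0, ".groupTM" = -3 * (25 - 25) / 25,
             "eyo1:.groupCY" = 0, "eyo1:.groupTM" = -3 / 25)
  # TM curve: level + slope*e + tm_delta*(e+25)/25 -> main effect at e=0 is
  # tm_delta, interaction slope tm_delta/25
  truth[".groupTM"] <- -3
  for (nm in names(truth))
    expect_lt(abs(f$beta[[nm]] - truth[[nm]]) / f$se[[nm]], 3)
  expect_true(f$converged)
  expect_gt(f$var_family, 0.05)
})

test_that("Wald statistics follow the two-sided normal reference", {
  fake <- structure(list(beta = c(a = 0, b = 1.96, c = -2.7),
                         se = c(a = 1, b = 1, c = 0.9),
                         vcov = diag(c(1, 1, 0.81)),
                         group_levels = c("NC", "CY"), ref_group = "NC",
                         eyo_cols = "eyo1"), class = "eyo_lmem")
  dimnames(fake$vcov) <- list(names(fake$beta), names(fake$beta))
  expect_equal(wald_contrast(fake, "a")$p, 1)
  expect_equal(wald_contrast(fake, "b")$p, 0.05, tolerance = 1e-3)
  z <- -2.7 / 0.9
  expect_equal(wald_contrast(fake, "c")$p, 2 * (1 - stats::pnorm(abs(z))),
               tolerance = 1e-12)
  expect_error(wald_contrast(fake, "nope"), "available")
})

test_that("TM-vs-CY linear contrast agrees with refitting CY as reference", {
  d <- fixture_prepared
  f_nc <- fit_eyo_lmem(d, "mmse")
  f_cy <- fit_eyo_lmem(d, "mmse", ref_group = "CY", knots = f_nc$knots)
  for (term in c("(group)", "eyo1", "eyo2")) {
    ct <- group_contrast(f_nc, groups = c("TM", "CY"), term = term)
    nm <- if (term == "(group)") ".groupTM" else paste0(term, ":.groupTM")
    expect_equal(ct$B, unname(f_cy$beta[nm]), tolerance = 1e-6)
    expect_equal(ct$SE, unname(f_cy$se[nm]), tolerance = 1e-4)
  }
})

test_that("likelihood-ratio selection behaves at both extremes", {
  d <- fixture_prepared
  fl <- fit_eyo_lmem(d, "mmse", eyo_form = "linear")
  # identical models: statistic 0, p 1, choose linear
  sel0 <- lrt_select(fl, fl)
  expect_equal(sel0$statistic, 0)
  expect_equal(sel0$p, 1)
  expect_equal(sel0$choice, "linear")
  # oracle chi-square tail for a genuine comparison
  fr <- fit_eyo_lmem(d, "mmse", eyo_form = "rcs")
  sel <- lrt_select(fl, fr)
  stat <- 2 * (fr$loglik - fl$loglik)
  df <- length(fr$beta) - length(fl$beta)
  expect_equal(sel$statistic, stat, tolerance = 1e-10)
  expect_equal(sel$p, stats::pchisq(stat, df, lower.tail = FALSE),
               tolerance = 1e-12)
  # strong nonlinear group effect: spline retained
  cfg <- sim_config(n_nc = 150, n_cy = 150, n_tm = 150,
                    visit_probs = c(`2` = 1), seed = 47)
  db <- suppressWarnings(assemble(simulate_cohort(cfg)$cohort))
  fl2 <- fit_eyo_lmem(db, "mmse", eyo_form = "linear")
  fr2 <- fit_eyo_lmem(db, "mmse", eyo_form = "rcs")
  expect_equal(lrt_select(fl2, fr2)$choice, "rcs")
  fl_sub <- fit_eyo_lmem(db[1:500, ], "mmse", eyo_form = "linear")
  expect_error(lrt_select(fl_sub, fr2), "different numbers of rows")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(53)
  for (i in 1:200) {
    p <- stats::runif(sample(1:8, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("estimates are invariant to row permutation and covariate rescaling", {
  d <- fixture_prepared
  f1 <- fit_eyo_lmem(d, "mmse")
  set.seed(59)
  f2 <- fit_eyo_lmem(d[sample(nrow(d)), ], "mmse")
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  # affine rescaling of a covariate leaves the LRT statistic unchanged
  d2 <- d
  d2$education <- d2$education * 10 + 5
  lrt1 <- lrt_select(fit_eyo_lmem(d, "mmse", eyo_form = "linear"),
                     fit_eyo_lmem(d, "mmse", eyo_form = "rcs"))
  lrt2 <- lrt_select(fit_eyo_lmem(d2, "mmse", eyo_form = "linear"),
                     fit_eyo_lmem(d2, "mmse", eyo_form = "rcs"))
  expect_equal(lrt1$statistic, lrt2$statistic, tolerance = 1e-4)
})

test_that("family variance component is recovered", {
  cfg <- sim_config(n_nc = 400, n_cy = 300, n_tm = 300,
                    family_size_probs = c(`2` = 0.5, `3` = 0.5),
                    visit_probs = c(`1` = 1),
                    outcomes = list(mmse = list(sigma_family = 1,
                                                sigma_subject = 0,
                                                sigma_resid = 1,
                                                carrier_delta = 0,
                                                tm_delta = 0)),
                    seed = 61)
  d <- suppressWarnings(assemble(simulate_cohort(cfg)$cohort))
  f <- fit_eyo_lmem(d, "mmse", eyo_form = "linear")
  expect_lt(abs(f$var_family - 1), 0.25)
  expect_lt(abs(f$var_resid - 1), 0.25)
})

test_that("degenerate designs raise informative errors", {
  d <- fixture_prepared
  expect_error(fit_eyo_lmem(d[d$group == "TM", ], "mmse"),
               "two non-empty groups")
  expect_error(fit_eyo_lmem(d, "not_a_column"), "not found")
  idx <- unlist(lapply(c("NC", "CY", "TM"), function(g)
    which(d$group == g)[1:3]))
  expect_error(fit_eyo_lmem(d[idx, ], "mmse", eyo_form = "linear"),
               "complete cases")
})

test_that("model object methods are coherent", {
  f <- fit_eyo_lmem(fixture_prepared, "mmse")
  expect_equal(unname(f$se), unname(sqrt(diag(f$vcov))))
  expect_s3_class(summary(f), "summary.eyo_lmem")
  expect_equal(coef(f), f$beta)
  expect_equal(nobs(f), f$n_obs)
  grid <- data.frame(eyo = c(-10, 0), group = "TM")
  pr <- predict(f, grid, se.fit = TRUE)
  expect_length(pr$fit, 2)
  expect_true(all(pr$se.fit > 0))
  expect_length(residuals(f), f$n_obs)
})
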