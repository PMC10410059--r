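test_that("same config and seed give byte-identical cohorts", {
  cfg <- sim_config(n_nc = 20, n_cy = 10, n_tm = 15, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$divergence_eyo, b$truth$divergence_eyo)
})

test_that("default group sizes match the targeted cohort structure", {
  sim <- simulate_cohort(sim_config(seed = 1))
  subj <- sim$cohort[!duplicated(sim$cohort$subject_id), ]
  expect_equal(as.integer(table(subj$group)), c(202L, 65L, 135L))
  # carriers have codons consistent with their domain group
  cls <- classify_variant(subj$codon[subj$group == "TM"])
  expect_true(all(cls$group == "TM"))
  cls <- classify_variant(subj$codon[subj$group == "CY"])
  expect_true(all(cls$group == "CY"))
  expect_true(all(is.na(subj$codon[subj$group == "NC"])))
})

test_that("noiseless limit reproduces the group mean curves exactly", {
  zero <- list(sigma_family = 0, sigma_subject = 0, sigma_resid = 0)
  cfg <- sim_config(n_nc = 8, n_cy = 8, n_tm = 8,
                    icv_sd = 0, hv_asym_sd = 0, suvr_region_sd = 0,
                    outcomes = stats::setNames(
                      rep(list(zero), 6),
                      c("mmse", "cdr_sb", "hv", "pib", "csf_ptau181",
                        "csf_ab42_40")),
                    seed = 9)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  tr <- sim$truth
  for (oc in c("mmse", "cdr_sb", "csf_ptau181", "csf_ab42_40")) {
    expected <- vapply(seq_len(nrow(co)), function(i)
      tr$curve(oc, as.character(co$group[i]), co$eyo[i]), 1.0)
    expect_equal(co[[oc]], expected, tolerance = 1e-12)
  }
  hv_bilat <- (co$hv_left + co$hv_right) / 2
  expected_hv <- vapply(seq_len(nrow(co)), function(i)
    tr$curve("hv", as.character(co$group[i]), co$eyo[i]), 1.0)
  expect_equal(hv_bilat, expected_hv, tolerance = 1e-9)
  expect_equal(composite_suvr(co),
               vapply(seq_len(nrow(co)), function(i)
                 tr$curve("pib", as.character(co$group[i]), co$eyo[i]), 1.0),
               tolerance = 1e-9)
})

test_that("truth difference curve is zero before divergence, matches direct evaluation", {
  cfg <- sim_config(n_nc = 2, n_cy = 2, n_tm = 2,
                    outcomes = list(hv = list(
                      level = 0, slope = 0, carrier_delta = 5,
                      carrier_hinge = -18, tm_divergence = -10, tm_delta = 2,
                      ramp_power = 1, ramp_scale = 10,
                      range = c(-1e6, 1e6))),
                    seed = 3)
  tr <- simulate_cohort(cfg)$truth
  g <- seq(-25, 10, by = 0.5)
  d <- truth_difference_curve(tr, "hv", g)
  expect_true(all(d[g < -10] == 0))
  expect_true(any(d[g >= -10] != 0))
  # closed-form oracle: the carrier term cancels, the TM ramp remains
  expect_equal(d, 2 * pmax((g + 10) / 10, 0), tolerance = 1e-12)
  expect_equal(tr$divergence_eyo[["hv"]], -10)
  # identical TM/CY curves: all-zero difference and no divergence point
  cfg0 <- sim_config(n_nc = 2, n_cy = 2, n_tm = 2,
                     outcomes = list(hv = list(tm_delta = 0)), seed = 3)
  tr0 <- simulate_cohort(cfg0)$truth
  expect_true(all(truth_difference_curve(tr0, "hv", g) == 0))
  expect_true(is.na(tr0$divergence_eyo[["hv"]]))
  expect_error(truth_difference_curve(tr, "nope", g), "unknown outcome")
  expect_error(truth_difference_curve(tr, "hv", c(-30, 0)), "range")
})

test_that("empirical group means converge to the truth curves", {
  cfg <- sim_config(n_nc = 4000, n_cy = 4000, n_tm = 4000,
                    visit_probs = c(`1` = 1), seed = 77)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  tr <- sim$truth
  p <- cfg$outcomes$mmse
  sd_obs <- sqrt(p$sigma_family^2 + p$sigma_subject^2 + p$sigma_resid^2)
  bins <- cut(co$eyo, breaks = seq(-25, 10, by = 2.5))
  for (g in c("NC", "CY", "TM")) {
    rows <- co$group == g
    for (b in levels(bins)) {
      sel <- rows & bins == b & !is.na(bins)
      n <- sum(sel)
      if (n < 50) next
      expected <- mean(tr$curve("mmse", g, co$eyo[sel]))
      se <- sd_obs / sqrt(n)
      expect_lt(abs(mean(co$mmse[sel]) - expected), 3 * se + 0.02)
    }
  }
})

test_that("within-family correlation matches the variance-component ratio", {
  cfg <- sim_config(n_nc = 1500, n_cy = 1500, n_tm = 1500,
                    family_size_probs = c(`2` = 1),
                    visit_probs = c(`1` = 1),
                    outcomes = list(mmse = list(sigma_family = 1,
                                                sigma_subject = 0,
                                                sigma_resid = 1,
                                                carrier_delta = 0,
                                                tm_delta = 0)),
                    seed = 13)
  sim <- simulate_cohort(cfg)
  co <- sim$cohort
  resid <- co$mmse - sim$truth$curve("mmse", "NC", co$eyo)
  # all groups share the NC curve here (no carrier effects)
  sp <- split(resid, co$family_id)
  pairs <- t(vapply(sp[lengths(sp) == 2], identity, numeric(2)))
  icc <- stats::cor(pairs[, 1], pairs[, 2])
  expect_lt(abs(icc - 0.5), 0.05) # 1^2 / (1^2 + 1^2)
})

test_that("noiseless longitudinal slopes equal the generating slope", {
  cfg <- sim_config(n_nc = 6, n_cy = 6, n_tm = 6,
                    visit_probs = c(`3` = 1),
                    outcomes = list(mmse = list(
                      level = 25, slope = -1.2, carrier_delta = 0,
                      tm_delta = 0, sigma_family = 0, sigma_subject = 0,
                      sigma_resid = 0, range = c(-1e6, 1e6))),
                    seed = 21)
  co <- simulate_cohort(cfg)$cohort
  sl <- subject_slopes(co, "mmse")
  expect_equal(sl$slope, rep(-1.2, nrow(sl)), tolerance = 1e-10)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_cy = 0), "at least one subject")
  expect_error(sim_config(visit_interval_mean = 0), "positive")
  expect_error(sim_config(eyo_range = c(5, -5)), "min < max")
  expect_error(sim_config(outcomes = list(mmse = list(sigma_resid = -1))),
               "negative SD")
})

test_that("cohort and truth round-trip through their on-disk formats", {
  sim <- simulate_cohort(sim_config(n_nc = 6, n_cy = 6, n_tm = 6, seed = 4))
  pre <- file.path(tempdir(), "rt")
  paths <- write_cohort(sim, pre)
  back <- read_cohort(paths[["cohort"]])
  expect_equal(nrow(back), nrow(sim$cohort))
  expect_equal(back$mmse, sim$cohort$mmse, tolerance = 1e-12)
  expect_equal(as.character(back$group), as.character(sim$cohort$group))
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$divergence_eyo$mmse,
               sim$truth$divergence_eyo[["mmse"]])
})
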