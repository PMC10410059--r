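#' Mediation of group differences by a brain measure
#'
#' Tests whether group differences in a mediator (canonically ICV-adjusted
#' hippocampal volume) statistically account for group differences in a
#' cognitive outcome, using sequential standardized regressions and a
#' product-of-coefficients indirect effect with a percentile bootstrap:
#' \itemize{
#'   \item direct: outcome ~ group + covariates (coefficient of group);
#'   \item mediator model: outcome ~ mediator + group + covariates
#'     (coefficients of mediator and the residual direct effect of group);
#'   \item path a: mediator ~ group + covariates.
#' }
#' Outcome, mediator and continuous covariates are z-scored on the analysis
#' sample, the group contrast stays a binary indicator, so coefficients are
#' in outcome-SD units per group switch. For ordinary linear fits the exact
#' identity `direct = residual_direct + indirect` holds. Baseline visits
#' only (one row per subject); the bootstrap resamples whole families within
#' group strata.
#'
#' @param data model-ready table ([assemble()] output).
#' @param outcome,mediator column names.
#' @param groups length-2: indicator is 1 for `groups[1]`, 0 for
#'   `groups[2]`; other rows are dropped.
#' @param covariates covariate columns (default: the trajectory-model set).
#' @param n_boot bootstrap replicates (>= 100), default 5000.
#' @param seed integer seed.
#' @param conf CI level for the bootstrap percentile intervals.
#' @return object of class `psen1_mediation` with elements `direct`,
#'   `mediator_effect`, `residual_direct` (each `est`, `se`, `p`),
#'   `indirect` (`est`, `ci`), `full_mediation` flag, `n`, `n_boot`, `seed`.
#' @export
mediate_groups <- function(data, outcome = "mmse", mediator = "hv",
                           groups = c("TM", "CY"),
                           covariates = c("eyo", "visit_age", "sex",
                                          "apoe4", "education"),
                           n_boot = 5000L, seed = 1L, conf = 0.95) {
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  d <- as.data.frame(data)
  need <- c(outcome, mediator, "group", "subject_id", "family_id", covariates)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  # baseline visit = first visit per subject
  ord <- order(d$subject_id, d$visit_age)
  d <- d[ord, ]
  d <- d[!duplicated(d$subject_id), ]
  d <- d[d$group %in% groups, ]
  d <- d[stats::complete.cases(d[, c(outcome, mediator, covariates)]), ]
  n <- nrow(d)
  if (n < 10L) stop("too few complete baseline cases (", n, ")", call. = FALSE)
  if (stats::sd(d[[mediator]]) == 0)
    stop("mediator is constant", call. = FALSE)

  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  y <- zs(d[[outcome]])
  m <- zs(d[[mediator]])
  g <- as.numeric(d$group == groups[1])
  Cc <- lapply(covariates, function(cv) {
    v <- d[[cv]]
    if (is.numeric(v)) {
      matrix(zs(v), ncol = 1, dimnames = list(NULL, cv))
    } else {
      mm <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, seq_len(ncol(mm)))
      mm
    }
  })
  C <- do.call(cbind, Cc)

  paths <- function(y, m, g, C) {
    X1 <- cbind(`(Intercept)` = 1, g = g, C)
    X2 <- cbind(`(Intercept)` = 1, m = m, g = g, C)
    f1 <- stats::lm.fit(X1, y)   # direct
    f2 <- stats::lm.fit(X2, y)   # mediator + residual direct
    f3 <- stats::lm.fit(X1, m)   # path a
    cf <- function(f, nm) {
      b <- f$coefficients[nm]
      if (is.na(b)) 0 else unname(b)
    }
    list(direct = cf(f1, "g"), b = cf(f2, "m"), resid_direct = cf(f2, "g"),
         a = cf(f3, "g"), aliased = anyNA(f2$coefficients),
         fits = list(f1, f2, f3))
  }
  pt <- paths(y, m, g, C)

  se_p <- function(f, nm) {
    rdf <- f$df.residual
    if (rdf <= 0 || f$rank < 1L) return(c(NA_real_, NA_real_))
    sig2 <- sum(f$residuals^2) / rdf
    R <- qr.R(f$qr)[seq_len(f$rank), seq_len(f$rank), drop = FALSE]
    nm_used <- names(f$coefficients)[f$qr$pivot[seq_len(f$rank)]]
    ses <- stats::setNames(sqrt(diag(chol2inv(R)) * sig2), nm_used)
    if (!nm %in% names(ses)) return(c(NA_real_, NA_real_))
    se <- ses[[nm]]
    if (se == 0) return(c(0, NA_real_))
    tval <- f$coefficients[[nm]] / se
    c(se, 2 * stats::pt(-abs(tval), rdf))
  }
  d_sp <- se_p(pt$fits[[1]], "g")
  b_sp <- se_p(pt$fits[[2]], "m")
  r_sp <- se_p(pt$fits[[2]], "g")

  # percentile bootstrap over families within group strata
  fam_key <- paste(d$group, d$family_id)
  fams_by_group <- split(seq_len(n), fam_key)
  group_of_fam <- vapply(fams_by_group, function(i) as.character(d$group[i[1]]), "")
  set.seed(.split_seed(seed, 20L))
  boot <- matrix(NA_real_, n_boot, 2L,
                 dimnames = list(NULL, c("indirect", "resid_direct")))
  fam_ids <- names(fams_by_group)
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(gr) {
      pool <- fam_ids[group_of_fam == gr]
      unlist(fams_by_group[sample(pool, length(pool), replace = TRUE)],
             use.names = FALSE)
    }), use.names = FALSE)
    pb <- paths(y[idx], m[idx], g[idx], C[idx, , drop = FALSE])
    boot[b, ] <- c(pb$a * pb$b, pb$resid_direct)
  }
  a_ci <- (1 - conf) / 2
  ind_ci <- unname(stats::quantile(boot[, "indirect"], c(a_ci, 1 - a_ci)))
  rd_ci <- unname(stats::quantile(boot[, "resid_direct"], c(a_ci, 1 - a_ci)))

  full_mediation <- isTRUE(d_sp[2] < 0.05) &&
    (is.na(r_sp[2]) || r_sp[2] >= 0.05) &&
    (ind_ci[1] > 0 || ind_ci[2] < 0)

  structure(list(
    direct = list(est = pt$direct, se = d_sp[1], p = d_sp[2]),
    mediator_effect = list(est = pt$b, se = b_sp[1], p = b_sp[2]),
    residual_direct = list(est = pt$resid_direct, se = r_sp[1], p = r_sp[2],
                           ci = rd_ci, aliased = pt$aliased),
    indirect = list(est = pt$a * pt$b, ci = ind_ci),
    path_a = pt$a,
    full_mediation = full_mediation,
    outcome = outcome, mediator = mediator, groups = groups,
    covariates = covariates, n = n, n_boot = n_boot, seed = as.integer(seed),
    conf = conf), class = "psen1_mediation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psen1_mediation <- function(x, ...) {
  cat(sprintf("Mediation of %s-vs-%s differences in '%s' by '%s' (n = %d)\n",
              x$groups[1], x$groups[2], x$outcome, x$mediator, x$n))
  fmt <- function(nm, e) cat(sprintf("  %-16s beta = %6.3f  p = %s\n", nm,
                                     e$est, format.pval(e$p, digits = 3)))
  fmt("direct", x$direct)
  fmt("mediator", x$mediator_effect)
  fmt("residual direct", x$residual_direct)
  cat(sprintf("  indirect (a*b)   beta = %6.3f  %d%% bootstrap CI [%.3f, %.3f]\n",
              x$indirect$est, round(100 * x$conf), x$indirect$ci[1],
              x$indirect$ci[2]))
  cat(if (x$full_mediation) "  -> consistent with full mediation\n"
      else "  -> not consistent with full mediation\n")
  invisible(x)
}

#' @export
as.data.frame.psen1_mediation <- function(x, ...) {
  data.frame(outcome = x$outcome, mediator = x$mediator,
             contrast = paste(x$groups, collapse = " vs "),
             direct = x$direct$est, direct_p = x$direct$p,
             mediator_effect = x$mediator_effect$est,
             mediator_p = x$mediator_effect$p,
             residual_direct = x$residual_direct$est,
             residual_direct_p = x$residual_direct$p,
             indirect = x$indirect$est,
             indirect_lo = x$indirect$ci[1], indirect_hi = x$indirect$ci[2],
             full_mediation = x$full_mediation,
             n = x$n, n_boot = x$n_boot, seed = x$seed)
}
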