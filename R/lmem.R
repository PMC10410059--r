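#' Fit the EYO trajectory mixed model
#'
#' The package's central estimator: a linear mixed-effects model of one
#' outcome over expected years to symptom onset (EYO), with EYO entering
#' either linearly or as a restricted cubic spline (knots at empirical EYO
#' quantiles, default 0.10/0.50/0.90), a group main effect, group
#' interactions with every EYO basis column, demographic covariates, and a
#' family random intercept. Estimation is by maximum likelihood (not REML)
#' so that likelihood-ratio comparisons of fixed-effect structures are valid
#' and reported estimates come from the same fit.
#'
#' Covariates default to sex, APOE e4 status and age at visit, plus years of
#' education for clinical/cognitive outcomes (`mmse`, `cdr_sb`). Inference
#' on fixed effects uses the normal reference; see the methods vignette for
#' why and for the known limitations.
#'
#' @param data model-ready table from [assemble()] (or any data frame with
#'   the needed columns).
#' @param outcome name of the outcome column.
#' @param eyo_form `"rcs"` (restricted cubic spline) or `"linear"`.
#' @param group_var `"group"` (NC/CY/TM) or `"codon_group"`
#'   (pre200/post200; non-carriers are excluded).
#' @param covariates explicit covariate names, or `NULL` for the default
#'   set.
#' @param extra_covariates additional fixed-effect columns (e.g. `pib` and
#'   `csf_ptau181` for the pathology-adjusted sensitivity model).
#' @param knot_probs quantile probabilities for knot placement.
#' @param knots explicit knot locations (overrides `knot_probs`).
#' @param knot_sample `"pooled"` (all rows entering the model; default) or
#'   `"carriers"`.
#' @param include_age include age at visit as a covariate (default TRUE; a
#'   warning is raised if age and EYO are nearly collinear).
#' @param clinical_outcomes outcomes that get the education covariate.
#' @param ref_group reference level for the group factor; default NC when
#'   present (contrasts are then reported relative to non-carriers).
#' @return object of class `eyo_lmem`: fixed-effect estimates `beta`, their
#'   covariance `vcov`, `se`, variance components `var_family` and
#'   `var_resid`, `loglik`, `n_obs`, `n_families`, a `converged` flag, the
#'   resolved `knots`, and the underlying `lme4` fit in `$fit`.
#' @seealso [wald_contrast()], [group_contrast()], [lrt_select()],
#'   [posterior_draws()], [divergence_analysis()]
#' @export
fit_eyo_lmem <- function(data, outcome,
                         eyo_form = c("rcs", "linear"),
                         group_var = c("group", "codon_group"),
                         covariates = NULL,
                         extra_covariates = character(),
                         knot_probs = c(0.10, 0.50, 0.90),
                         knots = NULL,
                         knot_sample = c("pooled", "carriers"),
                         include_age = TRUE,
                         clinical_outcomes = c("mmse", "cdr_sb"),
                         ref_group = NULL) {
  eyo_form <- match.arg(eyo_form)
  group_var <- match.arg(group_var)
  knot_sample <- match.arg(knot_sample)
  if (!outcome %in% names(data))
    stop("outcome '", outcome, "' not found in data", call. = FALSE)
  if (is.null(covariates)) {
    covariates <- c("sex", "apoe4")
    if (include_age) covariates <- c(covariates, "visit_age")
    if (outcome %in% clinical_outcomes) covariates <- c(covariates, "education")
  }
  covariates <- union(covariates, extra_covariates)
  need <- c(outcome, "eyo", group_var, "family_id", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  d <- as.data.frame(data)[, need]
  names(d)[1] <- ".y"
  names(d)[3] <- ".group"
  keep <- stats::complete.cases(d)
  d <- d[keep, , drop = FALSE]
  d$.group <- droplevels(factor(d$.group))
  if (nlevels(d$.group) < 2L)
    stop("singular design: need at least two non-empty groups, got: ",
         paste(levels(d$.group), collapse = ", "), call. = FALSE)
  ref <- ref_group %||% intersect(c("NC", "CY", "pre200"), levels(d$.group))[1]
  if (!ref %in% levels(d$.group))
    stop("ref_group '", ref, "' is not a group level", call. = FALSE)
  d$.group <- stats::relevel(d$.group, ref = ref)
  for (cv in covariates)
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])

  if ("visit_age" %in% covariates &&
      abs(stats::cor(d$eyo, d$visit_age)) > 0.95)
    warning("age at visit and EYO are nearly collinear (|r| > 0.95); ",
            "consider include_age = FALSE", call. = FALSE)

  if (eyo_form == "rcs") {
    if (is.null(knots)) {
      ksrc <- if (knot_sample == "carriers" && group_var == "group")
        d$eyo[d$.group != "NC"] else d$eyo
      knots <- knots_from_quantiles(ksrc, knot_probs)
    }
    basis <- rcs_basis(d$eyo, knots)
    eyo_cols <- paste0("eyo", seq_len(ncol(basis)))
    for (j in seq_along(eyo_cols)) d[[eyo_cols[j]]] <- basis[, j]
  } else {
    knots <- NULL
    eyo_cols <- "eyo1"
    d$eyo1 <- d$eyo
  }

  rhs <- c(covariates, eyo_cols, ".group",
           paste0(eyo_cols, ":.group"))
  fixed <- stats::reformulate(rhs, response = ".y")
  full <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + "),
                                  "+ (1 | family_id)"))
  p_fixed <- length(attr(stats::terms(fixed), "term.labels")) # rough lower bound
  if (nrow(d) <= p_fixed + 2L)
    stop("too few complete cases (", nrow(d), ") for the fixed effects",
         call. = FALSE)

  msgs <- character(0)
  fit <- withCallingHandlers(
    suppressMessages(lme4::lmer(full, data = d, REML = FALSE,
      control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                  check.nobs.vs.nRE = "ignore"))),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- length(conv_msgs) == 0L &&
    !any(grepl("failed to converge", msgs))
  singular <- lme4::isSingular(fit)

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  dimnames(V) <- list(names(beta), names(beta))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_family <- vc$vcov[vc$grp == "family_id"][1]
  var_resid <- stats::sigma(fit)^2
  if (nrow(d) < 10L * length(beta))
    warning("fewer than 10 complete cases per fixed effect; estimates may be ",
            "unstable", call. = FALSE)

  xlev <- list(.group = levels(d$.group))
  for (cv in covariates)
    if (is.factor(d[[cv]])) xlev[[cv]] <- levels(d[[cv]])
  cov_ref <- lapply(d[covariates], function(z)
    if (is.numeric(z)) mean(z) else factor(levels(z)[1], levels = levels(z)))

  structure(list(
    beta = beta, se = sqrt(diag(V)), vcov = V,
    var_family = var_family, var_resid = var_resid,
    loglik = as.numeric(stats::logLik(fit)),
    n_obs = nrow(d), n_families = length(unique(d$family_id)),
    converged = converged, singular = singular, messages = msgs,
    outcome = outcome, eyo_form = eyo_form, group_var = group_var,
    covariates = covariates, knots = knots, eyo_cols = eyo_cols,
    fixed_formula = fixed, xlev = xlev, cov_ref = cov_ref,
    group_levels = levels(d$.group), ref_group = ref,
    outcome_sd = stats::sd(d$.y),
    eyo_support = range(d$eyo),
    fit = fit), class = "eyo_lmem")
}

# fixed-effect design matrix for new data on an existing fit's scale
.eyo_design <- function(object, newdata) {
  nd <- as.data.frame(newdata)
  if (!".group" %in% names(nd)) {
    gv <- if (object$group_var %in% names(nd)) object$group_var else "group"
    if (!gv %in% names(nd)) stop("newdata needs a '", object$group_var,
                                 "' column", call. = FALSE)
    nd$.group <- nd[[gv]]
  }
  nd$.group <- factor(as.character(nd$.group), levels = object$xlev$.group)
  if (anyNA(nd$.group))
    stop("newdata has group levels absent from the fit", call. = FALSE)
  for (cv in object$covariates) {
    if (!cv %in% names(nd)) nd[[cv]] <- object$cov_ref[[cv]]
    if (!is.null(object$xlev[[cv]]))
      nd[[cv]] <- factor(as.character(nd[[cv]]), levels = object$xlev[[cv]])
  }
  if (object$eyo_form == "rcs") {
    basis <- rcs_basis(nd$eyo, object$knots)
    for (j in seq_along(object$eyo_cols)) nd[[object$eyo_cols[j]]] <- basis[, j]
  } else nd$eyo1 <- nd$eyo
  tt <- stats::delete.response(stats::terms(object$fixed_formula))
  mf <- stats::model.frame(tt, nd, xlev = object$xlev,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  X[, names(object$beta), drop = FALSE]
}

#' @export
print.eyo_lmem <- function(x, ...) {
  cat("EYO trajectory LMEM (", x$eyo_form, " EYO, ML) for '", x$outcome,
      "'\n", sep = "")
  cat(sprintf("  n = %d observations in %d families; logLik = %.2f\n",
              x$n_obs, x$n_families, x$loglik))
  if (!is.null(x$knots))
    cat("  knots:", paste(sprintf("%.2f", x$knots), collapse = ", "), "\n")
  cat(sprintf("  var(family) = %.4g, var(resid) = %.4g\n",
              x$var_family, x$var_resid))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
summary.eyo_lmem <- function(object, ...) {
  z <- object$beta / object$se
  tab <- data.frame(B = object$beta, SE = object$se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.eyo_lmem"
  out
}

#' @export
print.summary.eyo_lmem <- function(x, ...) {
  print(x$fit)
  cat("\nFixed effects (normal reference):\n")
  stats::printCoefmat(as.matrix(x$coefficients), P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.eyo_lmem <- function(object, ...) object$beta

#' @export
vcov.eyo_lmem <- function(object, ...) object$vcov

#' @export
logLik.eyo_lmem <- function(object, ...) {
  structure(object$loglik, df = length(object$beta) + 2L,
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.eyo_lmem <- function(object, ...) object$n_obs

#' Population-level predictions from an EYO trajectory model
#'
#' Fixed-effects-only predictions (random effects set to zero). `newdata`
#' needs `eyo` and the group column; covariates missing from `newdata` are
#' held at their reference values (means for continuous, reference level
#' for factors).
#'
#' @param object an `eyo_lmem`.
#' @param newdata data frame of prediction points.
#' @param se.fit also return standard errors of the linear predictor.
#' @param ... unused.
#' @return numeric vector, or list with `fit` and `se.fit`.
#' @export
predict.eyo_lmem <- function(object, newdata, se.fit = FALSE, ...) {
  X <- .eyo_design(object, newdata)
  est <- drop(X %*% object$beta)
  if (!se.fit) return(est)
  list(fit = est, se.fit = sqrt(rowSums((X %*% object$vcov) * X)))
}

#' @export
fitted.eyo_lmem <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.eyo_lmem <- function(object, ...) stats::residuals(object$fit)

#' @export
simulate.eyo_lmem <- function(object, nsim = 1, seed = NULL, ...)
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)

#' Wald test of a single fixed effect
#'
#' @param fit an `eyo_lmem`.
#' @param term coefficient name (see `names(coef(fit))`).
#' @return list with `B`, `SE`, `z`, `p` (two-sided, normal reference).
#' @export
wald_contrast <- function(fit, term) {
  stopifnot(inherits(fit, "eyo_lmem"))
  if (!term %in% names(fit$beta))
    stop("unknown term '", term, "'; available: ",
         paste(names(fit$beta), collapse = ", "), call. = FALSE)
  B <- unname(fit$beta[term]); SE <- unname(fit$se[term])
  z <- B / SE
  list(B = B, SE = SE, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pairwise group contrast on an EYO term
#'
#' Linear contrast of coefficients comparing two groups on the group main
#' effect or on a group-by-EYO-basis interaction; equivalent to refitting
#' with the other group as reference level.
#'
#' @param fit an `eyo_lmem`.
#' @param groups length-2 character vector, contrast is `groups[1] -
#'   groups[2]`.
#' @param term `"(group)"` for the main effect, or an EYO basis column name
#'   (`"eyo1"`, `"eyo2"`) for its interaction.
#' @return list with `B`, `SE`, `z`, `p`.
#' @export
group_contrast <- function(fit, groups = c("TM", "CY"), term = "eyo2") {
  stopifnot(inherits(fit, "eyo_lmem"), length(groups) == 2L)
  bad <- setdiff(groups, fit$group_levels)
  if (length(bad))
    stop("group(s) not in fit: ", paste(bad, collapse = ", "), call. = FALSE)
  cname <- function(g) {
    if (g == fit$ref_group) return(NA_character_)
    if (term == "(group)") paste0(".group", g) else paste0(term, ":.group", g)
  }
  if (term != "(group)" && !term %in% fit$eyo_cols)
    stop("unknown term '", term, "'; EYO basis columns: ",
         paste(fit$eyo_cols, collapse = ", "), call. = FALSE)
  L <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  for (s in c(1, -1)) {
    cn <- cname(groups[if (s == 1) 1 else 2])
    if (!is.na(cn)) {
      if (!cn %in% names(L))
        stop("coefficient '", cn, "' not in fit", call. = FALSE)
      L[cn] <- L[cn] + s
    }
  }
  B <- drop(L %*% fit$beta)
  SE <- sqrt(drop(t(L) %*% fit$vcov %*% L))
  z <- B / SE
  list(B = B, SE = SE, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Likelihood-ratio choice between linear and spline EYO forms
#'
#' Both fits must be maximum-likelihood fits of the same rows with nested
#' fixed effects. The spline form is retained iff the likelihood-ratio test
#' of the added nonlinear columns (and their group interactions) is
#' significant at `alpha`.
#'
#' @param fit_linear,fit_rcs `eyo_lmem` fits with `eyo_form` `"linear"` and
#'   `"rcs"`.
#' @param alpha selection level, default 0.05.
#' @return list of class `eyo_lrt`: `statistic`, `df`, `p`, `choice`
#'   (`"rcs"` or `"linear"`), and the chosen fit in `$fit`.
#' @export
lrt_select <- function(fit_linear, fit_rcs, alpha = 0.05) {
  stopifnot(inherits(fit_linear, "eyo_lmem"), inherits(fit_rcs, "eyo_lmem"))
  if (fit_linear$n_obs != fit_rcs$n_obs)
    stop("fits use different numbers of rows (", fit_linear$n_obs, " vs ",
         fit_rcs$n_obs, ")", call. = FALSE)
  df <- length(fit_rcs$beta) - length(fit_linear$beta)
  stat <- max(0, 2 * (fit_rcs$loglik - fit_linear$loglik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  choice <- if (df > 0L && p < alpha) "rcs" else "linear"
  structure(list(statistic = stat, df = df, p = p, alpha = alpha,
                 choice = choice,
                 fit = if (choice == "rcs") fit_rcs else fit_linear),
            class = "eyo_lrt")
}

#' @export
print.eyo_lrt <- function(x, ...) {
  cat(sprintf("LRT linear vs spline EYO: chi^2 = %.3f, df = %d, p = %.3g -> %s\n",
              x$statistic, x$df, x$p, x$choice))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (as applied to the CSF analyte
#' analyses); input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
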