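# split-chain convergence diagnostics for a draws matrix organised as
# iterations within chains (iter fastest); standard split-Rhat and a
# pair-summed autocorrelation ESS
.chain_diagnostics <- function(draws, n_chains) {
  n_total <- nrow(draws)
  iter <- n_total %/% n_chains
  half <- iter %/% 2L
  out <- data.frame(param = colnames(draws), rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  if (half < 4L) return(out)
  for (j in seq_len(ncol(draws))) {
    segs <- lapply(seq_len(n_chains), function(c) {
      x <- draws[((c - 1L) * iter + 1L):(c * iter), j]
      list(x[seq_len(half)], x[(half + 1L):(2L * half)])
    })
    segs <- unlist(segs, recursive = FALSE)
    m <- length(segs); n <- half
    means <- vapply(segs, mean, 1.0)
    vars <- vapply(segs, stats::var, 1.0)
    W <- mean(vars)
    B <- n * stats::var(means)
    varhat <- (n - 1) / n * W + B / n
    out$rhat[j] <- if (W > 0) sqrt(varhat / W) else NA_real_
    if (varhat <= 0) next
    # averaged autocovariance across split chains, Geyer pair truncation
    max_lag <- min(n - 1L, 200L)
    acov <- rowMeans(vapply(segs, function(x) {
      a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                      type = "covariance", demean = TRUE)$acf[, 1, 1]
      a
    }, numeric(max_lag + 1L)))
    rho <- 1 - (W - acov[-1L]) / varhat
    s <- 0; t <- 1L
    while (t + 1L <= length(rho)) {
      pair <- rho[t] + rho[t + 1L]
      if (pair < 0) break
      s <- s + pair
      t <- t + 2L
    }
    out$ess[j] <- min(m * n / (1 + 2 * s), m * n)
  }
  out
}

#' Draws from the posterior of the trajectory model's fixed effects
#'
#' Samples the fixed-effect vector of a fitted EYO trajectory model from its
#' normal-approximation posterior: the maximum-likelihood estimate and
#' covariance are combined by precision weighting with independent
#' weakly-informative normal(0, `prior_scale` * sd(outcome)) priors. Draws
#' are organised into chains purely for the split-chain convergence
#' diagnostics that are attached to (and never discarded from) the result.
#' With `prior_only = TRUE` the data are ignored and the prior itself is
#' sampled (prior-predictive mode).
#'
#' @param fit an [fit_eyo_lmem()] result.
#' @param n_draws total number of draws (>= 1000 for reported results).
#' @param seed integer seed; same seed, same draws.
#' @param n_chains chains for the diagnostics split.
#' @param prior_scale prior SD in units of the outcome SD.
#' @param prior_only sample the prior instead of the posterior.
#' @return object of class `eyo_posterior`: `draws` (n_draws x n_fixed),
#'   `diagnostics` (per-parameter split-chain statistic and effective sample
#'   size), `seed`, `n_chains`, and the originating `fit`.
#' @export
posterior_draws <- function(fit, n_draws = 4000, seed = 1L, n_chains = 4L,
                            prior_scale = 10, prior_only = FALSE) {
  stopifnot(inherits(fit, "eyo_lmem"))
  if (n_draws < 4L * n_chains) stop("n_draws too small", call. = FALSE)
  p <- length(fit$beta)
  prior_sd <- prior_scale * fit$outcome_sd
  if (prior_only) {
    mp <- rep(0, p)
    Vp <- diag(rep(prior_sd^2, p), p)
  } else {
    Vinv <- solve(fit$vcov)
    P <- Vinv + diag(rep(1 / prior_sd^2, p), p)
    Vp <- solve(P)
    Vp <- (Vp + t(Vp)) / 2
    mp <- drop(Vp %*% (Vinv %*% fit$beta))
  }
  iter <- ceiling(n_draws / n_chains)
  draws <- matrix(NA_real_, iter * n_chains, p,
                  dimnames = list(NULL, names(fit$beta)))
  for (c in seq_len(n_chains)) {
    set.seed(.split_seed(seed, 10L + c))
    draws[((c - 1L) * iter + 1L):(c * iter), ] <-
      MASS::mvrnorm(iter, mu = mp, Sigma = Vp)
  }
  diag_tab <- .chain_diagnostics(draws, n_chains)
  if (any(is.finite(diag_tab$rhat) & diag_tab$rhat > 1.05))
    stop("posterior sampling failed convergence diagnostics (max split ",
         "statistic = ", sprintf("%.3f", max(diag_tab$rhat, na.rm = TRUE)),
         ")", call. = FALSE)
  structure(list(draws = draws[seq_len(n_draws), , drop = FALSE],
                 diagnostics = diag_tab, seed = as.integer(seed),
                 n_chains = as.integer(n_chains),
                 prior_scale = prior_scale, prior_only = prior_only,
                 fit = fit), class = "eyo_posterior")
}

#' @export
print.eyo_posterior <- function(x, ...) {
  cat(sprintf("Posterior draws: %d draws x %d fixed effects (%d chains, seed %d)\n",
              nrow(x$draws), ncol(x$draws), x$n_chains, x$seed))
  cat(sprintf("  max split-chain statistic = %.3f, min ESS = %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior group-difference curves over EYO
#'
#' For every posterior draw and every grid point, the difference in the
#' expected outcome between two groups at identical covariate values. All
#' covariate terms cancel algebraically, so the curves depend only on the
#' group main effect and the group-by-EYO interactions; the result is
#' invariant to the reference covariate values used.
#'
#' @param post an [posterior_draws()] result.
#' @param eyo_grid grid of EYO values; default spans -25..10 at `step`,
#'   clipped to the observed EYO support of the fit. Grid points outside the
#'   support are an error (no extrapolated divergence).
#' @param groups length-2: difference is `groups[1] - groups[2]` (default TM
#'   minus CY).
#' @param step grid step in years when `eyo_grid` is NULL.
#' @param covariates optional named list of covariate reference values.
#' @return object of class `eyo_diffcurves`: `eyo_grid`, `diff_draws`
#'   (n_draws x n_grid), `groups`.
#' @export
difference_curves <- function(post, eyo_grid = NULL, groups = c("TM", "CY"),
                              step = 0.1, covariates = NULL) {
  stopifnot(inherits(post, "eyo_posterior"))
  fit <- post$fit
  sup <- fit$eyo_support
  if (is.null(eyo_grid)) {
    lo <- max(-25, sup[1]); hi <- min(10, sup[2])
    eyo_grid <- seq(ceiling(lo / step) * step, hi, by = step)
  }
  if (any(eyo_grid < sup[1] - 1e-9) || any(eyo_grid > sup[2] + 1e-9))
    stop("grid extends beyond the observed EYO support [",
         sprintf("%.2f, %.2f", sup[1], sup[2]),
         "]; divergence is not extrapolated", call. = FALSE)
  if (any(diff(eyo_grid) <= 0))
    stop("eyo_grid must be strictly increasing", call. = FALSE)
  nd <- function(g) {
    base <- data.frame(eyo = eyo_grid, .group = g)
    if (!is.null(covariates))
      for (nm in names(covariates)) base[[nm]] <- covariates[[nm]]
    base
  }
  Xd <- .eyo_design(fit, nd(groups[1])) - .eyo_design(fit, nd(groups[2]))
  structure(list(eyo_grid = eyo_grid,
                 diff_draws = post$draws %*% t(Xd),
                 groups = groups, seed = post$seed),
            class = "eyo_diffcurves")
}

#' First EYO of persistent group divergence
#'
#' Computes an equal-tailed credible interval of the group difference at
#' every grid point and reports the earliest EYO at which the interval
#' excludes zero *and keeps excluding zero at every later grid point* (the
#' persistence rule; transient crossings do not count). Returns no
#' divergence point when no such EYO exists.
#'
#' @param curves an [difference_curves()] result.
#' @param level credible level in (0, 1), default 0.99.
#' @param hpd use highest-posterior-density intervals instead of
#'   equal-tailed.
#' @return object of class `eyo_divergence`: `divergence_eyo` (NA if none),
#'   `level`, `eyo_grid`, `lower`, `upper`, `median`, `groups`.
#' @export
divergence_point <- function(curves, level = 0.99, hpd = FALSE) {
  stopifnot(inherits(curves, "eyo_diffcurves"))
  if (level <= 0 || level >= 1)
    stop("credible level must be in (0, 1)", call. = FALSE)
  nd <- nrow(curves$diff_draws)
  if (nd < 100L) stop("need at least 100 draws", call. = FALSE)
  if (nd < 1000L)
    warning("fewer than 1000 draws; intervals are noisy", call. = FALSE)
  a <- (1 - level) / 2
  if (hpd) {
    bounds <- apply(curves$diff_draws, 2, function(x) {
      x <- sort(x)
      k <- max(1L, floor(level * length(x)))
      w <- x[(k):length(x)] - x[seq_len(length(x) - k + 1L)]
      i <- which.min(w)
      c(x[i], x[i + k - 1L])
    })
  } else {
    bounds <- apply(curves$diff_draws, 2, stats::quantile,
                    probs = c(a, 1 - a), names = FALSE)
  }
  lower <- bounds[1, ]; upper <- bounds[2, ]
  excl <- lower > 0 | upper < 0
  suffix_all <- rev(cumprod(rev(excl)) == 1)
  div <- if (any(suffix_all)) curves$eyo_grid[which(suffix_all)[1]] else NA_real_
  structure(list(divergence_eyo = div, level = level,
                 eyo_grid = curves$eyo_grid, lower = lower, upper = upper,
                 median = apply(curves$diff_draws, 2, stats::median),
                 groups = curves$groups, persistence = TRUE, hpd = hpd,
                 n_draws = nd), class = "eyo_divergence")
}

#' @export
print.eyo_divergence <- function(x, ...) {
  cat(sprintf("Divergence of %s - %s (%.0f%% credible interval, %d draws):\n",
              x$groups[1], x$groups[2], 100 * x$level, x$n_draws))
  if (is.na(x$divergence_eyo)) {
    cat("  no persistent divergence on the evaluated EYO grid\n")
  } else {
    cat(sprintf("  first persistent divergence at EYO = %.1f years\n",
                x$divergence_eyo))
  }
  invisible(x)
}

#' @export
plot.eyo_divergence <- function(x, ...) {
  graphics::plot(x$eyo_grid, x$median, type = "l",
                 ylim = range(c(x$lower, x$upper, 0)),
                 xlab = "EYO (years)",
                 ylab = paste(x$groups[1], "-", x$groups[2], "difference"),
                 ...)
  graphics::polygon(c(x$eyo_grid, rev(x$eyo_grid)),
                    c(x$lower, rev(x$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::abline(h = 0, lty = 2)
  if (!is.na(x$divergence_eyo))
    graphics::abline(v = x$divergence_eyo, lty = 3)
  invisible(x)
}

#' End-to-end divergence analysis for one outcome
#'
#' Fits the trajectory model, samples the fixed-effect posterior, forms the
#' TM-minus-CY difference curves and locates the first persistent
#' divergence. The pathology-adjusted sensitivity variant is this same
#' pipeline with `extra_covariates = c("pib", "csf_ptau181")`.
#'
#' @inheritParams fit_eyo_lmem
#' @inheritParams posterior_draws
#' @inheritParams divergence_point
#' @param groups groups to difference (default TM minus CY).
#' @param step grid step, years.
#' @param ... passed to [fit_eyo_lmem()].
#' @return an `eyo_divergence` with the fit attached as attribute `"fit"`.
#' @export
divergence_analysis <- function(data, outcome, eyo_form = "rcs",
                                groups = c("TM", "CY"), n_draws = 4000,
                                seed = 1L, level = 0.99, step = 0.1, ...) {
  fit <- fit_eyo_lmem(data, outcome, eyo_form = eyo_form, ...)
  post <- posterior_draws(fit, n_draws = n_draws, seed = seed)
  dc <- difference_curves(post, groups = groups, step = step)
  res <- divergence_point(dc, level = level)
  attr(res, "fit") <- fit
  res
}
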