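#' Per-subject annualized slopes
#'
#' Extracts each subject's annualized rate of change on one outcome: an
#' ordinary least-squares slope of the outcome on years since the subject's
#' first visit (default), or the subject-level BLUP slope from a random-
#' slope mixed model (`method = "blup"`, as a sensitivity alternative).
#' Subjects with fewer than two distinct non-missing time points get no
#' slope; they are listed in the `"excluded"` attribute, never silently
#' dropped.
#'
#' @param data visit-level data with `subject_id`, `group`, `visit_age`,
#'   `eyo` and the outcome column.
#' @param outcome outcome column name.
#' @param method `"ols"` (per-subject least squares) or `"blup"`.
#' @return data frame of class `slope_table`: `subject_id`, `group`,
#'   `baseline_eyo`, `slope` (outcome units per year), `n_visits`,
#'   `followup_years`; attribute `"excluded"` lists subjects without a
#'   slope and the reason.
#' @export
subject_slopes <- function(data, outcome, method = c("ols", "blup")) {
  method <- match.arg(method)
  d <- as.data.frame(data)
  need <- c("subject_id", "group", "visit_age", "eyo", outcome)
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- d[!is.na(d[[outcome]]) & !is.na(d$visit_age), ]
  sp <- split(d, d$subject_id)
  rows <- lapply(sp, function(s) {
    t <- s$visit_age - min(s$visit_age)
    data.frame(subject_id = s$subject_id[1],
               group = as.character(s$group[1]),
               baseline_eyo = s$eyo[which.min(s$visit_age)],
               n_visits = nrow(s),
               followup_years = max(t),
               distinct_t = length(unique(t)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  usable <- tab$distinct_t >= 2L
  excluded <- data.frame(
    subject_id = tab$subject_id[!usable],
    reason = ifelse(tab$n_visits[!usable] < 2L, "single visit",
                    "visits at identical times"))
  tab$slope <- NA_real_
  if (method == "ols") {
    for (id in tab$subject_id[usable]) {
      s <- sp[[id]]
      t <- s$visit_age - min(s$visit_age)
      y <- s[[outcome]]
      tab$slope[tab$subject_id == id] <-
        sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    }
  } else {
    dd <- d[d$subject_id %in% tab$subject_id[usable], ]
    dd$.t <- stats::ave(dd$visit_age, dd$subject_id,
                        FUN = function(a) a - min(a))
    dd$.y <- dd[[outcome]]
    mfit <- suppressMessages(
      lme4::lmer(.y ~ .t + (1 + .t | subject_id), data = dd, REML = FALSE))
    re <- lme4::ranef(mfit)$subject_id
    sl <- lme4::fixef(mfit)[[".t"]] + re[, ".t"]
    tab$slope[match(rownames(re), tab$subject_id)] <- sl
  }
  tab <- tab[, c("subject_id", "group", "baseline_eyo", "slope",
                 "n_visits", "followup_years")]
  structure(tab, excluded = excluded, outcome = outcome, method = method,
            class = c("slope_table", "data.frame"))
}

#' Compare group rates of change past a divergence threshold
#'
#' Restricts the slope table to subjects whose baseline EYO is at or past
#' `threshold_eyo` (the cross-sectional divergence point feeds in here) and
#' compares the two groups' annualized slopes with a two-sample t-test:
#' Welch by default, pooled-variance Student with `var_equal = TRUE`.
#'
#' @param slopes a [subject_slopes()] table.
#' @param threshold_eyo baseline-EYO threshold, years; subjects with
#'   `baseline_eyo >= threshold_eyo` are kept.
#' @param groups length-2 groups to compare (default TM vs CY).
#' @param var_equal pooled-variance Student t instead of Welch.
#' @return object of class `slope_comparison`: `t`, `df`, `p`, per-group
#'   `means`, `sds`, `ns`, the `threshold_eyo` used and the test flavour.
#' @export
compare_slopes <- function(slopes, threshold_eyo, groups = c("TM", "CY"),
                           var_equal = FALSE) {
  s <- as.data.frame(slopes)
  s <- s[!is.na(s$slope) & s$group %in% groups &
           s$baseline_eyo >= threshold_eyo, ]
  x <- s$slope[s$group == groups[1]]
  y <- s$slope[s$group == groups[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("fewer than 2 ", paste(groups[c(length(x) < 2L, length(y) < 2L)],
                                collapse = " and "),
         " subjects remain at threshold EYO >= ", threshold_eyo,
         call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 means = stats::setNames(c(mean(x), mean(y)), groups),
                 sds = stats::setNames(c(stats::sd(x), stats::sd(y)), groups),
                 ns = stats::setNames(c(length(x), length(y)), groups),
                 threshold_eyo = threshold_eyo,
                 method = if (var_equal) "student" else "welch",
                 outcome = attr(slopes, "outcome")),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Annualized slopes, %s vs %s (baseline EYO >= %.1f, %s t-test)\n",
              names(x$means)[1], names(x$means)[2], x$threshold_eyo,
              x$method))
  for (g in names(x$means))
    cat(sprintf("  %s: n = %d, mean = %.3f (SD %.3f) per year\n",
                g, x$ns[[g]], x$means[[g]], x$sds[[g]]))
  cat(sprintf("  t(%.1f) = %.2f, p = %s\n", x$df, x$t,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' @export
as.data.frame.slope_comparison <- function(x, ...) {
  data.frame(outcome = x$outcome %||% NA_character_,
             group1 = names(x$means)[1], group2 = names(x$means)[2],
             threshold_eyo = x$threshold_eyo, method = x$method,
             t = x$t, df = x$df, p = x$p,
             mean1 = x$means[[1]], mean2 = x$means[[2]],
             sd1 = x$sds[[1]], sd2 = x$sds[[2]],
             n1 = x$ns[[1]], n2 = x$ns[[2]])
}
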