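#' Baseline demographics with between-group tests
#'
#' One baseline row per subject; continuous characteristics are summarised
#' as mean (SD) and compared with two-sample t-tests, categorical ones as
#' percentages compared with chi-square tests on the contingency counts
#' (no continuity correction by default). Pairwise comparisons (CY vs NC,
#' TM vs NC, TM vs CY) are unadjusted for multiplicity, and significance
#' flags use p < 0.05.
#'
#' @param data visit-level table with `subject_id`, `group`, `sex`,
#'   `apoe4`, `education`, `visit_age`, `expected_aao`, `eyo`.
#' @param yates apply the continuity correction in the chi-square tests.
#' @return object of class `demographics_report`: `summary` (formatted
#'   per-group values), `pvalues` (full precision), `flags`.
#' @export
demographics <- function(data, yates = FALSE) {
  d <- as.data.frame(data)
  d <- d[order(d$subject_id, d$visit_age), ]
  d <- d[!duplicated(d$subject_id), ]
  d$group <- droplevels(factor(d$group, levels = c("NC", "CY", "TM")))
  groups <- levels(d$group)
  small <- names(which(table(d$group) < 2L))
  if (length(small))
    warning("group(s) with < 2 subjects, tests suppressed: ",
            paste(small, collapse = ", "), call. = FALSE)

  chars <- list(
    `Female, %` = list(var = "sex", type = "cat", level = "F"),
    `Education, years` = list(var = "education", type = "num"),
    `APOE e4+, %` = list(var = "apoe4", type = "cat", level = "carrier"),
    `Age at visit, years` = list(var = "visit_age", type = "num"),
    `AAO, years` = list(var = "expected_aao", type = "num"),
    `EYO, years` = list(var = "eyo", type = "num"))
  chars <- Filter(function(ch) ch$var %in% names(d), chars)
  pairs <- list(c("CY", "NC"), c("TM", "NC"), c("TM", "CY"))
  pairs <- Filter(function(p) all(p %in% groups), pairs)

  cell <- function(ch, g) {
    v <- d[[ch$var]][d$group == g]
    if (ch$type == "num") sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
    else sprintf("%.1f", 100 * mean(v == ch$level))
  }
  test <- function(ch, p) {
    if (any(p %in% small)) return(NA_real_)
    a <- d[d$group == p[1], ]; b <- d[d$group == p[2], ]
    if (ch$type == "num") {
      stats::t.test(a[[ch$var]], b[[ch$var]])$p.value
    } else {
      counts <- rbind(table(factor(a[[ch$var]] == ch$level, c(FALSE, TRUE))),
                      table(factor(b[[ch$var]] == ch$level, c(FALSE, TRUE))))
      if (any(colSums(counts) == 0)) return(NA_real_)
      suppressWarnings(stats::chisq.test(counts, correct = yates)$p.value)
    }
  }
  summ <- data.frame(characteristic = names(chars))
  for (g in groups)
    summ[[g]] <- vapply(chars, cell, "", g = g)
  pv <- data.frame(characteristic = names(chars))
  for (p in pairs)
    pv[[paste(p, collapse = "_vs_")]] <- vapply(chars, test, 1.0, p = p)
  flags <- pv
  flags[-1] <- lapply(pv[-1], function(x) !is.na(x) & x < 0.05)
  structure(list(summary = summ, pvalues = pv, flags = flags,
                 n = table(d$group)), class = "demographics_report")
}

#' @export
print.demographics_report <- function(x, ...) {
  hdr <- sprintf("%s (N = %d)", names(x$n), as.integer(x$n))
  tab <- x$summary
  names(tab)[-1] <- hdr
  print(tab, row.names = FALSE)
  cat("\nPairwise p-values (t / chi-square, unadjusted):\n")
  pv <- x$pvalues
  pv[-1] <- lapply(pv[-1], function(p) format.pval(p, digits = 3))
  print(pv, row.names = FALSE)
  invisible(x)
}

#' Fit and tabulate trajectory models for a set of outcomes
#'
#' The batch driver behind the model report: for each outcome it fits the
#' linear and spline EYO forms, keeps the spline only if the likelihood-
#' ratio test retains it, and tabulates every pairwise group contrast on
#' every EYO-by-group interaction term. P-values for CSF outcomes are
#' additionally Benjamini-Hochberg adjusted across analytes within each
#' (term, contrast) family.
#'
#' @param data model-ready table ([assemble()] output).
#' @param outcomes outcome column names to model.
#' @param group_var `"group"` or `"codon_group"`.
#' @param csf_outcomes outcomes treated as CSF analytes for BH adjustment.
#' @param alpha model-selection level for [lrt_select()].
#' @param ... passed to [fit_eyo_lmem()].
#' @return data frame of class `trajectory_report`: one row per outcome x
#'   EYO term x group contrast with `B`, `SE`, `z`, `p`, `p_bh`, plus the
#'   chosen EYO form per outcome; fitted models in attribute `"fits"`.
#' @export
trajectory_report <- function(data, outcomes = c("mmse", "cdr_sb", "hv", "pib"),
                              group_var = "group",
                              csf_outcomes = c("csf_ptau181", "csf_ab42_40"),
                              alpha = 0.05, ...) {
  term_label <- c(eyo1 = "Linear EYO*group", eyo2 = "Cubic EYO*group")
  rows <- list()
  fits <- list()
  for (oc in outcomes) {
    fl <- fit_eyo_lmem(data, oc, eyo_form = "linear", group_var = group_var, ...)
    fit <- fl
    sel <- NULL
    rcs_ok <- tryCatch({
      fr <- fit_eyo_lmem(data, oc, eyo_form = "rcs", group_var = group_var, ...)
      sel <- lrt_select(fl, fr, alpha = alpha)
      fit <- sel$fit
      TRUE
    }, error = function(e) FALSE)
    fits[[oc]] <- fit
    lv <- fit$group_levels
    pair_list <- Filter(function(p) all(p %in% lv),
                        list(c("TM", "NC"), c("CY", "NC"), c("TM", "CY"),
                             c("post200", "pre200")))
    for (term in fit$eyo_cols) {
      for (p in pair_list) {
        ct <- group_contrast(fit, groups = p, term = term)
        rows[[length(rows) + 1L]] <- data.frame(
          outcome = oc,
          eyo_form = fit$eyo_form,
          term = if (term %in% names(term_label)) term_label[[term]] else term,
          contrast = paste(p, collapse = " vs "),
          B = ct$B, SE = ct$SE, z = ct$z, p = ct$p,
          lrt_p = if (!is.null(sel)) sel$p else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- NA_real_
  is_csf <- out$outcome %in% csf_outcomes
  if (any(is_csf)) {
    for (key in unique(paste(out$term, out$contrast)[is_csf])) {
      sel_rows <- is_csf & paste(out$term, out$contrast) == key
      out$p_bh[sel_rows] <- bh_adjust(out$p[sel_rows])
    }
  }
  structure(out, fits = fits, class = c("trajectory_report", "data.frame"))
}

#' @export
as.data.frame.eyo_divergence <- function(x, ...) {
  data.frame(eyo = x$eyo_grid, lower = x$lower, median = x$median,
             upper = x$upper)
}

#' One-row summary of a divergence result
#'
#' @param x an `eyo_divergence`.
#' @param outcome optional outcome label.
#' @return one-row data frame.
#' @export
divergence_summary <- function(x, outcome = NA_character_) {
  stopifnot(inherits(x, "eyo_divergence"))
  data.frame(outcome = outcome,
             divergence_eyo = x$divergence_eyo,
             level = x$level, n_draws = x$n_draws,
             groups = paste(x$groups, collapse = " vs "),
             persistence = x$persistence)
}

#' Write a reproducible run archive
#'
#' Collects stage outputs into one directory of delimited-text reports: for
#' every stage a full-precision machine-readable CSV plus a fixed-precision
#' formatted twin, together with the configuration, seed and package
#' version, and a manifest listing every stage exactly once (missing stages
#' are listed with status `missing`, producing a partial archive rather
#' than an error). Re-running a seeded pipeline and re-archiving reproduces
#' the files byte-for-byte; nothing in the archive depends on wall-clock
#' time.
#'
#' @param dir output directory (created if needed).
#' @param stages named list of data frames (or objects with an
#'   `as.data.frame` method); `NULL` entries are recorded as missing.
#' @param config list written as `config.yaml`.
#' @param seed integer recorded alongside the config.
#' @param digits significant digits for the formatted twins.
#' @return invisibly, the manifest data frame.
#' @export
run_report <- function(dir, stages, config = list(), seed = NA_integer_,
                       digits = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = names(stages), file = NA_character_,
                         status = "missing")
  for (i in seq_along(stages)) {
    nm <- names(stages)[i]
    if (is.null(stages[[i]])) next
    df <- as.data.frame(stages[[i]])
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, na = "NA")
    fmt <- df
    fmt[] <- lapply(fmt, function(col)
      if (is.numeric(col)) formatC(col, digits = digits, format = "g") else col)
    utils::write.csv(fmt, file.path(dir, paste0(nm, "_formatted.csv")),
                     row.names = FALSE, na = "NA", quote = FALSE)
    manifest$file[i] <- basename(f)
    manifest$status[i] <- "present"
  }
  yaml::write_yaml(list(seed = seed,
                        package_version =
                          as.character(utils::packageVersion("psen1traj")),
                        config = config),
                   file.path(dir, "config.yaml"))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
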