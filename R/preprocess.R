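#' Expected years to symptom onset
#'
#' EYO is visit age minus the expected age at symptom onset supplied for the
#' participant's family/variant; negative values are pre-symptomatic.
#' Missing AAO gives missing EYO (the row is retained and excluded from EYO
#' models downstream).
#'
#' @param visit_age,expected_aao numeric vectors, years.
#' @return numeric vector of EYO values, years.
#' @examples
#' compute_eyo(40, 48.8) # -8.8
#' @export
compute_eyo <- function(visit_age, expected_aao) {
  if (any(expected_aao <= 0, na.rm = TRUE))
    stop("expected age at onset must be positive", call. = FALSE)
  visit_age - expected_aao
}

#' Fit an intracranial-volume adjustment
#'
#' Residual method: regress the volume on ICV over the estimation sample and
#' keep the slope and grand means, so that
#' `adjusted = volume - slope * (icv - mean_icv)` preserves the sample mean
#' of the raw volume.
#'
#' @param volume,icv numeric vectors, mm^3; pairs with missing values are
#'   dropped from estimation.
#' @return list of class `icv_adjustment` with `slope`, `mean_icv`,
#'   `mean_volume`, `n`.
#' @export
fit_icv_adjustment <- function(volume, icv) {
  if (any(icv <= 0, na.rm = TRUE))
    stop("ICV must be positive", call. = FALSE)
  ok <- is.finite(volume) & is.finite(icv)
  if (sum(ok) < 3L) stop("too few complete volume/ICV pairs", call. = FALSE)
  v <- volume[ok]; i <- icv[ok]
  slope <- if (stats::var(i) > 0) stats::cov(v, i) / stats::var(i) else 0
  structure(list(slope = slope, mean_icv = mean(i), mean_volume = mean(v),
                 n = sum(ok)), class = "icv_adjustment")
}

#' Apply an intracranial-volume adjustment
#'
#' @param volume,icv numeric vectors, mm^3.
#' @param reference an `icv_adjustment` from [fit_icv_adjustment()].
#' @return adjusted volumes, mm^3.
#' @export
adjust_icv <- function(volume, icv, reference) {
  stopifnot(inherits(reference, "icv_adjustment"))
  if (any(icv <= 0, na.rm = TRUE))
    stop("ICV must be positive", call. = FALSE)
  volume - reference$slope * (icv - reference$mean_icv)
}

#' Composite amyloid PET SUVR
#'
#' Unweighted mean of the 14 regional SUVRs (7 cortical regions x 2
#' hemispheres, see [suvr_regions()]). Rows missing any required region get
#' a missing composite; they are counted, not dropped.
#'
#' @param data data frame containing columns `suvr_<region>_<lh|rh>`.
#' @return numeric vector of composite SUVRs.
#' @export
composite_suvr <- function(data) {
  cols <- .suvr_cols()
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("missing regional SUVR column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- as.matrix(data[, cols])
  out <- rowMeans(m)
  out[rowSums(is.na(m)) > 0L] <- NA_real_
  out
}

#' Assemble the model-ready analysis table
#'
#' From a raw visit table this: recomputes/validates EYO; averages left and
#' right hippocampal volumes; applies the ICV residual adjustment (slope
#' estimated on the full analysis sample, or on non-carriers only); adds the
#' composite PiB SUVR; codes categorical covariates with the conventional
#' references (sex F, APOE e4 non-carrier, group NC); and flags complete
#' cases per analysis outcome. No row is dropped: every exclusion reason is
#' recorded in the `"exclusions"` attribute.
#'
#' @param raw data frame, one row per participant-visit (the simulator's
#'   output shape or equivalent real data).
#' @param icv_sample `"all"` (default) or `"nc"`: sample used to estimate
#'   the ICV adjustment slope.
#' @param strict if `TRUE`, instrument-range violations (MMSE outside 0-30,
#'   CDR-SB outside 0-18, non-positive volumes) are errors; default warns.
#' @return data frame with analysis columns `mmse`, `cdr_sb`, `hv`, `pib`,
#'   `csf_ptau181`, `csf_ab42_40`, complete-case flags `cc_<outcome>`, and
#'   attributes `"icv_adjustment"` and `"exclusions"`.
#' @export
assemble <- function(raw, icv_sample = c("all", "nc"), strict = FALSE) {
  icv_sample <- match.arg(icv_sample)
  d <- as.data.frame(raw)
  key <- paste(d$subject_id, d$visit, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (subject, visit) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  exclusions <- data.frame(subject_id = character(0), reason = character(0))
  note <- function(ids, reason) {
    if (length(ids))
      exclusions <<- rbind(exclusions,
                           data.frame(subject_id = unique(ids), reason = reason))
  }

  d$eyo <- compute_eyo(d$visit_age, d$expected_aao)
  note(d$subject_id[is.na(d$eyo)], "missing AAO: excluded from EYO models")

  if (all(c("hv_left", "hv_right") %in% names(d))) {
    hv_bilat <- (d$hv_left + d$hv_right) / 2
  } else if ("hv" %in% names(d)) {
    hv_bilat <- d$hv
  } else hv_bilat <- rep(NA_real_, nrow(d))
  if ("icv" %in% names(d) && any(is.finite(hv_bilat))) {
    est <- if (icv_sample == "nc") d$group == "NC" else rep(TRUE, nrow(d))
    ref <- fit_icv_adjustment(hv_bilat[est], d$icv[est])
    d$hv <- adjust_icv(hv_bilat, d$icv, ref)
    attr(d, "icv_adjustment") <- ref
  } else d$hv <- hv_bilat

  if (all(.suvr_cols() %in% names(d))) {
    d$pib <- composite_suvr(d)
    note(d$subject_id[is.na(d$pib)], "incomplete regional SUVRs: no composite")
  }

  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$apoe4 <- factor(d$apoe4, levels = c("non-carrier", "carrier"))
  if (!is.factor(d$group))
    d$group <- factor(d$group, levels = intersect(c("NC", "CY", "TM"),
                                                  unique(d$group)))
  if ("codon" %in% names(d)) {
    cg <- classify_variant(ifelse(is.na(d$codon), 1L, d$codon))$codon_group
    cg[is.na(d$codon)] <- NA
    d$codon_group <- cg
  }

  rng <- list(mmse = c(0, 30), cdr_sb = c(0, 18))
  for (nm in names(rng)) {
    if (!nm %in% names(d)) next
    bad <- sum(d[[nm]] < rng[[nm]][1] | d[[nm]] > rng[[nm]][2], na.rm = TRUE)
    if (bad > 0) {
      msg <- sprintf("%d %s value(s) outside [%g, %g]", bad, nm,
                     rng[[nm]][1], rng[[nm]][2])
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  if (any(stats::na.omit(d$hv) <= 0)) {
    msg <- "non-positive adjusted hippocampal volume(s)"
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }

  covs <- c("eyo", "visit_age", "sex", "apoe4", "education")
  for (oc in intersect(c("mmse", "cdr_sb", "hv", "pib", "csf_ptau181",
                         "csf_ab42_40"), names(d))) {
    cc <- !is.na(d[[oc]])
    for (cv in intersect(covs, names(d))) cc <- cc & !is.na(d[[cv]])
    d[[paste0("cc_", oc)]] <- cc
    note(d$subject_id[!cc], paste0("incomplete case for ", oc))
  }
  attr(d, "exclusions") <- exclusions
  d
}
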