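#' Default outcome trajectory parameters
#'
#' One parameter block per simulated outcome. Each block describes the group
#' mean trajectory over EYO and the variance components around it:
#' \describe{
#'   \item{level, slope}{non-carrier mean at EYO 0 and a mild per-year drift
#'     (non-carriers are modelled as level + slope * EYO).}
#'   \item{carrier_hinge, carrier_delta}{carriers (CY and TM alike) add a
#'     hinged cubic departure that is 0 before `carrier_hinge`, reaches
#'     `carrier_delta` at EYO 0 and continues linearly afterwards
#'     (natural-spline-style tail, keeping bounded scales in range).}
#'   \item{tm_divergence, tm_delta, ramp_power, ramp_scale}{the TM group adds
#'     a hinged ramp `((eyo - tm_divergence)/ramp_scale)^ramp_power` (0 below
#'     the hinge) scaled by `tm_delta`; by construction TM and CY means are
#'     identical below `tm_divergence`. `ramp_scale` defaults to
#'     `-tm_divergence` so the ramp reaches `tm_delta` at EYO 0.
#'     `tm_divergence = NA` means the groups never differ.}
#'   \item{sigma_family, sigma_subject, sigma_resid}{SDs of the family
#'     intercept, the subject intercept and the visit-level residual.}
#'   \item{range}{instrument range; the mean curve is clamped to it.}
#' }
#'
#' @return named list of parameter blocks (mmse, cdr_sb, hv, pib,
#'   csf_ptau181, csf_ab42_40).
#' @export
default_outcome_params <- function() {
  list(
    mmse = list(level = 29, slope = -0.02, carrier_hinge = -12,
                carrier_delta = -4.5, tm_divergence = -4, tm_delta = -2,
                ramp_power = 1, ramp_scale = NA,
                sigma_family = 0.4, sigma_subject = 0.8, sigma_resid = 1.3,
                range = c(0, 30)),
    cdr_sb = list(level = 0.05, slope = 0.002, carrier_hinge = -10,
                  carrier_delta = 3, tm_divergence = -1, tm_delta = 0.9,
                  ramp_power = 1, ramp_scale = 5,
                  sigma_family = 0.25, sigma_subject = 0.5, sigma_resid = 0.7,
                  range = c(0, 18)),
    hv = list(level = 3600, slope = -6, carrier_hinge = -15,
              carrier_delta = -550, tm_divergence = -11, tm_delta = -250,
              ramp_power = 1, ramp_scale = NA,
              sigma_family = 100, sigma_subject = 220, sigma_resid = 140,
              range = c(500, 6000)),
    pib = list(level = 1.05, slope = 0, carrier_hinge = -20,
               carrier_delta = 1.5, tm_divergence = NA, tm_delta = 0,
               ramp_power = 1, ramp_scale = NA,
               sigma_family = 0.08, sigma_subject = 0.25, sigma_resid = 0.12,
               range = c(0.6, 6)),
    csf_ptau181 = list(level = 20, slope = 0.05, carrier_hinge = -22,
                       carrier_delta = 60, tm_divergence = 3, tm_delta = 15,
                       ramp_power = 1, ramp_scale = 5,
                       sigma_family = 3, sigma_subject = 8, sigma_resid = 6,
                       range = c(1, 300)),
    csf_ab42_40 = list(level = 0.110, slope = 0, carrier_hinge = -24,
                       carrier_delta = -0.035, tm_divergence = NA, tm_delta = 0,
                       ramp_power = 1, ramp_scale = NA,
                       sigma_family = 0.004, sigma_subject = 0.010,
                       sigma_resid = 0.006, range = c(0.01, 0.2))
  )
}

#' Simulation configuration
#'
#' Bundles and validates everything [simulate_cohort()] needs. Defaults
#' reproduce the structure of the observational ADAD cohort the package
#' targets: 202 non-carriers, 65 cytoplasmic-domain and 135 transmembrane-
#' domain PSEN1 variant carriers, family clustering, baseline EYO uniform on
#' -25..+10 years and longitudinal follow-up averaging about 3 years.
#'
#' @param n_nc,n_cy,n_tm subjects per group (all must be >= 1).
#' @param family_size_probs named numeric vector: probability of a family
#'   contributing 1, 2, ... enrolled members.
#' @param eyo_range baseline EYO support, years (min < max).
#' @param visit_probs probability of a subject contributing 1, 2, ... visits.
#' @param visit_interval_mean,visit_interval_sd between-visit gap, years
#'   (mean must be > 0; draws are floored at 0.25 y).
#' @param aao_mean,aao_sd expected age at symptom onset, drawn per family.
#' @param sex_p_female,apoe4_p,education_mean,education_sd,education_range
#'   covariate generators (education is truncated normal).
#' @param icv_mean,icv_sd,icv_slope,hv_asym_sd intracranial volume draw, the
#'   slope coupling observed hippocampal volume to ICV, and the SD of the
#'   per-subject left/right asymmetry (the left/right mean is exact).
#' @param suvr_region_sd measurement SD of each regional SUVR around the
#'   latent composite.
#' @param outcomes outcome parameter blocks, see [default_outcome_params()];
#'   entries you pass are merged over the defaults.
#' @param covariate_effects numeric vector `c(sex, apoe4, education, age)`
#'   added to every outcome's mean (on each outcome's own scale); default all
#'   zero so the generating group curves are the marginal group means.
#' @param seed integer seed; the stream is split by purpose (structure,
#'   covariates, noise) so changing the visit schedule does not perturb
#'   covariate draws.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_nc = 202L, n_cy = 65L, n_tm = 135L,
                       family_size_probs = c(`1` = 0.45, `2` = 0.30,
                                             `3` = 0.15, `4` = 0.10),
                       eyo_range = c(-25, 10),
                       visit_probs = c(`1` = 0.25, `2` = 0.20, `3` = 0.20,
                                       `4` = 0.15, `5` = 0.10, `6` = 0.10),
                       visit_interval_mean = 1.4, visit_interval_sd = 0.4,
                       aao_mean = 46.6, aao_sd = 7.0,
                       sex_p_female = 0.58, apoe4_p = 0.30,
                       education_mean = 15.0, education_sd = 2.8,
                       education_range = c(6, 22),
                       icv_mean = 1.45e6, icv_sd = 1.3e5, icv_slope = 0.0015,
                       hv_asym_sd = 25, suvr_region_sd = 0.05,
                       outcomes = list(), covariate_effects = c(sex = 0,
                         apoe4 = 0, education = 0, age = 0),
                       seed = 1L) {
  counts <- c(NC = n_nc, CY = n_cy, TM = n_tm)
  if (any(counts < 1L))
    stop("all three groups must have at least one subject", call. = FALSE)
  if (visit_interval_mean <= 0)
    stop("visit interval mean must be positive", call. = FALSE)
  if (eyo_range[1] >= eyo_range[2])
    stop("eyo_range must satisfy min < max", call. = FALSE)
  base <- default_outcome_params()
  for (nm in names(outcomes)) {
    if (is.null(base[[nm]])) base[[nm]] <- outcomes[[nm]]
    else base[[nm]][names(outcomes[[nm]])] <- outcomes[[nm]]
  }
  for (nm in names(base)) {
    p <- base[[nm]]
    if (any(c(p$sigma_family, p$sigma_subject, p$sigma_resid) < 0))
      stop("negative SD in outcome block '", nm, "'", call. = FALSE)
    if (is.na(p$ramp_scale) || is.null(p$ramp_scale)) {
      base[[nm]]$ramp_scale <- if (!is.na(p$tm_divergence) && p$tm_divergence < 0)
        -p$tm_divergence else 5
    }
  }
  structure(list(counts = counts, family_size_probs = family_size_probs,
                 eyo_range = eyo_range, visit_probs = visit_probs,
                 visit_interval_mean = visit_interval_mean,
                 visit_interval_sd = visit_interval_sd,
                 aao_mean = aao_mean, aao_sd = aao_sd,
                 sex_p_female = sex_p_female, apoe4_p = apoe4_p,
                 education_mean = education_mean, education_sd = education_sd,
                 education_range = education_range,
                 icv_mean = icv_mean, icv_sd = icv_sd, icv_slope = icv_slope,
                 hv_asym_sd = hv_asym_sd, suvr_region_sd = suvr_region_sd,
                 outcomes = base, covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# hinged cubic departure: 0 below h, ((e-h)/-h)^3 on [h, 0], linear tail
# beyond 0 with the cubic's slope at 0 (natural continuation)
.hinge_cubic <- function(e, h) {
  stopifnot(h < 0)
  u <- pmin(e, 0)
  v <- ifelse(u <= h, 0, ((u - h) / (-h))^3)
  v + ifelse(e > 0, 3 * e / (-h), 0)
}

.hinge_ramp <- function(e, d, scale, power = 1) {
  pmax((e - d) / scale, 0)^power
}

# group mean trajectory for one outcome block, clamped to instrument range
.mean_curve <- function(p, group, eyo) {
  mu <- p$level + p$slope * eyo
  if (group %in% c("CY", "TM"))
    mu <- mu + p$carrier_delta * .hinge_cubic(eyo, p$carrier_hinge)
  if (group == "TM" && !is.na(p$tm_divergence) && p$tm_delta != 0)
    mu <- mu + p$tm_delta * .hinge_ramp(eyo, p$tm_divergence, p$ramp_scale,
                                        p$ramp_power)
  pmin(pmax(mu, p$range[1]), p$range[2])
}

#' PiB composite regions
#'
#' The seven cortical regions entering the composite amyloid PET SUVR, each
#' measured in both hemispheres.
#' @return character vector of region stems.
#' @export
suvr_regions <- function() {
  c("lat_orbitofrontal", "med_orbitofrontal", "rostral_middle_frontal",
    "superior_frontal", "superior_temporal", "middle_temporal", "precuneus")
}

.suvr_cols <- function() {
  as.vector(t(outer(suvr_regions(), c("lh", "rh"),
                    function(r, h) paste0("suvr_", r, "_", h))))
}

# derive sub-seeds below 2^31 from one user seed
.split_seed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

# sample() that never falls into the length-1 "sample from 1:n" trap
.sample_from <- function(vals, n, prob = NULL)
  vals[sample.int(length(vals), n, replace = TRUE, prob = prob)]

#' Simulate an ADAD-like cohort with known ground truth
#'
#' Generates one row per participant-visit with family clustering, group
#' mean trajectories over EYO, family/subject/visit variance components and
#' raw measurement columns (left/right hippocampal volume with ICV coupling,
#' 14 regional SUVRs around a latent composite, CSF analytes) shaped like
#' the tables the preprocessing step expects. TM and CY mean curves are
#' identical below each outcome's true divergence EYO by construction, so
#' the returned ground truth is a valid oracle for divergence recovery.
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (data frame, one row per visit) and `truth`
#'   (class `cohort_truth`: generating parameters, a `curve(outcome, group,
#'   eyo)` evaluator and the per-outcome true divergence EYO).
#' @examples
#' sim <- simulate_cohort(sim_config(n_nc = 5, n_cy = 5, n_tm = 5, seed = 7))
#' table(sim$cohort$group[!duplicated(sim$cohort$subject_id)])
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  counts <- cfg$counts

  ## --- structure stream: families, AAO, EYO, visit schedule, codons ----
  set.seed(.split_seed(cfg$seed, 1L))
  subj <- do.call(rbind, lapply(names(counts), function(g) {
    n <- counts[[g]]
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, .sample_from(as.integer(names(cfg$family_size_probs)),
                                     1L, prob = cfg$family_size_probs))
    fam <- rep(seq_along(sizes), sizes)[seq_len(n)]
    data.frame(group = g, fam_local = fam)
  }))
  subj$family_id <- sprintf("F%s%03d", substr(subj$group, 1, 1), subj$fam_local)
  subj$subject_id <- sprintf("S%04d", seq_len(nrow(subj)))
  fams <- unique(subj[, c("group", "family_id")])
  fams$aao <- pmin(pmax(stats::rnorm(nrow(fams), cfg$aao_mean, cfg$aao_sd), 30), 70)
  subj$expected_aao <- fams$aao[match(subj$family_id, fams$family_id)]
  subj$baseline_eyo <- stats::runif(nrow(subj), cfg$eyo_range[1], cfg$eyo_range[2])
  subj$n_visits <- .sample_from(as.integer(names(cfg$visit_probs)),
                                nrow(subj), prob = cfg$visit_probs)
  intervals <- lapply(subj$n_visits, function(k)
    if (k <= 1L) numeric(0)
    else pmax(stats::rnorm(k - 1L, cfg$visit_interval_mean,
                           cfg$visit_interval_sd), 0.25))
  # carrier codons drawn uniformly over the matching domain intervals
  dom <- psen1_domains()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  draw_codon <- function(lbl) {
    rows <- dom[dom$label == lbl, , drop = FALSE]
    pool <- unlist(mapply(seq, rows$start_codon, rows$end_codon,
                          SIMPLIFY = FALSE))
    .sample_from(pool, 1L)
  }
  subj$codon <- NA_integer_
  carrier <- subj$group %in% c("CY", "TM")
  subj$codon[carrier] <- vapply(subj$group[carrier], draw_codon, 1L)
  subj$variant <- NA_character_
  subj$variant[carrier] <- paste0(sample(aa, sum(carrier), TRUE),
                                  subj$codon[carrier],
                                  sample(aa, sum(carrier), TRUE))

  ## --- covariate stream: depends only on subject count ------------------
  set.seed(.split_seed(cfg$seed, 2L))
  ns <- nrow(subj)
  subj$sex <- ifelse(stats::runif(ns) < cfg$sex_p_female, "F", "M")
  subj$apoe4 <- ifelse(stats::runif(ns) < cfg$apoe4_p, "carrier", "non-carrier")
  subj$education <- pmin(pmax(stats::rnorm(ns, cfg$education_mean,
                                           cfg$education_sd),
                              cfg$education_range[1]), cfg$education_range[2])
  subj$icv <- stats::rnorm(ns, cfg$icv_mean, cfg$icv_sd)
  subj$hv_asym <- stats::rnorm(ns, 0, cfg$hv_asym_sd)

  ## --- visit expansion ---------------------------------------------------
  idx <- rep(seq_len(ns), subj$n_visits)
  visit <- unlist(lapply(subj$n_visits, seq_len))
  offset <- unlist(mapply(function(k, iv) c(0, cumsum(iv)),
                          subj$n_visits, intervals, SIMPLIFY = FALSE))
  cohort <- subj[idx, c("subject_id", "family_id", "group", "variant", "codon",
                        "expected_aao", "sex", "apoe4", "education", "icv")]
  cohort$visit <- visit
  cohort$eyo <- subj$baseline_eyo[idx] + offset
  cohort$visit_age <- cohort$expected_aao + cohort$eyo
  rownames(cohort) <- NULL
  nv <- nrow(cohort)

  ## --- noise stream: random effects and residuals -----------------------
  set.seed(.split_seed(cfg$seed, 3L))
  ce <- cfg$covariate_effects
  cov_shift <- ce[["sex"]] * (cohort$sex == "F") +
    ce[["apoe4"]] * (cohort$apoe4 == "carrier") +
    ce[["education"]] * (cohort$education - cfg$education_mean) +
    ce[["age"]] * (cohort$visit_age - mean(cohort$visit_age))
  fam_ids <- unique(cohort$family_id)
  latent <- list()
  for (nm in names(cfg$outcomes)) {
    p <- cfg$outcomes[[nm]]
    u_f <- stats::rnorm(length(fam_ids), 0, p$sigma_family)
    b_s <- stats::rnorm(ns, 0, p$sigma_subject)
    e_v <- stats::rnorm(nv, 0, p$sigma_resid)
    mu <- numeric(nv)
    for (g in c("NC", "CY", "TM")) {
      rows <- cohort$group == g
      mu[rows] <- .mean_curve(p, g, cohort$eyo[rows])
    }
    latent[[nm]] <- mu + cov_shift +
      u_f[match(cohort$family_id, fam_ids)] + b_s[idx] + e_v
  }
  cohort$mmse <- latent$mmse
  cohort$cdr_sb <- latent$cdr_sb
  hv_total <- latent$hv + cfg$icv_slope * (cohort$icv - cfg$icv_mean)
  asym <- subj$hv_asym[idx]
  cohort$hv_left <- hv_total + asym
  cohort$hv_right <- hv_total - asym
  reg_off <- stats::setNames(seq(-0.06, 0.06, length.out = 14),
                             .suvr_cols())
  reg_off <- reg_off - mean(reg_off)
  for (cl in .suvr_cols())
    cohort[[cl]] <- latent$pib + reg_off[[cl]] +
      stats::rnorm(nv, 0, cfg$suvr_region_sd)
  cohort$csf_ptau181 <- latent$csf_ptau181
  cohort$csf_ab42_40 <- latent$csf_ab42_40
  cohort$group <- factor(cohort$group, levels = c("NC", "CY", "TM"))

  truth <- structure(list(
    outcomes = cfg$outcomes,
    eyo_range = cfg$eyo_range,
    divergence_eyo = vapply(cfg$outcomes, function(p)
      if (is.na(p$tm_divergence) || p$tm_delta == 0) NA_real_
      else p$tm_divergence, 1.0),
    curve = function(outcome, group, eyo) {
      p <- cfg$outcomes[[outcome]]
      if (is.null(p)) stop("unknown outcome '", outcome, "'", call. = FALSE)
      .mean_curve(p, match.arg(group, c("NC", "CY", "TM")), eyo)
    },
    seed = cfg$seed), class = "cohort_truth")

  list(cohort = cohort, truth = truth)
}

#' True TM - CY mean difference on an EYO grid
#'
#' Evaluates the generating mean curves directly; zero below the true
#' divergence EYO by construction. Used as the oracle in divergence
#' recovery tests.
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @param outcome outcome name.
#' @param eyo_grid numeric grid inside the simulated EYO range.
#' @return numeric vector of TM minus CY mean differences.
#' @export
truth_difference_curve <- function(truth, outcome, eyo_grid) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (!outcome %in% names(truth$outcomes))
    stop("unknown outcome '", outcome, "'; available: ",
         paste(names(truth$outcomes), collapse = ", "), call. = FALSE)
  if (any(eyo_grid < truth$eyo_range[1] - 1e-9) ||
      any(eyo_grid > truth$eyo_range[2] + 1e-9))
    stop("grid outside the simulated EYO range", call. = FALSE)
  truth$curve(outcome, "TM", eyo_grid) - truth$curve(outcome, "CY", eyo_grid)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat("Ground truth for simulated ADAD cohort\n")
  cat("  outcomes:", paste(names(x$outcomes), collapse = ", "), "\n")
  d <- x$divergence_eyo
  cat("  true TM/CY divergence EYO:\n")
  for (nm in names(d))
    cat(sprintf("    %-12s %s\n", nm,
                if (is.na(d[[nm]])) "none" else sprintf("%.1f y", d[[nm]])))
  invisible(x)
}

#' Write a simulated cohort and its ground truth to disk
#'
#' The cohort goes out as comma-separated text (header row, `NA` for
#' missing); the ground truth as a YAML sidecar holding the generating
#' parameters and true divergence points.
#'
#' @param sim result of [simulate_cohort()].
#' @param prefix output path prefix; writes `<prefix>_cohort.csv` and
#'   `<prefix>_truth.yaml`.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(sim, prefix) {
  paths <- c(cohort = paste0(prefix, "_cohort.csv"),
             truth = paste0(prefix, "_truth.yaml"))
  utils::write.csv(sim$cohort, paths[["cohort"]], row.names = FALSE, na = "NA")
  truth <- sim$truth
  yaml::write_yaml(list(seed = truth$seed,
                        eyo_range = truth$eyo_range,
                        divergence_eyo = as.list(truth$divergence_eyo),
                        outcomes = truth$outcomes), paths[["truth"]])
  invisible(paths)
}

#' Read a cohort table written by [write_cohort()] or the CLI
#'
#' @param path CSV file with one row per participant-visit.
#' @return data frame with `group` restored as a factor.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  if ("group" %in% names(x))
    x$group <- factor(x$group, levels = intersect(c("NC", "CY", "TM",
                                                    "unclassified"),
                                                  unique(x$group)))
  x
}
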