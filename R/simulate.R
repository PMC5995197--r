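#' Phenotype labels used throughout the package
#'
#' Healthy controls (HC), clinically isolated syndrome (CIS),
#' relapsing-remitting (RRMS), secondary-progressive (SPMS) and
#' primary-progressive (PPMS) multiple sclerosis.
#' @export
EBM_PHENOTYPES <- c("HC", "CIS", "RRMS", "SPMS", "PPMS")

#' Candidate region names (Desikan-Killiany-Tourville convention,
#' left/right already averaged)
#'
#' @param l number of regions requested
#' @return character vector of length \code{l}
#' @export
dkt_region_names <- function(l) {
  pool <- c(
    "thalamus", "precuneus", "posterior_cingulate", "middle_cingulate",
    "brainstem", "putamen", "pallidum", "caudate", "accumbens", "insula",
    "precentral", "postcentral", "cuneus", "superior_temporal",
    "middle_temporal", "inferior_temporal", "fusiform", "parahippocampal",
    "hippocampus", "amygdala", "superior_frontal", "middle_frontal",
    "inferior_frontal", "frontal_operculum", "transverse_temporal",
    "lingual", "pericalcarine", "supramarginal", "angular", "entorhinal")
  if (l <= length(pool)) pool[seq_len(l)]
  else c(pool, sprintf("region_%02d", seq_len(l - length(pool))))
}

#' Build and validate a simulation configuration
#'
#' Defines the generative model for a synthetic multiple sclerosis imaging
#' cohort: a planted sequence in which regions become atrophic, a latent
#' integer stage per subject and visit, two-Gaussian region volumes in z
#' units mapped to millilitres with additive nuisance-covariate effects,
#' monotone longitudinal stage progression, and lesion load / EDSS coupled
#' linearly to the latent stage.
#'
#' @param n_per_phenotype named integer vector of subject counts per
#'   phenotype (names from \code{EBM_PHENOTYPES}).
#' @param n_regions number of regions \code{l} (>= 2).
#' @param true_sequence \code{"random"} or an integer permutation of
#'   \code{1:n_regions}; position 1 is the first region to become atrophic.
#' @param separation difference in z units between the normal mean (0) and
#'   the abnormal mean (\code{-separation}); scalar or length-l vector.
#' @param sigma_normal,sigma_abnormal spreads of the two components (z units).
#' @param baseline_stage_prob named per-phenotype success probability; a
#'   subject's baseline stage is Binomial(\code{n_regions}, p). Healthy
#'   controls default to 0 (always stage 0).
#' @param progression_rate named per-phenotype expected stages gained per
#'   year; visit-to-visit increments are Poisson.
#' @param visits_per_subject number of visits (>= 1).
#' @param visit_interval_years spacing between visits in years.
#' @param covariate_effects list with elements \code{tiv} (ml volume per ml
#'   of intracranial volume), \code{age} (ml per year), \code{sex} (ml offset
#'   for females), \code{field} (ml offset at 3T), \code{protocol} (numeric
#'   vector of ml offsets, one per protocol beyond the first).
#' @param lesion_coupling,edss_coupling lists \code{(intercept, slope, sd)}
#'   giving the affine dependence of T2 lesion load (ml) and EDSS on the
#'   latent stage plus Gaussian noise.
#' @param region_mean_ml,region_scale_ml location and z-to-ml scale of raw
#'   region volumes; scalars or length-l vectors.
#' @param seed RNG seed used by \code{simulate_cohort}.
#' @return an object of class \code{ebm_sim_config}
#' @export
sim_config <- function(n_per_phenotype = c(HC = 100, CIS = 80, RRMS = 200,
                                           SPMS = 60, PPMS = 60),
                       n_regions = 10,
                       true_sequence = "random",
                       separation = 2,
                       sigma_normal = 1,
                       sigma_abnormal = 1,
                       baseline_stage_prob = c(HC = 0, CIS = 0.3, RRMS = 0.5,
                                               SPMS = 0.65, PPMS = 0.5),
                       progression_rate = c(HC = 0, CIS = 0.2, RRMS = 0.4,
                                            SPMS = 1.0, PPMS = 0.5),
                       visits_per_subject = 2,
                       visit_interval_years = 1,
                       covariate_effects = list(tiv = 1 / 150, age = -0.05,
                                                sex = 1.0, field = 0.5,
                                                protocol = c(0.8)),
                       lesion_coupling = list(intercept = 2, slope = 1, sd = 2),
                       edss_coupling = list(intercept = 1, slope = 0.3, sd = 1),
                       region_mean_ml = NULL,
                       region_scale_ml = 1,
                       seed = 1L) {
  l <- as.integer(n_regions)
  if (is.na(l) || l < 2) stop("n_regions must be an integer >= 2", call. = FALSE)
  if (is.null(names(n_per_phenotype)) ||
      !all(names(n_per_phenotype) %in% EBM_PHENOTYPES))
    stop("n_per_phenotype must be named with phenotypes from EBM_PHENOTYPES",
         call. = FALSE)
  if (any(n_per_phenotype < 0)) stop("subject counts must be >= 0", call. = FALSE)
  if (identical(true_sequence, "random")) {
    true_sequence <- NULL  # drawn at simulation time from the seed
  } else {
    true_sequence <- as.integer(true_sequence)
    if (length(true_sequence) != l || !setequal(true_sequence, seq_len(l)))
      stop("true_sequence must be a permutation of 1:n_regions", call. = FALSE)
  }
  separation <- rep_len(separation, l)
  if (any(separation < 0)) stop("separation must be >= 0", call. = FALSE)
  if (sigma_normal <= 0 || sigma_abnormal <= 0)
    stop("sigmas must be > 0", call. = FALSE)
  if (visits_per_subject < 1) stop("visits_per_subject must be >= 1", call. = FALSE)
  if (visit_interval_years <= 0)
    stop("visit_interval_years must be > 0", call. = FALSE)
  for (ph in names(n_per_phenotype)) {
    if (is.na(baseline_stage_prob[ph]) || baseline_stage_prob[ph] < 0 ||
        baseline_stage_prob[ph] > 1)
      stop("baseline_stage_prob must contain a probability for ", ph,
           call. = FALSE)
    if (is.na(progression_rate[ph]) || progression_rate[ph] < 0)
      stop("progression_rate must contain a non-negative rate for ", ph,
           call. = FALSE)
  }
  if (is.null(region_mean_ml))
    region_mean_ml <- seq(8, 18, length.out = l)
  cfg <- list(n_per_phenotype = n_per_phenotype, n_regions = l,
              true_sequence = true_sequence,
              separation = separation, sigma_normal = sigma_normal,
              sigma_abnormal = sigma_abnormal,
              baseline_stage_prob = baseline_stage_prob,
              progression_rate = progression_rate,
              visits_per_subject = as.integer(visits_per_subject),
              visit_interval_years = visit_interval_years,
              covariate_effects = covariate_effects,
              lesion_coupling = lesion_coupling,
              edss_coupling = edss_coupling,
              region_mean_ml = rep_len(region_mean_ml, l),
              region_scale_ml = rep_len(region_scale_ml, l),
              seed = as.integer(seed))
  class(cfg) <- "ebm_sim_config"
  cfg
}

#' Advance latent stages over follow-up visits
#'
#' Stages follow a monotone non-decreasing jump process: between consecutive
#' visits each subject gains a Poisson number of stages with mean
#' \code{rate * interval}, capped at \code{l}.
#'
#' @param baseline_stage integer vector of baseline stages (one per subject)
#' @param rate per-subject expected stages gained per year
#' @param n_visits total number of visits (including baseline)
#' @param interval_years years between consecutive visits
#' @param l maximum stage (number of regions)
#' @return integer matrix, subjects x visits, non-decreasing along rows
#' @export
advance_stages <- function(baseline_stage, rate, n_visits, interval_years, l) {
  n <- length(baseline_stage)
  rate <- rep_len(rate, n)
  out <- matrix(0L, nrow = n, ncol = n_visits)
  out[, 1] <- as.integer(pmin(baseline_stage, l))
  if (n_visits >= 2) {
    for (v in 2:n_visits) {
      inc <- rpois(n, lambda = rate * interval_years)
      out[, v] <- as.integer(pmin(out[, v - 1] + inc, l))
    }
  }
  out
}

#' Simulate a cohort with planted atrophy sequence and stages
#'
#' Generates one row per scan. For a scan at latent stage \code{k}, the
#' regions at positions \code{1..k} of the planted sequence are drawn from
#' the abnormal Gaussian \code{N(-separation, sigma_abnormal^2)} and the
#' remaining regions from \code{N(0, sigma_normal^2)} (z units); z values are
#' mapped to millilitre volumes and nuisance-covariate effects (intracranial
#' volume, age at entry, sex, field strength, protocol) are added. Lesion
#' load and EDSS are affine in the latent stage plus noise; EDSS is rounded
#' to the clinical half-point grid in [0, 10] and lesion load truncated at 0.
#' Clinical scores are only generated for patients.
#'
#' @param config an \code{ebm_sim_config}
#' @return list with elements \code{cohort} (data.frame, one row per scan;
#'   region volumes in columns prefixed \code{vol_}) and \code{truth}
#'   (list: \code{true_sequence} as region indices and names,
#'   \code{stages} data.frame of latent stages per scan, and the planted
#'   coupling coefficients)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ebm_sim_config"))
  set.seed(config$seed)
  l <- config$n_regions
  regions <- dkt_region_names(l)
  seqn <- config$true_sequence
  if (is.null(seqn)) seqn <- sample(l)
  # position_of[r] = rank of region r in the planted sequence
  position_of <- match(seq_len(l), seqn)

  counts <- config$n_per_phenotype[config$n_per_phenotype > 0]
  phenotype <- rep(names(counts), counts)
  n <- length(phenotype)
  if (n == 0) stop("no subjects requested", call. = FALSE)
  subject_id <- sprintf("S%04d", seq_len(n))

  age <- round(rnorm(n, mean = 40, sd = 10), 1)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  tiv <- rnorm(n, mean = 1500, sd = 150)
  field <- sample(c("1.5T", "3T"), n, replace = TRUE)
  n_protocols <- length(config$covariate_effects$protocol) + 1
  protocol <- sample(sprintf("P%d", seq_len(n_protocols)), n, replace = TRUE)

  base_stage <- integer(n)
  for (ph in names(counts)) {
    idx <- phenotype == ph
    base_stage[idx] <- rbinom(sum(idx), l, config$baseline_stage_prob[ph])
  }
  rates <- unname(config$progression_rate[phenotype])
  stages <- advance_stages(base_stage, rates, config$visits_per_subject,
                           config$visit_interval_years, l)

  nv <- config$visits_per_subject
  visit_time <- rep((seq_len(nv) - 1) * config$visit_interval_years, times = n)
  row_subject <- rep(seq_len(n), each = nv)
  stage_vec <- as.integer(t(stages))
  J <- n * nv

  # z-scale volumes: abnormal component for positions <= stage
  z <- matrix(rnorm(J * l, mean = 0, sd = config$sigma_normal), nrow = J)
  abn <- outer(stage_vec, position_of, ">=")
  n_ab <- sum(abn)
  if (n_ab > 0) {
    sep_m <- matrix(rep(config$separation, each = J), nrow = J)
    z[abn] <- rnorm(n_ab, mean = -sep_m[abn], sd = config$sigma_abnormal)
  }

  ce <- config$covariate_effects
  cov_shift <- ce$tiv * (tiv[row_subject] - 1500) +
    ce$age * (age[row_subject] - 40) +
    ce$sex * (sex[row_subject] == "F") +
    ce$field * (field[row_subject] == "3T")
  proto_idx <- match(protocol[row_subject], sprintf("P%d", seq_len(n_protocols)))
  proto_off <- c(0, ce$protocol)[proto_idx]
  cov_shift <- cov_shift + proto_off

  vols <- sweep(z, 2, config$region_scale_ml, "*")
  vols <- sweep(vols, 2, config$region_mean_ml, "+")
  vols <- vols + cov_shift
  vols <- pmax(vols, 0.5)  # volumes are physical: truncate rare low tails
  colnames(vols) <- paste0("vol_", regions)

  is_patient <- phenotype[row_subject] != "HC"
  lc <- config$lesion_coupling
  ec <- config$edss_coupling
  lesion <- ifelse(is_patient,
                   pmax(0, lc$intercept + lc$slope * stage_vec +
                          rnorm(J, sd = lc$sd)), NA_real_)
  edss_raw <- ec$intercept + ec$slope * stage_vec + rnorm(J, sd = ec$sd)
  edss <- ifelse(is_patient, pmin(10, pmax(0, round(edss_raw * 2) / 2)),
                 NA_real_)
  dur_base <- c(HC = NA, CIS = 0.4, RRMS = 7, SPMS = 15, PPMS = 6.8)
  duration <- dur_base[phenotype[row_subject]] + visit_time
  duration <- ifelse(is_patient, pmax(0, duration), NA_real_)

  cohort <- data.frame(
    subject_id = subject_id[row_subject],
    visit_time_years = visit_time,
    phenotype = phenotype[row_subject],
    age_at_entry = age[row_subject],
    sex = sex[row_subject],
    total_icv_ml = tiv[row_subject],
    field_strength = field[row_subject],
    protocol_id = protocol[row_subject],
    lesion_load_ml = lesion,
    edss = edss,
    disease_duration_years = unname(duration),
    stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(vols))

  truth <- list(
    true_sequence = seqn,
    true_sequence_regions = regions[seqn],
    stages = data.frame(subject_id = subject_id[row_subject],
                        visit_time_years = visit_time,
                        true_stage = stage_vec,
                        stringsAsFactors = FALSE),
    lesion_coupling = lc,
    edss_coupling = ec,
    covariate_effects = ce)
  list(cohort = cohort, truth = truth)
}
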