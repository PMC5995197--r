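#' Mixed-effects association between model stage and a predictor
#'
#' Fits a linear mixed model with the model stage as the outcome, the
#' requested predictor as fixed effect, and repeated measures handled by a
#' subject random intercept plus (by default) a subject random slope on the
#' time axis. Reports the raw and standardized fixed-effect coefficient
#' with its Wald standard error and p-value. A singular random-slope fit
#' falls back to a random intercept only, with a message.
#'
#' @param stages a data.frame with columns \code{stage}, \code{subject_id},
#'   plus the predictor and time columns (e.g. the output of
#'   \code{assign_stages} after merging clinical columns)
#' @param predictor name of the fixed-effect column of interest
#' @param time name of the time axis for the random slope (default
#'   \code{"visit_time_years"}); set \code{random_slope = FALSE} for a
#'   random intercept only
#' @param random_slope include a subject random slope on \code{time}
#' @param extra_terms optional character vector of additional fixed-effect
#'   terms (e.g. an interaction \code{"treated:visit_time_years"})
#' @param REML use REML (default FALSE: maximum likelihood)
#' @return data.frame of class \code{ebm_association} with one row per
#'   fixed-effect term: estimate, SE, standardized estimate, z, p; the
#'   fitted \code{lme4} model in attribute \code{"model"}
#' @export
mixed_effect_association <- function(stages, predictor,
                                     time = "visit_time_years",
                                     random_slope = TRUE,
                                     extra_terms = NULL, REML = FALSE) {
  need <- c("stage", "subject_id", predictor)
  miss <- setdiff(need, names(stages))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- stages[complete.cases(stages[, unique(c(need, time))]), , drop = FALSE]
  if (is.numeric(d[[predictor]]) && var(d[[predictor]]) == 0)
    stop("zero-variance predictor: ", predictor, call. = FALSE)
  fixed <- paste(c(predictor, extra_terms), collapse = " + ")
  fit <- fit_mixed_with_fallback(paste("stage ~", fixed), d,
                                 time = time, random_slope = random_slope,
                                 REML = REML)
  summarize_fixed_effects(fit, d, outcome = "stage")
}

# fit with the richest identifiable random-effects structure:
# subject random slope on time -> subject random intercept -> plain OLS.
# Downgrades happen on singular fits or on designs where the structure is
# unidentifiable (e.g. single-visit data), with a message.
fit_mixed_with_fallback <- function(fixed_formula, data, time,
                                    random_slope = TRUE, REML = FALSE) {
  try_lmer <- function(re) {
    fml <- as.formula(paste(fixed_formula, "+", re))
    tryCatch(suppressWarnings(lme4::lmer(fml, data = data, REML = REML)),
             error = function(e) NULL)
  }
  if (random_slope) {
    fit <- try_lmer(paste0("(1 + ", time, " | subject_id)"))
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-4)) return(fit)
    message("random-slope fit singular or unidentifiable; ",
            "falling back to random intercept only")
  }
  fit <- try_lmer("(1 | subject_id)")
  if (!is.null(fit)) return(fit)
  message("random-intercept fit unidentifiable (single scan per subject?); ",
          "falling back to ordinary least squares")
  lm(as.formula(fixed_formula), data = data)
}

summarize_fixed_effects <- function(fit, data, outcome) {
  cf <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  sd_out <- sd(data[[outcome]])
  std <- vapply(names(cf), function(term) {
    if (term %in% names(data) && is.numeric(data[[term]]))
      cf[[term]] * sd(data[[term]]) / sd_out
    else NA_real_
  }, numeric(1))
  out <- data.frame(term = names(cf), estimate = unname(cf),
                    se = unname(se), std_estimate = unname(std),
                    z = unname(z), p = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- fit
  class(out) <- c("ebm_association", class(out))
  out
}

#' Annualized EDSS change regressed on annualized stage change
#'
#' Per subject with at least two visits spanning a positive interval,
#' computes the annualized change (last minus first, divided by elapsed
#' years) of both the EDSS and the model stage, then fits an ordinary
#' least-squares regression of annualized EDSS change on annualized stage
#' change and disease duration at study entry. A rank-based (Spearman)
#' confirmation of the stage-change association is attached, reflecting the
#' ordinal character of both scales.
#'
#' @param stages data.frame with columns \code{subject_id},
#'   \code{visit_time_years}, \code{stage}, \code{edss},
#'   \code{disease_duration_years}
#' @return data.frame of class \code{ebm_association} (one row per
#'   coefficient); attributes: \code{"model"} (the \code{lm} fit),
#'   \code{"per_subject"} (the annualized table), \code{"n_excluded"}
#'   (single-visit subjects dropped), \code{"spearman"} (rank-based
#'   confirmation)
#' @export
annualized_change_regression <- function(stages) {
  need <- c("subject_id", "visit_time_years", "stage", "edss",
            "disease_duration_years")
  miss <- setdiff(need, names(stages))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- stages[complete.cases(stages[, need]), need]
  per <- lapply(split(d, d$subject_id), function(s) {
    s <- s[order(s$visit_time_years), ]
    span <- s$visit_time_years[nrow(s)] - s$visit_time_years[1]
    if (nrow(s) < 2 || span <= 0) return(NULL)
    data.frame(subject_id = s$subject_id[1],
               annualized_edss_change = (s$edss[nrow(s)] - s$edss[1]) / span,
               annualized_stage_change = (s$stage[nrow(s)] - s$stage[1]) / span,
               duration_at_entry = s$disease_duration_years[1],
               stringsAsFactors = FALSE)
  })
  n_excluded <- sum(vapply(per, is.null, logical(1)))
  tab <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) < 3)
    stop("need at least 3 subjects with >= 2 visits", call. = FALSE)
  if (n_excluded > 0)
    message(n_excluded, " single-visit subject(s) excluded")
  if (var(tab$annualized_stage_change) < 1e-10)
    warning("annualized stage change is near-constant; regression is ",
            "ill-conditioned", call. = FALSE)
  fit <- lm(annualized_edss_change ~ annualized_stage_change +
              duration_at_entry, data = tab)
  sm <- summary(fit)$coefficients
  sd_out <- sd(tab$annualized_edss_change)
  std <- vapply(rownames(sm), function(term) {
    if (term %in% names(tab)) sm[term, 1] * sd(tab[[term]]) / sd_out
    else NA_real_
  }, numeric(1))
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    std_estimate = std, z = sm[, 3], p = sm[, 4],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "model") <- fit
  attr(out, "per_subject") <- tab
  attr(out, "n_excluded") <- n_excluded
  attr(out, "spearman") <- suppressWarnings(
    cor(tab$annualized_edss_change, tab$annualized_stage_change,
        method = "spearman"))
  class(out) <- c("ebm_association", class(out))
  out
}

#' Per-group stage intercepts and slopes over time
#'
#' Fits a mixed model of stage on time crossed with a grouping factor
#' (clinical phenotype, treatment flag, comorbidity flag, ...) with subject
#' random intercept and slope, and reports each group's fitted baseline
#' stage (intercept) and annual rate of change (slope) with standard
#' errors, plus pairwise Wald contrasts of both.
#'
#' @param stages data.frame with \code{stage}, \code{subject_id},
#'   \code{visit_time_years} and the grouping column
#' @param group name of the grouping column (>= 2 levels present)
#' @param REML use REML (default FALSE)
#' @return list of class \code{ebm_group_summary}: \code{groups} (per-group
#'   intercept and slope with SEs), \code{contrasts} (pairwise differences
#'   with Wald p-values), and the fitted model
#' @export
group_stage_summary <- function(stages, group, REML = FALSE) {
  need <- c("stage", "subject_id", "visit_time_years", group)
  miss <- setdiff(need, names(stages))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d <- stages[complete.cases(stages[, need]), need]
  d$.group <- factor(d[[group]])
  # drop groups represented by a single subject
  n_subj <- tapply(d$subject_id, d$.group, function(s) length(unique(s)))
  small <- names(n_subj)[n_subj < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with a single subject: ",
            paste(small, collapse = ", "), call. = FALSE)
    d <- d[!(d$.group %in% small), ]
    d$.group <- droplevels(d$.group)
  }
  if (nlevels(d$.group) < 2)
    stop("need at least two groups for a contrast", call. = FALSE)
  fit <- fit_mixed_with_fallback(
    "stage ~ 0 + .group + .group:visit_time_years", d,
    time = "visit_time_years", random_slope = TRUE, REML = REML)
  cf <- if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
  V <- as.matrix(vcov(fit))
  lev <- levels(d$.group)
  i_int <- match(paste0(".group", lev), names(cf))
  i_slp <- match(paste0(".group", lev, ":visit_time_years"), names(cf))
  groups <- data.frame(group = lev,
                       intercept = unname(cf[i_int]),
                       intercept_se = sqrt(diag(V)[i_int]),
                       slope = unname(cf[i_slp]),
                       slope_se = sqrt(diag(V)[i_slp]),
                       stringsAsFactors = FALSE)
  pairs <- utils::combn(seq_along(lev), 2)
  contrasts <- do.call(rbind, apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    rows <- lapply(c(intercept = TRUE, slope = FALSE), function(is_int) {
      idx <- if (is_int) i_int else i_slp
      est <- cf[idx[i]] - cf[idx[j]]
      se <- sqrt(V[idx[i], idx[i]] + V[idx[j], idx[j]] -
                   2 * V[idx[i], idx[j]])
      data.frame(quantity = if (is_int) "intercept" else "slope",
                 group_a = lev[i], group_b = lev[j],
                 difference = unname(est), se = se,
                 p = 2 * pnorm(-abs(est / se)), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  rownames(contrasts) <- NULL
  out <- list(groups = groups, contrasts = contrasts, model = fit)
  class(out) <- "ebm_group_summary"
  out
}

#' @export
print.ebm_group_summary <- function(x, ...) {
  cat("Per-group model-stage trajectories (intercept = baseline stage,",
      "slope = stages/year):\n")
  print(x$groups, digits = 3)
  invisible(x)
}
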