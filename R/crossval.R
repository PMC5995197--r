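#' Subject-level, phenotype-stratified cross-validation folds
#'
#' All scans of a subject share one fold (preventing within-subject leakage
#' between training and test data), and subjects are allocated round-robin
#' within each phenotype so that every training set keeps healthy controls
#' for the fixed mixture component.
#'
#' @param cohort a cohort data.frame (or any data.frame with
#'   \code{subject_id} and \code{phenotype})
#' @param k_folds number of folds (default 10)
#' @param seed optional RNG seed
#' @return integer vector of fold labels (1..k_folds), one per row of
#'   \code{cohort}
#' @export
make_folds <- function(cohort, k_folds = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subj <- unique(cohort$subject_id)
  if (length(subj) < k_folds)
    stop("fewer subjects (", length(subj), ") than folds (", k_folds, ")",
         call. = FALSE)
  pheno <- cohort$phenotype[match(subj, cohort$subject_id)]
  fold_of <- setNames(integer(length(subj)), subj)
  offset <- 0L
  for (ph in unique(pheno)) {
    members <- sample(subj[pheno == ph])
    # continue the round-robin across phenotypes to keep fold sizes balanced
    fold_of[members] <- ((offset + seq_along(members) - 1L) %% k_folds) + 1L
    offset <- offset + length(members)
  }
  unname(fold_of[cohort$subject_id])
}

#' Cross-validated sequence estimation, posterior sampling and held-out
#' staging
#'
#' Repeats the model fit across k folds: in each iteration the mixtures and
#' the greedy maximum-likelihood sequence are re-estimated on the training
#' k-1 folds, the sequence posterior is sampled by MCMC
#' (\code{samples_per_fold} draws, initialized at the training-fold
#' sequence), and the held-out fold is staged with the training-fold model.
#' Samples from all folds are aggregated into a single positional variance
#' diagram ordered by the full-data maximum-likelihood sequence, so the
#' diagram reflects both posterior and across-fold uncertainty. Every scan
#' receives exactly one held-out stage, from a model never trained on its
#' own subject.
#'
#' @param adjusted an \code{ebm_adjusted} object (adjustment is fitted once,
#'   on the full table)
#' @param regions regions entering the model (e.g. the selected set)
#' @param k_folds number of folds (default 10)
#' @param samples_per_fold MCMC draws per fold (default 10000)
#' @param burn_in MCMC burn-in per fold
#' @param n_starts,n_iter greedy-ascent settings per fold
#' @param stage_scans which scans to stage: \code{"all"} or
#'   \code{"patients"}
#' @param seed RNG seed controlling folds, greedy restarts and MCMC
#' @return list of class \code{ebm_cv}: \code{pvd} (aggregate positional
#'   variance diagram), \code{stages} (held-out stage per scan),
#'   \code{fold_sequences} (k x l matrix), \code{full_fit} (the full-data
#'   \code{ebm_fit}), \code{folds}, \code{n_samples}, per-fold acceptance
#'   rates
#' @export
cross_validated_ebm <- function(adjusted, regions, k_folds = 10L,
                                samples_per_fold = 10000L, burn_in = 1000L,
                                n_starts = 10L, n_iter = 1000L,
                                stage_scans = c("all", "patients"),
                                seed = 1L) {
  stopifnot(inherits(adjusted, "ebm_adjusted"))
  stage_scans <- match.arg(stage_scans)
  set.seed(seed)
  folds <- make_folds(adjusted$meta, k_folds)
  l <- length(regions)

  # full-data fit orders the rows of the aggregate diagram
  mix_full <- fit_mixtures(adjusted, regions)
  lik_full <- event_likelihoods(adjusted, mix_full, scans = "patients")
  full_fit <- greedy_ascent(lik_full, n_starts = n_starts, n_iter = n_iter)

  all_samples <- vector("list", k_folds)
  fold_seqs <- matrix(NA_integer_, nrow = k_folds, ncol = l)
  acc <- numeric(k_folds)
  stage_list <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    train <- folds != f
    test <- !train
    if (!any(adjusted$meta$phenotype[train] == "HC" &
             adjusted$meta$visit_time_years[train] == 0))
      stop("fold ", f, " leaves no healthy-control baselines for training; ",
           "stratify folds by phenotype", call. = FALSE)
    adj_train <- subset_adjusted(adjusted, train)
    mix <- fit_mixtures(adj_train, regions)
    lik_train <- event_likelihoods(adj_train, mix, scans = "patients")
    fit <- greedy_ascent(lik_train, n_starts = n_starts, n_iter = n_iter)
    fold_seqs[f, ] <- fit$sequence
    samp <- mcmc_sequences(lik_train, fit$sequence,
                           n_samples = samples_per_fold, burn_in = burn_in)
    all_samples[[f]] <- samp$samples
    acc[f] <- samp$acceptance_rate
    # stage held-out scans with the training-fold mixtures and sequence
    lik_test <- event_likelihoods(adjusted, mix,
                                  scans = which(test &
                                    (stage_scans == "all" |
                                     adjusted$meta$phenotype != "HC")))
    st <- assign_stages(lik_test, fit$sequence)
    st$fold <- f
    stage_list[[f]] <- st
  }
  samples <- do.call(rbind, all_samples)
  pvd <- positional_variance(samples, full_fit$sequence, regions = regions)
  stages <- do.call(rbind, stage_list)
  out <- list(pvd = pvd, stages = stages, fold_sequences = fold_seqs,
              full_fit = full_fit, folds = folds,
              n_samples = nrow(samples), acceptance_rates = acc,
              regions = regions, seed = seed)
  class(out) <- "ebm_cv"
  out
}

subset_adjusted <- function(adjusted, rows) {
  out <- adjusted
  out$z <- adjusted$z[rows, , drop = FALSE]
  out$meta <- adjusted$meta[rows, , drop = FALSE]
  out
}

#' @export
print.ebm_cv <- function(x, ...) {
  cat("Cross-validated event-based model:", nrow(x$fold_sequences),
      "folds,", x$n_samples, "aggregated posterior samples\n")
  cat("Mean MCMC acceptance rate:",
      sprintf("%.3f", mean(x$acceptance_rates)), "\n")
  invisible(x)
}
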