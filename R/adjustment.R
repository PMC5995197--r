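#' Default nuisance covariates for volume adjustment
#' @export
EBM_COVARIATES <- c("total_icv_ml", "age_at_entry", "sex",
                    "field_strength", "protocol_id")

region_columns <- function(cohort, prefix = "vol_") {
  nm <- names(cohort)[startsWith(names(cohort), prefix)]
  if (length(nm) == 0) stop("no region volume columns (prefix '", prefix,
                            "') found", call. = FALSE)
  nm
}

#' Residualize regional volumes against nuisance covariates and z-score
#'
#' Fits one ordinary least-squares model per region with the volume as the
#' outcome and the nuisance covariates (intracranial volume, age at study
#' entry, sex, scanner field strength, MRI protocol by default) as
#' predictors; categorical covariates enter as indicator contrasts. The
#' residuals are standardized to z-scores using the healthy-control baseline
#' residual mean and SD, so "normal" is centred at 0 with unit spread — the
#' anchor required for the fixed normal mixture component.
#'
#' @param cohort a cohort data.frame (see \code{simulate_cohort} /
#'   \code{load_cohort} for the column dictionary)
#' @param covariates character vector of covariate column names
#' @param fit_on \code{"all"} (default) fits the regressions on all scans;
#'   \code{"controls"} restricts the fit to healthy-control scans, which
#'   avoids absorbing disease signal correlated with covariates at the cost
#'   of extrapolating the nuisance model to patients.
#' @param prefix prefix identifying region volume columns
#' @return an object of class \code{ebm_adjusted}: list with \code{z}
#'   (scans x regions matrix of adjusted z-scores), \code{coefficients}
#'   (regions x terms), \code{hc_center}, \code{hc_scale}, and the scan
#'   metadata columns of \code{cohort}
#' @export
adjust_volumes <- function(cohort, covariates = EBM_COVARIATES,
                           fit_on = c("all", "controls"),
                           prefix = "vol_") {
  fit_on <- match.arg(fit_on)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0)
    stop("covariates not in cohort table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  regs <- region_columns(cohort, prefix)
  fml <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- model.matrix(fml, data = cohort)
  if (nrow(X) != nrow(cohort))
    stop("covariates contain missing values", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    # identify the offending column for the error message
    bad <- colnames(X)[qr(X)$pivot[-seq_len(qr(X)$rank)]]
    stop("rank-deficient covariate design; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit_rows <- if (fit_on == "controls") which(cohort$phenotype == "HC")
              else seq_len(nrow(cohort))
  if (length(fit_rows) < ncol(X) + 10)
    stop("need at least 10 more scans than fitted coefficients", call. = FALSE)

  Y <- as.matrix(cohort[, regs, drop = FALSE])
  if (anyNA(Y)) {
    n_missing <- sum(is.na(Y))
    message(n_missing, " missing volume value(s); affected scans excluded ",
            "per region")
  }
  complete <- !colSums(is.na(Y[fit_rows, , drop = FALSE]))
  beta <- matrix(NA_real_, nrow = ncol(X), ncol = ncol(Y),
                 dimnames = list(colnames(X), colnames(Y)))
  if (any(complete))
    beta[, complete] <- lm.fit(X[fit_rows, , drop = FALSE],
                               Y[fit_rows, complete, drop = FALSE])$coefficients
  for (r in which(!complete)) {   # per-region refit on complete rows only
    ok <- fit_rows[!is.na(Y[fit_rows, r])]
    beta[, r] <- lm.fit(X[ok, , drop = FALSE], Y[ok, r])$coefficients
  }
  resid_all <- Y - X %*% beta

  hc_base <- which(cohort$phenotype == "HC" & cohort$visit_time_years == 0)
  if (length(hc_base) < 2)
    stop("need healthy-control baseline scans to anchor the z-scores",
         call. = FALSE)
  ctr <- colMeans(resid_all[hc_base, , drop = FALSE], na.rm = TRUE)
  scl <- apply(resid_all[hc_base, , drop = FALSE], 2, sd, na.rm = TRUE)
  degenerate <- which(!is.finite(scl) | scl <= 0)
  if (length(degenerate) > 0)
    stop("zero healthy-control variance in region(s): ",
         paste(regs[degenerate], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(resid_all, 2, ctr, "-"), 2, scl, "/")
  colnames(z) <- sub(paste0("^", prefix), "", regs)

  meta_cols <- setdiff(names(cohort), regs)
  out <- list(z = z,
              coefficients = t(beta),
              hc_center = setNames(ctr, colnames(z)),
              hc_scale = setNames(scl, colnames(z)),
              meta = cohort[, meta_cols, drop = FALSE],
              covariates = covariates,
              fit_on = fit_on)
  class(out) <- "ebm_adjusted"
  out
}

#' @export
print.ebm_adjusted <- function(x, ...) {
  cat("Adjusted volumes:", nrow(x$z), "scans x", ncol(x$z), "regions\n")
  cat("Covariates:", paste(x$covariates, collapse = ", "),
      "(fit on", x$fit_on, "scans)\n")
  invisible(x)
}

#' Select regions separating patients from controls at baseline
#'
#' Applies a two-sample Welch t-test per region comparing adjusted baseline
#' volumes of all patients against healthy controls, and selects regions
#' with p below the Bonferroni-corrected threshold \code{alpha / n_tested}.
#' With the paper-style corrected level 0.01 over ~100 regions this is an
#' uncorrected per-test cutoff of 1e-4.
#'
#' @param adjusted an \code{ebm_adjusted} object
#' @param alpha corrected significance level (default 0.01)
#' @return data.frame with one row per region (sorted by p): region name,
#'   group means, t statistic, p-value, selected flag. Regions untestable
#'   because of zero variance in a group carry \code{NA} p and are never
#'   selected. The per-test cutoff is stored in attribute \code{"cutoff"}.
#' @export
select_regions <- function(adjusted, alpha = 0.01) {
  stopifnot(inherits(adjusted, "ebm_adjusted"))
  base <- adjusted$meta$visit_time_years == 0
  grp_hc <- base & adjusted$meta$phenotype == "HC"
  grp_ms <- base & adjusted$meta$phenotype != "HC"
  if (!any(grp_hc) || !any(grp_ms))
    stop("both patients and healthy controls are required at baseline",
         call. = FALSE)
  regs <- colnames(adjusted$z)
  n_test <- length(regs)
  cutoff <- alpha / n_test
  res <- lapply(regs, function(r) {
    x <- adjusted$z[grp_ms, r]
    y <- adjusted$z[grp_hc, r]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (var(x) == 0 || var(y) == 0)
      return(data.frame(region = r, mean_patients = mean(x),
                        mean_controls = mean(y), t = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    tt <- t.test(x, y)  # Welch by default
    data.frame(region = r, mean_patients = mean(x), mean_controls = mean(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$selected <- !is.na(out$p) & out$p < cutoff
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "alpha") <- alpha
  out
}
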