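COHORT_MANDATORY <- c("subject_id", "visit_time_years", "phenotype")
COHORT_NUMERIC <- c("visit_time_years", "age_at_entry", "total_icv_ml",
                    "lesion_load_ml", "edss", "disease_duration_years")

#' Load and validate a cohort table
#'
#' Reads a CSV/TSV cohort table (one row per scan) and validates it against
#' the column dictionary used throughout the package: mandatory columns
#' \code{subject_id}, \code{visit_time_years}, \code{phenotype}
#' (from \code{EBM_PHENOTYPES}), region volume columns identified by a
#' common prefix (default \code{vol_}), and optional clinical/covariate
#' columns. Violations are reported with row and column coordinates.
#'
#' @param path file path (delimiter inferred from the extension: .tsv/.txt
#'   use tab, otherwise comma)
#' @param prefix prefix identifying region volume columns
#' @return validated cohort data.frame
#' @export
load_cohort <- function(path, prefix = "vol_") {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  cohort <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                     check.names = FALSE)
  validate_cohort(cohort, prefix = prefix)
}

#' Validate an in-memory cohort table
#'
#' @param cohort data.frame, one row per scan
#' @param prefix region column prefix
#' @return the cohort, invisibly checked
#' @export
validate_cohort <- function(cohort, prefix = "vol_") {
  miss <- setdiff(COHORT_MANDATORY, names(cohort))
  if (length(miss) > 0)
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_ph <- which(!cohort$phenotype %in% EBM_PHENOTYPES)
  if (length(bad_ph) > 0)
    stop("unknown phenotype in row(s) ",
         paste(utils::head(bad_ph, 5), collapse = ", "),
         " (allowed: ", paste(EBM_PHENOTYPES, collapse = ", "), ")",
         call. = FALSE)
  key <- paste(cohort$subject_id, cohort$visit_time_years)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (subject, visit) row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  regs <- region_columns(cohort, prefix)
  for (r in regs) {
    if (!is.numeric(cohort[[r]]))
      stop("non-numeric volume column: ", r, call. = FALSE)
    neg <- which(cohort[[r]] <= 0)
    if (length(neg) > 0)
      stop("non-positive volume in column ", r, ", row(s) ",
           paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort data.frame
#' @param path output path
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (j in seq_along(out))   # full precision so finite doubles round-trip
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  out[out == "NA"] <- NA
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
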