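#' Stage log-likelihood profile for one scan
#'
#' For a scan with per-region event / non-event densities, the stage-k
#' log-likelihood is the log product of event densities for the first k
#' sequence positions and non-event densities for the rest, for k = 0..l.
#'
#' @param p_event,p_noevent per-region density vectors (original region
#'   order, strictly positive)
#' @param seq integer permutation giving the event sequence
#' @return numeric vector of length l + 1 (stages 0..l)
#' @export
stage_profile <- function(p_event, p_noevent, seq) {
  if (length(p_event) != length(p_noevent))
    stop("density vectors must have equal length", call. = FALSE)
  if (any(p_event <= 0) || any(p_noevent <= 0))
    stop("densities must be strictly positive", call. = FALSE)
  seq <- as.integer(seq)
  if (!setequal(seq, seq_along(p_event)))
    stop("seq must be a permutation of the regions", call. = FALSE)
  lpe <- log(p_event)[seq]
  lpn <- log(p_noevent)[seq]
  prof <- c(0, cumsum(lpe)) + rev(c(0, cumsum(rev(lpn))))
  names(prof) <- 0:length(seq)
  prof
}

#' Assign each scan its maximum-likelihood model stage
#'
#' The stage of a scan is the k maximizing the stage-k likelihood along the
#' given sequence; ties are broken toward the smaller k (the conservative
#' choice: fewer atrophic regions claimed). Stage 0 means no region has
#' become abnormal; stage l means all have. Set \code{one_based = TRUE} to
#' report stages on a 1..l+1 presentation scale instead.
#'
#' @param lik an \code{ebm_likelihoods} object
#' @param seq the event sequence (integer permutation or region names)
#' @param one_based report stages shifted up by one (default FALSE)
#' @param keep_profile attach the full stage log-likelihood matrix
#' @return data.frame of class \code{ebm_stages}: one row per scan with the
#'   scan metadata (when present) and a \code{stage} column; optionally the
#'   profile matrix in attribute \code{"profile"}
#' @export
assign_stages <- function(lik, seq, one_based = FALSE, keep_profile = FALSE) {
  stopifnot(inherits(lik, "ebm_likelihoods"))
  seq <- resolve_sequence(lik, seq)
  prof <- stage_profiles_cpp(lik$log_p_event, lik$log_p_noevent, seq)
  stage <- max.col(prof, ties.method = "first") - 1L  # ties toward smaller k
  if (one_based) stage <- stage + 1L
  out <- if (!is.null(lik$meta)) cbind(lik$meta,
                                       data.frame(stage = stage))
         else data.frame(scan = seq_len(lik$n_scans), stage = stage)
  if (keep_profile) attr(out, "profile") <- prof
  class(out) <- c("ebm_stages", class(out))
  out
}
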