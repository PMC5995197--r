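#' Uniform prior over model stages 0..l
#'
#' Stage k means the first k events of the sequence have occurred; stage 0
#' (no events) is included so that healthy scans have positive prior mass.
#'
#' @param l number of regions
#' @return numeric vector of length l + 1 summing to 1
#' @export
uniform_stage_prior <- function(l) rep(1 / (l + 1), l + 1)

resolve_sequence <- function(lik, seq) {
  if (is.character(seq)) {
    idx <- match(seq, lik$regions)
    if (anyNA(idx)) stop("unknown region(s) in sequence: ",
                         paste(seq[is.na(idx)], collapse = ", "), call. = FALSE)
    seq <- idx
  }
  seq <- as.integer(seq)
  if (!setequal(seq, seq_len(lik$n_regions)) ||
      length(seq) != lik$n_regions)
    stop("sequence must be a permutation of the regions in the likelihood ",
         "matrices", call. = FALSE)
  seq
}

check_prior <- function(prior, l) {
  if (is.null(prior)) return(uniform_stage_prior(l))
  if (length(prior) != l + 1)
    stop("stage prior must have length l + 1 (stages 0..l)", call. = FALSE)
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-8)
    stop("stage prior must be a probability distribution over 0..l",
         call. = FALSE)
  prior
}

#' Total data log-likelihood of an event sequence
#'
#' For each scan, sums over the latent stage k = 0..l the prior P(k) times
#' the product of event densities for regions at sequence positions <= k and
#' non-event densities for the rest; the scan contributions multiply. All
#' arithmetic is in log space (prefix/suffix cumulative sums plus
#' log-sum-exp), so evaluation is O(l) per scan.
#'
#' @param lik an \code{ebm_likelihoods} object
#' @param seq an event sequence: integer permutation (indices into
#'   \code{lik$regions}) or character vector of region names
#' @param prior stage prior over 0..l; default uniform
#' @return scalar log-likelihood
#' @export
sequence_loglik <- function(lik, seq, prior = NULL) {
  stopifnot(inherits(lik, "ebm_likelihoods"))
  seq <- resolve_sequence(lik, seq)
  prior <- check_prior(prior, lik$n_regions)
  seq_loglik_cpp(lik$log_p_event, lik$log_p_noevent, seq, log(prior))
}

#' Greedy-ascent search for the maximum-likelihood event sequence
#'
#' Runs \code{n_starts} independent searches, each starting from a uniformly
#' random permutation and proposing \code{n_iter} random transpositions
#' (swaps of two positions); a proposal is accepted only if it strictly
#' increases the sequence log-likelihood, so each trajectory is
#' non-decreasing. The best sequence over all starts is returned together
#' with the per-start final log-likelihoods, whose spread is the standard
#' convergence diagnostic.
#'
#' @param lik an \code{ebm_likelihoods} object
#' @param n_starts number of random restarts (default 10)
#' @param n_iter proposals per start (default 1000)
#' @param prior stage prior; default uniform
#' @param seed optional RNG seed for reproducibility
#' @return object of class \code{ebm_fit}: list with \code{sequence}
#'   (integer permutation), \code{sequence_regions}, \code{loglik},
#'   \code{start_loglik}, \code{trace} (n_starts x n_iter, non-decreasing
#'   rows), \code{start_sequences}
#' @export
greedy_ascent <- function(lik, n_starts = 10L, n_iter = 1000L, prior = NULL,
                          seed = NULL) {
  stopifnot(inherits(lik, "ebm_likelihoods"))
  if (n_starts < 1 || n_iter < 1)
    stop("n_starts and n_iter must be >= 1", call. = FALSE)
  prior <- check_prior(prior, lik$n_regions)
  if (!is.null(seed)) set.seed(seed)
  res <- greedy_cpp(lik$log_p_event, lik$log_p_noevent, log(prior),
                    as.integer(n_starts), as.integer(n_iter))
  res$sequence_regions <- lik$regions[res$sequence]
  res$regions <- lik$regions
  class(res) <- "ebm_fit"
  res
}

#' @export
print.ebm_fit <- function(x, ...) {
  cat("Maximum-likelihood event sequence (log-likelihood ",
      format(x$loglik, digits = 8), "):\n", sep = "")
  cat(paste(seq_along(x$sequence_regions), x$sequence_regions,
            collapse = " -> "), "\n")
  cat("Final log-likelihood range over restarts: [",
      format(min(x$start_loglik), digits = 8), ", ",
      format(max(x$start_loglik), digits = 8), "]\n", sep = "")
  invisible(x)
}

#' Metropolis MCMC over event sequences
#'
#' Samples the posterior over sequences under a uniform prior on
#' permutations, using the symmetric random-transposition proposal and
#' acceptance probability min(1, exp(delta log-likelihood)). Initialize at
#' the greedy maximum-likelihood sequence to shorten burn-in.
#'
#' @param lik an \code{ebm_likelihoods} object
#' @param init initial sequence (integer permutation or region names)
#' @param n_samples retained draws
#' @param burn_in discarded initial draws (default 1000)
#' @param prior stage prior; default uniform
#' @param seed optional RNG seed
#' @return object of class \code{ebm_samples}: list with \code{samples}
#'   (n_samples x l integer matrix, row = permutation), \code{loglik},
#'   \code{acceptance_rate}, \code{regions}, \code{burn_in}
#' @export
mcmc_sequences <- function(lik, init, n_samples, burn_in = 1000L,
                           prior = NULL, seed = NULL) {
  stopifnot(inherits(lik, "ebm_likelihoods"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  init <- resolve_sequence(lik, init)
  prior <- check_prior(prior, lik$n_regions)
  if (!is.null(seed)) set.seed(seed)
  res <- mcmc_cpp(lik$log_p_event, lik$log_p_noevent, log(prior),
                  init, as.integer(n_samples), as.integer(burn_in))
  out <- list(samples = res$samples, loglik = res$loglik,
              acceptance_rate = res$acceptance_rate,
              regions = lik$regions, burn_in = as.integer(burn_in))
  class(out) <- "ebm_samples"
  out
}

#' @export
print.ebm_samples <- function(x, ...) {
  cat("MCMC sequence samples:", nrow(x$samples), "draws over",
      length(x$regions), "regions; acceptance rate",
      sprintf("%.3f", x$acceptance_rate), "\n")
  invisible(x)
}

#' Positional variance diagram
#'
#' Summarizes ordering uncertainty: entry (r, p) is the fraction of
#' posterior samples in which region r occupies sequence position p. Rows
#' are ordered by a reference sequence (normally the maximum-likelihood
#' one), so a certain posterior gives the identity matrix. Because every
#' sample is a permutation, rows and columns each sum to 1.
#'
#' @param samples an \code{ebm_samples} object, or an integer matrix of
#'   permutations (one per row)
#' @param reference sequence ordering the rows (integer permutation or
#'   region names); regions taken from \code{samples} when available
#' @param regions region names (needed when \code{samples} is a bare matrix)
#' @return l x l matrix of class \code{ebm_pvd}; rownames are region names
#'   in reference order, colnames the positions
#' @export
positional_variance <- function(samples, reference, regions = NULL) {
  if (inherits(samples, "ebm_samples")) {
    regions <- samples$regions
    samples <- samples$samples
  }
  samples <- as.matrix(samples)
  l <- ncol(samples)
  if (is.null(regions)) regions <- sprintf("R%02d", seq_len(l))
  if (nrow(samples) < 1) stop("no samples", call. = FALSE)
  if (is.character(reference)) reference <- match(reference, regions)
  reference <- as.integer(reference)
  if (!setequal(reference, seq_len(l)))
    stop("reference must be a permutation of the sampled regions",
         call. = FALSE)
  counts <- matrix(0, nrow = l, ncol = l)
  for (p in seq_len(l)) {
    tab <- tabulate(samples[, p], nbins = l)
    counts[, p] <- counts[, p] + tab
  }
  pvd <- counts / nrow(samples)
  pvd <- pvd[reference, , drop = FALSE]
  dimnames(pvd) <- list(regions[reference], seq_len(l))
  class(pvd) <- c("ebm_pvd", class(pvd))
  pvd
}

#' Heatmap of a positional variance diagram
#'
#' @param x an \code{ebm_pvd} matrix
#' @param ... passed to \code{graphics::image}
#' @export
plot.ebm_pvd <- function(x, ...) {
  l <- ncol(x)
  m <- unclass(x)
  graphics::image(x = seq_len(l), y = seq_len(l), z = t(m[l:1, ]),
                  col = gray(seq(1, 0, length.out = 64)),
                  xlab = "Sequence position", ylab = "", axes = FALSE, ...)
  graphics::axis(1, at = seq_len(l))
  graphics::axis(2, at = seq_len(l), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
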