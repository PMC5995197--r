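#' Estimate the fixed normal mixture component from healthy controls
#'
#' The normal ("no event") component of each region's two-Gaussian mixture
#' is pinned to the healthy-control distribution: its mean and SD are the
#' sample mean and SD of the control baseline z-values and are never
#' re-estimated during EM.
#'
#' @param hc_values numeric vector of healthy-control z-values (>= 20)
#' @param sigma_floor smallest admissible SD (z units)
#' @return named numeric vector \code{c(mu, sigma)}
#' @export
estimate_normal_component <- function(hc_values, sigma_floor = 0.05) {
  hc_values <- hc_values[is.finite(hc_values)]
  if (length(hc_values) < 20)
    stop("need at least 20 healthy-control values", call. = FALSE)
  s <- sd(hc_values)
  if (!is.finite(s) || s < sigma_floor)
    stop("degenerate healthy-control distribution: SD below the floor of ",
         sigma_floor, call. = FALSE)
  c(mu = mean(hc_values), sigma = s)
}

#' Fit the abnormal component of a fixed-normal two-Gaussian mixture
#'
#' Expectation-maximization over the abnormal mean, abnormal SD and mixing
#' fraction, with the normal component frozen at the healthy-control
#' estimate. Atrophy means smaller volume, so the abnormal mean is
#' constrained to lie at or below the normal mean (enforced by projection).
#' Initialization is deterministic: the abnormal mean starts at the mean of
#' patient values below the normal mean (falling back to \code{mu_normal - 1}),
#' the abnormal SD at the normal SD, and the mixing fraction at 0.5.
#'
#' @param patient_values numeric z-values from patient scans (>= 30)
#' @param mu_normal,sigma_normal frozen normal-component parameters
#' @param tol convergence tolerance on successive log-likelihoods
#' @param max_iter iteration cap
#' @param sigma_floor smallest admissible abnormal SD
#' @return object of class \code{ebm_mixture}: list with \code{mu_normal},
#'   \code{sigma_normal}, \code{mu_abnormal}, \code{sigma_abnormal},
#'   \code{mixing_fraction}, \code{loglik} (per-iteration trace),
#'   \code{iterations}, \code{converged}, \code{weak_event}
#' @export
fit_region_mixture <- function(patient_values, mu_normal = 0, sigma_normal = 1,
                               tol = 1e-6, max_iter = 500L,
                               sigma_floor = 0.05) {
  x <- patient_values[is.finite(patient_values)]
  if (length(x) < 30)
    stop("need at least 30 patient values", call. = FALSE)
  if (sigma_normal < sigma_floor)
    stop("sigma_normal below the floor", call. = FALSE)

  below <- x[x < mu_normal]
  mu_a <- if (length(below) > 0) mean(below) else mu_normal - 1
  mu_a <- min(mu_a, mu_normal)
  sig_a <- sigma_normal
  w <- 0.5

  obs_ll <- function(mu_a, sig_a, w) {
    d <- w * dnorm(x, mu_a, sig_a) + (1 - w) * dnorm(x, mu_normal, sigma_normal)
    sum(log(pmax(d, 1e-300)))
  }
  ll_trace <- obs_ll(mu_a, sig_a, w)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    da <- w * dnorm(x, mu_a, sig_a)
    dn <- (1 - w) * dnorm(x, mu_normal, sigma_normal)
    resp <- da / pmax(da + dn, 1e-300)
    sw <- sum(resp)
    w <- sw / length(x)
    if (sw > 0) {
      mu_a <- sum(resp * x) / sw
      sig_a <- sqrt(sum(resp * (x - mu_a)^2) / sw)
    }
    mu_a <- min(mu_a, mu_normal)            # atrophy = smaller volume
    sig_a <- max(sig_a, sigma_floor)
    ll_new <- obs_ll(mu_a, sig_a, w)
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll_trace[length(ll_trace) - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  # weak event: the mixture explains the patient data no better than the
  # pure normal model, i.e. there is no detectable abnormal component. The
  # region is made explicitly uninformative (abnormal pinned to normal,
  # mixing ~ 0) so identical components leave the sequence likelihood and
  # staging invariant.
  ll_normal <- sum(dnorm(x, mu_normal, sigma_normal, log = TRUE))
  gain <- (ll_trace[length(ll_trace)] - ll_normal) / length(x)
  weak <- w < 0.02 || gain < 1e-3
  if (weak) {
    warning("weak-event region: mixing fraction ", signif(w, 3),
            " (log-likelihood gain ", signif(gain, 2),
            " per scan); event likelihoods will never dominate",
            call. = FALSE)
    mu_a <- mu_normal
    sig_a <- sigma_normal
    w <- 0
  }
  if (!converged)
    warning("EM did not converge within ", max_iter,
            " iterations; best iterate returned", call. = FALSE)
  out <- list(mu_normal = mu_normal, sigma_normal = sigma_normal,
              mu_abnormal = mu_a, sigma_abnormal = sig_a,
              mixing_fraction = w, loglik = ll_trace,
              iterations = it, converged = converged, weak_event = weak)
  class(out) <- "ebm_mixture"
  out
}

#' @export
print.ebm_mixture <- function(x, ...) {
  cat(sprintf(
    "Two-Gaussian mixture (normal fixed): normal N(%.3f, %.3f^2), abnormal N(%.3f, %.3f^2), mixing %.3f (%d EM iterations, %s)\n",
    x$mu_normal, x$sigma_normal, x$mu_abnormal, x$sigma_abnormal,
    x$mixing_fraction, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Fit per-region mixtures across a cohort
#'
#' The normal component comes from healthy-control baseline scans; the
#' abnormal component is fitted by EM on patient scans (all visits by
#' default, or patients pooled with controls via \code{pool_controls}).
#'
#' @param adjusted an \code{ebm_adjusted} object
#' @param regions region names to model (default: all)
#' @param pool_controls if TRUE the mixture is fitted on patients and
#'   controls pooled; default FALSE (patients only)
#' @param ... passed to \code{fit_region_mixture}
#' @return named list of \code{ebm_mixture} objects
#' @export
fit_mixtures <- function(adjusted, regions = colnames(adjusted$z),
                         pool_controls = FALSE, ...) {
  stopifnot(inherits(adjusted, "ebm_adjusted"))
  hc_base <- adjusted$meta$phenotype == "HC" &
    adjusted$meta$visit_time_years == 0
  fit_rows <- if (pool_controls) rep(TRUE, nrow(adjusted$z))
              else adjusted$meta$phenotype != "HC"
  out <- lapply(regions, function(r) {
    nc <- estimate_normal_component(adjusted$z[hc_base, r])
    fit_region_mixture(adjusted$z[fit_rows, r],
                       mu_normal = nc[["mu"]], sigma_normal = nc[["sigma"]],
                       ...)
  })
  names(out) <- regions
  out
}

#' Export mixture parameters as a table
#'
#' @param mixtures named list of \code{ebm_mixture} objects
#' @return data.frame, one row per region
#' @export
mixture_table <- function(mixtures) {
  do.call(rbind, lapply(names(mixtures), function(r) {
    m <- mixtures[[r]]
    data.frame(region = r, mu_normal = m$mu_normal,
               sigma_normal = m$sigma_normal, mu_abnormal = m$mu_abnormal,
               sigma_abnormal = m$sigma_abnormal,
               mixing_fraction = m$mixing_fraction,
               iterations = m$iterations, converged = m$converged,
               stringsAsFactors = FALSE)
  }))
}

#' Per-scan event and non-event likelihood matrices
#'
#' Evaluates, for each scan and region, the Gaussian density of the adjusted
#' value under the abnormal component (the likelihood that atrophy has
#' occurred, P(x|E)) and under the fixed normal component (P(x|not E)).
#' Densities are floored at 1e-300 and carried in log space. Missing values
#' get the uninformative pair (1, 1).
#'
#' @param adjusted an \code{ebm_adjusted} object
#' @param mixtures named list of \code{ebm_mixture} objects (defines the
#'   region set and order)
#' @param scans \code{"patients"} (default), \code{"all"}, or a logical/
#'   integer row index into the scan table
#' @return object of class \code{ebm_likelihoods}: list with \code{log_p_event}
#'   and \code{log_p_noevent} (J x l matrices), \code{regions}, \code{meta}
#' @export
event_likelihoods <- function(adjusted, mixtures,
                              scans = c("patients", "all")) {
  stopifnot(inherits(adjusted, "ebm_adjusted"))
  if (is.character(scans)) {
    scans <- match.arg(scans)
    rows <- if (scans == "all") seq_len(nrow(adjusted$z))
            else which(adjusted$meta$phenotype != "HC")
  } else rows <- scans
  regs <- names(mixtures)
  miss <- setdiff(regs, colnames(adjusted$z))
  if (length(miss) > 0)
    stop("no adjusted values for region(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- adjusted$z[rows, regs, drop = FALSE]
  lpe <- lpn <- matrix(0, nrow = nrow(x), ncol = length(regs),
                       dimnames = list(NULL, regs))
  n_miss <- 0L
  for (i in seq_along(regs)) {
    m <- mixtures[[regs[i]]]
    xi <- x[, i]
    ok <- is.finite(xi)
    n_miss <- n_miss + sum(!ok)
    lpe[ok, i] <- log(pmax(dnorm(xi[ok], m$mu_abnormal, m$sigma_abnormal),
                           1e-300))
    lpn[ok, i] <- log(pmax(dnorm(xi[ok], m$mu_normal, m$sigma_normal),
                           1e-300))
    # missing values already hold log(1) = 0 in both matrices
  }
  if (n_miss > 0)
    message(n_miss, " missing value(s) treated as uninformative (1, 1)")
  likelihood_matrices(exp(lpe), exp(lpn), meta = adjusted$meta[rows, ,
                                                               drop = FALSE],
                      log_input = list(lpe = lpe, lpn = lpn))
}

#' Construct likelihood matrices directly from densities
#'
#' Lower-level constructor used by \code{event_likelihoods} and by tests
#' that plant densities by hand.
#'
#' @param p_event,p_noevent J x l matrices of strictly positive densities
#' @param meta optional per-scan metadata data.frame with J rows
#' @param log_input internal: precomputed log matrices
#' @return object of class \code{ebm_likelihoods}
#' @export
likelihood_matrices <- function(p_event, p_noevent, meta = NULL,
                                log_input = NULL) {
  p_event <- as.matrix(p_event); p_noevent <- as.matrix(p_noevent)
  if (!all(dim(p_event) == dim(p_noevent)))
    stop("p_event and p_noevent must have identical dimensions", call. = FALSE)
  if (any(p_event <= 0) || any(p_noevent <= 0))
    stop("densities must be strictly positive (floor tiny values first)",
         call. = FALSE)
  if (!is.null(meta) && nrow(meta) != nrow(p_event))
    stop("meta must have one row per scan", call. = FALSE)
  regs <- colnames(p_event)
  if (is.null(regs)) regs <- sprintf("R%02d", seq_len(ncol(p_event)))
  if (is.null(log_input))
    log_input <- list(lpe = log(p_event), lpn = log(p_noevent))
  out <- list(log_p_event = unname(log_input$lpe),
              log_p_noevent = unname(log_input$lpn),
              regions = regs, n_scans = nrow(p_event),
              n_regions = ncol(p_event), meta = meta)
  class(out) <- "ebm_likelihoods"
  out
}

#' @export
print.ebm_likelihoods <- function(x, ...) {
  cat("Event likelihood matrices:", x$n_scans, "scans x", x$n_regions,
      "regions\n")
  invisible(x)
}
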