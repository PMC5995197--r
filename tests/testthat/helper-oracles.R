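# Independent oracles and fixture builders, deliberately naive:
# they evaluate the model definitions literally and stay independent of the
# package's fast implementations.

# all permutations of 1..n as a matrix (one per row)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# literal direct-summation total log-likelihood: per scan, sum the l+1
# stage terms as plain products, then log
oracle_seq_loglik <- function(p_event, p_noevent, seq, prior) {
  J <- nrow(p_event)
  total <- 0
  for (j in seq_len(J)) {
    s <- 0
    l <- length(seq)
    for (k in 0:l) {
      term <- prior[k + 1]
      if (k >= 1) for (i in 1:k) term <- term * p_event[j, seq[i]]
      if (k < l) for (i in (k + 1):l) term <- term * p_noevent[j, seq[i]]
      s <- s + term
    }
    total <- total + log(s)
  }
  total
}

# exact posterior over all permutations by enumeration
oracle_posterior <- function(p_event, p_noevent, prior) {
  l <- ncol(p_event)
  perms <- all_perms(l)
  ll <- apply(perms, 1, function(s)
    oracle_seq_loglik(p_event, p_noevent, s, prior))
  w <- exp(ll - max(ll))
  list(perms = perms, prob = w / sum(w), loglik = ll)
}

# literal stage profile for one scan
oracle_stage_profile <- function(p_event, p_noevent, seq) {
  l <- length(seq)
  sapply(0:l, function(k) {
    v <- 1
    if (k >= 1) for (i in 1:k) v <- v * p_event[seq[i]]
    if (k < l) for (i in (k + 1):l) v <- v * p_noevent[seq[i]]
    log(v)
  })
}

# random likelihood instance: J scans x l regions of positive densities
random_instance <- function(J, l) {
  list(p_event = matrix(exp(rnorm(J * l)), J, l),
       p_noevent = matrix(exp(rnorm(J * l)), J, l))
}

# a sharply separated instance whose ML sequence is the identity:
# scans progress through stages of the identity sequence with strong
# event/non-event contrast
separated_instance <- function(J, l, contrast = 6) {
  stage <- sample(0:l, J, replace = TRUE)
  x <- matrix(0, J, l)
  for (j in seq_len(J))
    x[j, ] <- ifelse(seq_len(l) <= stage[j], -contrast, 0) + rnorm(l, sd = 0.3)
  list(p_event = dnorm(x, -contrast, 1) + 1e-12,
       p_noevent = dnorm(x, 0, 1) + 1e-12)
}

small_cohort <- function(seed = 1, n = c(HC = 60, CIS = 30, RRMS = 60,
                                         SPMS = 30, PPMS = 30),
                         l = 6, separation = 2, ...) {
  simulate_cohort(sim_config(n_per_phenotype = n, n_regions = l,
                             separation = separation, seed = seed, ...))
}

kendall_to_planted <- function(fitted_regions, planted_regions) {
  cor(match(planted_regions, fitted_regions), seq_along(planted_regions),
      method = "kendall")
}
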