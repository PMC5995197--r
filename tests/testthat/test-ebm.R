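make_lik <- function(inst) likelihood_matrices(inst$p_event, inst$p_noevent)

test_that("the fast sequence log-likelihood equals the direct-summation
           oracle", {
  set.seed(1)
  for (rep in 1:20) {
    l <- sample(2:5, 1)
    J <- sample(1:20, 1)
    inst <- random_instance(J, l)
    lik <- make_lik(inst)
    s <- sample(l)
    expect_equal(sequence_loglik(lik, s),
                 oracle_seq_loglik(inst$p_event, inst$p_noevent, s,
                                   uniform_stage_prior(l)),
                 tolerance = 1e-10)
  }
})

test_that("uninformative data give zero log-likelihood for every
           permutation", {
  lik <- likelihood_matrices(matrix(1, 5, 3), matrix(1, 5, 3))
  for (s in list(1:3, c(3, 1, 2), c(2, 3, 1)))
    expect_equal(sequence_loglik(lik, s), 0, tolerance = 1e-12)
})

test_that("the two-region closed form matches", {
  # one scan; uniform prior over stages 0..2
  pe <- matrix(c(a1 <- 0.7, a2 <- 0.2), 1, 2)
  pn <- matrix(c(b1 <- 0.4, b2 <- 0.9), 1, 2)
  lik <- likelihood_matrices(pe, pn)
  manual <- log((b1 * b2 + a1 * b2 + a1 * a2) / 3)
  expect_equal(sequence_loglik(lik, 1:2), manual, tolerance = 1e-12)
})

test_that("rescaling one region's densities shifts every sequence's
           log-likelihood by the same constant", {
  set.seed(2)
  inst <- random_instance(8, 4)
  lik1 <- make_lik(inst)
  c0 <- 3.7
  inst2 <- inst
  inst2$p_event[, 2] <- inst2$p_event[, 2] * c0
  inst2$p_noevent[, 2] <- inst2$p_noevent[, 2] * c0
  lik2 <- make_lik(inst2)
  perms <- all_perms(4)
  d <- apply(perms, 1, function(s)
    sequence_loglik(lik2, s) - sequence_loglik(lik1, s))
  expect_equal(unname(d), rep(8 * log(c0), nrow(perms)), tolerance = 1e-9)
})

test_that("greedy ascent finds the exhaustive argmax on separated
           instances and its trajectories never decrease", {
  set.seed(3)
  inst <- separated_instance(40, 4)
  lik <- make_lik(inst)
  fit <- greedy_ascent(lik, n_starts = 10, n_iter = 300, seed = 4)
  post <- oracle_posterior(inst$p_event, inst$p_noevent,
                           uniform_stage_prior(4))
  best <- post$perms[which.max(post$loglik), ]
  expect_equal(fit$sequence, best)
  expect_equal(fit$loglik, max(post$loglik), tolerance = 1e-9)
  expect_true(all(apply(fit$trace, 1, function(tr) all(diff(tr) >= 0))))
  expect_gte(fit$loglik, max(fit$start_loglik) - 1e-12)
})

test_that("restarts converge to a similar likelihood on well separated
           data", {
  set.seed(5)
  inst <- separated_instance(100, 5)
  fit <- greedy_ascent(make_lik(inst), n_starts = 10, n_iter = 500, seed = 6)
  expect_lt(diff(range(fit$start_loglik)), 1e-6)
})

test_that("greedy and MCMC runs are seed-reproducible", {
  set.seed(7)
  inst <- random_instance(10, 5)
  lik <- make_lik(inst)
  f1 <- greedy_ascent(lik, n_starts = 3, n_iter = 100, seed = 11)
  f2 <- greedy_ascent(lik, n_starts = 3, n_iter = 100, seed = 11)
  expect_identical(f1$sequence, f2$sequence)
  expect_identical(f1$trace, f2$trace)
  m1 <- mcmc_sequences(lik, 1:5, n_samples = 200, burn_in = 50, seed = 12)
  m2 <- mcmc_sequences(lik, 1:5, n_samples = 200, burn_in = 50, seed = 12)
  expect_identical(m1$samples, m2$samples)
})

test_that("with uninformative data the sampler is a uniform walk on
           permutations", {
  lik <- likelihood_matrices(matrix(1, 4, 4), matrix(1, 4, 4))
  s <- mcmc_sequences(lik, 1:4, n_samples = 20000, burn_in = 500, seed = 13)
  expect_gt(s$acceptance_rate, 0.999)
  pvd <- positional_variance(s, 1:4)
  expect_true(all(abs(pvd - 0.25) < 0.03))
})

test_that("MCMC frequencies match the enumerated posterior on a sharp
           4-region instance", {
  set.seed(14)
  inst <- separated_instance(25, 4, contrast = 3)
  lik <- make_lik(inst)
  post <- oracle_posterior(inst$p_event, inst$p_noevent,
                           uniform_stage_prior(4))
  init <- post$perms[which.max(post$loglik), ]
  s <- mcmc_sequences(lik, init, n_samples = 50000, burn_in = 1000,
                      seed = 15)
  key <- apply(s$samples, 1, paste, collapse = "-")
  emp <- table(factor(key, levels = apply(post$perms, 1, paste,
                                          collapse = "-"))) / nrow(s$samples)
  tv <- 0.5 * sum(abs(as.numeric(emp) - post$prob))
  expect_lt(tv, 0.05)
})

test_that("positional variance diagrams are doubly stochastic, identity at
           zero uncertainty, and split rows under a half swap", {
  ref <- c(2, 4, 1, 3)
  same <- matrix(rep(ref, 10), nrow = 10, byrow = TRUE)
  pvd <- positional_variance(same, ref)
  expect_equal(unname(unclass(pvd)), diag(4), tolerance = 1e-15)
  swapped <- ref[c(2, 1, 3, 4)]
  half <- rbind(same, matrix(rep(swapped, 10), nrow = 10, byrow = TRUE))
  pvd2 <- positional_variance(half, ref)
  expect_equal(unname(pvd2[1, 1:2]), c(0.5, 0.5))
  expect_equal(unname(pvd2[2, 1:2]), c(0.5, 0.5))
  expect_equal(unname(pvd2[3, ]), c(0, 0, 1, 0))
  set.seed(16)
  rand <- t(replicate(200, sample(6)))
  pvd3 <- positional_variance(rand, 1:6)
  expect_equal(unname(rowSums(pvd3)), rep(1, 6), tolerance = 1e-12)
  expect_equal(unname(colSums(pvd3)), rep(1, 6), tolerance = 1e-12)
})

test_that("sequence and prior validation catch malformed input", {
  lik <- likelihood_matrices(matrix(1, 2, 3), matrix(1, 2, 3))
  expect_error(sequence_loglik(lik, c(1, 1, 2)), "permutation")
  expect_error(sequence_loglik(lik, 1:2), "permutation")
  expect_error(sequence_loglik(lik, 1:3, prior = c(0.5, 0.5)), "length")
  expect_error(sequence_loglik(lik, 1:3, prior = c(2, -1, 0, 0)),
               "probability")
  expect_error(likelihood_matrices(matrix(0, 2, 2), matrix(1, 2, 2)),
               "positive")
})
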