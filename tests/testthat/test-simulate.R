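test_that("config validation rejects malformed generative settings", {
  expect_error(sim_config(n_regions = 1), "n_regions")
  expect_error(sim_config(true_sequence = c(1, 1, 3), n_regions = 3),
               "permutation")
  expect_error(sim_config(sigma_normal = 0), "sigmas")
  expect_error(sim_config(n_per_phenotype = c(HC = -5, RRMS = 10)), ">= 0")
  expect_error(sim_config(visit_interval_years = 0), "interval")
})

test_that("same config and seed give identical cohorts", {
  cfg <- sim_config(n_per_phenotype = c(HC = 30, RRMS = 40), n_regions = 5,
                    seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$true_sequence, b$truth$true_sequence)
})

test_that("zero separation makes patient and control volumes exchangeable", {
  sim <- small_cohort(seed = 3, separation = 0,
                      n = c(HC = 80, RRMS = 80), l = 8)
  adj <- adjust_volumes(sim$cohort)
  base <- adj$meta$visit_time_years == 0
  for (r in colnames(adj$z)[1:3]) {
    p <- t.test(adj$z[base & adj$meta$phenotype == "RRMS", r],
                adj$z[base & adj$meta$phenotype == "HC", r])$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("planted two-group separation is recovered from sample means", {
  # direct group-mean check against the planted effect size
  cfg <- sim_config(n_per_phenotype = c(HC = 200, RRMS = 500), n_regions = 10,
                    separation = 2, visits_per_subject = 1,
                    baseline_stage_prob = c(HC = 0, RRMS = 1),  # all stage l
                    covariate_effects = list(tiv = 0, age = 0, sex = 0,
                                             field = 0, protocol = 0),
                    seed = 1)
  sim <- simulate_cohort(cfg)
  vols <- as.matrix(sim$cohort[, startsWith(names(sim$cohort), "vol_")])
  grp <- sim$cohort$phenotype
  for (r in seq_len(10)) {
    d <- mean(vols[grp == "HC", r]) - mean(vols[grp == "RRMS", r])
    se <- sqrt(var(vols[grp == "HC", r]) / 200 +
                 var(vols[grp == "RRMS", r]) / 500)
    # planted gap on the ml scale is separation * region_scale (= 2 ml)
    expect_lt(abs(d - 2), 3 * se)
  }
})

test_that("scans at true stage k draw abnormal values exactly at the first k
           sequence positions", {
  cfg <- sim_config(n_per_phenotype = c(HC = 50, SPMS = 1200), n_regions = 6,
                    separation = 3, visits_per_subject = 1,
                    covariate_effects = list(tiv = 0, age = 0, sex = 0,
                                             field = 0, protocol = 0),
                    region_mean_ml = 10, seed = 7)
  sim <- simulate_cohort(cfg)
  z <- as.matrix(sim$cohort[, startsWith(names(sim$cohort), "vol_")]) - 10
  stages <- sim$truth$stages$true_stage
  position <- match(seq_len(6), sim$truth$true_sequence)
  for (p in c(1, 3, 6)) {
    r <- which(position == p)
    ab <- stages >= p & sim$cohort$phenotype == "SPMS"
    no <- stages < p & sim$cohort$phenotype == "SPMS"
    if (sum(ab) > 50)
      expect_lt(abs(mean(z[ab, r]) + 3), 3 * sd(z[ab, r]) / sqrt(sum(ab)))
    if (sum(no) > 50)
      expect_lt(abs(mean(z[no, r])), 3 * sd(z[no, r]) / sqrt(sum(no)))
  }
})

test_that("stage advancement is monotone, capped, and matches the planted
           rate in expectation", {
  expect_identical(advance_stages(c(2L, 5L), rate = 0, n_visits = 4,
                                  interval_years = 1, l = 6),
                   matrix(c(2L, 5L), 2, 4))
  expect_identical(advance_stages(c(6L), rate = 10, n_visits = 3,
                                  interval_years = 1, l = 6),
                   matrix(6L, 1, 3))
  set.seed(21)
  st <- advance_stages(rep(0L, 2000), rate = 1, n_visits = 2,
                       interval_years = 1, l = 100)
  inc <- st[, 2] - st[, 1]
  expect_true(all(inc >= 0))
  expect_lt(abs(mean(inc) - 1), 3 * sd(inc) / sqrt(2000))
})

test_that("controls stay at stage 0 and carry no clinical scores", {
  sim <- small_cohort(seed = 5)
  hc <- sim$cohort$phenotype == "HC"
  expect_true(all(sim$truth$stages$true_stage[hc] == 0))
  expect_true(all(is.na(sim$cohort$edss[hc])))
  expect_true(all(is.na(sim$cohort$lesion_load_ml[hc])))
})

test_that("EDSS sits on the half-point grid in [0, 10] and lesion load is
           non-negative", {
  sim <- small_cohort(seed = 8)
  e <- sim$cohort$edss[!is.na(sim$cohort$edss)]
  expect_true(all(e >= 0 & e <= 10))
  expect_true(all(abs(e * 2 - round(e * 2)) < 1e-12))
  ll <- sim$cohort$lesion_load_ml[!is.na(sim$cohort$lesion_load_ml)]
  expect_true(all(ll >= 0))
})
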