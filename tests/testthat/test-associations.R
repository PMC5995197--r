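# build a longitudinal stage table with a directly planted fixed effect:
# stage_ij = subject intercept + subject slope * time + beta * lesion + eps
make_stage_table <- function(n_subjects = 200, visits = 3, beta_lesion = 0.25,
                             noise = 1, seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%03d", seq_len(n_subjects))
  b0 <- rnorm(n_subjects, 8, 3)
  b1 <- rnorm(n_subjects, 0.5, 0.3)
  d <- expand.grid(subject_id = subj, visit = seq_len(visits) - 1,
                   stringsAsFactors = FALSE)
  d$visit_time_years <- d$visit
  i <- match(d$subject_id, subj)
  d$lesion_load_ml <- pmax(0, rnorm(nrow(d), 10, 4))
  d$stage <- b0[i] + b1[i] * d$visit_time_years +
    beta_lesion * d$lesion_load_ml + rnorm(nrow(d), sd = noise)
  d$indep <- rnorm(nrow(d))
  d
}

test_that("a planted stage-lesion coupling is recovered within 2 SE", {
  d <- make_stage_table(n_subjects = 300, beta_lesion = 0.25, seed = 2)
  a <- mixed_effect_association(d, "lesion_load_ml")
  slope <- a$estimate[a$term == "lesion_load_ml"]
  se <- a$se[a$term == "lesion_load_ml"]
  expect_lt(abs(slope - 0.25), 2 * se)
  expect_lt(a$p[a$term == "lesion_load_ml"], 1e-6)
  # standardized coefficient definition
  expect_equal(a$std_estimate[a$term == "lesion_load_ml"],
               slope * sd(d$lesion_load_ml) / sd(d$stage), tolerance = 1e-10)
})

test_that("an independent predictor is rejected at roughly the nominal
           rate", {
  hits <- 0
  for (r in 1:60) {
    d <- make_stage_table(n_subjects = 40, visits = 2, seed = 100 + r)
    a <- suppressMessages(mixed_effect_association(d, "indep"))
    hits <- hits + (a$p[a$term == "indep"] < 0.05)
  }
  expect_lte(hits, 8)  # binomial(60, 0.05): P(X > 8) < 0.01
})

test_that("degenerate predictors error by name", {
  d <- make_stage_table(n_subjects = 40, seed = 3)
  d$flat <- 1
  expect_error(suppressMessages(mixed_effect_association(d, "flat")),
               "zero-variance")
})

test_that("annualized changes follow the definitional arithmetic", {
  d <- data.frame(subject_id = rep("A", 2), visit_time_years = c(0, 2),
                  stage = c(3, 7), edss = c(2, 3),
                  disease_duration_years = c(5, 7))
  d <- rbind(d, data.frame(subject_id = rep("B", 2),
                           visit_time_years = c(0, 4), stage = c(1, 3),
                           edss = c(1, 3), disease_duration_years = c(2, 6)),
             data.frame(subject_id = rep("C", 2), visit_time_years = c(0, 1),
                        stage = c(2, 4), edss = c(0, 1),
                        disease_duration_years = c(1, 2)))
  res <- annualized_change_regression(d)
  tab <- attr(res, "per_subject")
  expect_equal(tab$annualized_edss_change[tab$subject_id == "A"], 0.5)
  expect_equal(tab$annualized_stage_change[tab$subject_id == "A"], 2)
  expect_equal(tab$duration_at_entry, c(5, 2, 1))
})

test_that("a planted annualized EDSS-per-stage slope is recovered and
           single-visit subjects are dropped", {
  set.seed(4)
  n <- 600
  subj <- sprintf("P%03d", 1:n)
  rate <- pmax(0, rnorm(n, 1, 0.5))     # stages per year
  dur <- runif(n, 1, 15)
  rows <- lapply(1:n, function(i) {
    t <- c(0, 2)
    stage <- 5 + rate[i] * t
    edss <- 2 + 0.03 * stage + rnorm(2, sd = 0.1)
    data.frame(subject_id = subj[i], visit_time_years = t, stage = stage,
               edss = edss, disease_duration_years = dur[i] + t)
  })
  d <- do.call(rbind, rows)
  d <- rbind(d, data.frame(subject_id = "SINGLE", visit_time_years = 0,
                           stage = 3, edss = 2, disease_duration_years = 1))
  expect_message(res <- annualized_change_regression(d), "excluded")
  est <- res$estimate[res$term == "annualized_stage_change"]
  se <- res$se[res$term == "annualized_stage_change"]
  expect_lt(abs(est - 0.03), 2 * se)
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("no stage progression makes the annualized regression
           ill-conditioned", {
  d <- make_stage_table(n_subjects = 30, seed = 5)
  d$stage <- ave(d$stage, d$subject_id, FUN = function(x) x[1])  # frozen
  d$edss <- rep(c(2, 2.5), length.out = nrow(d))
  d$disease_duration_years <- runif(nrow(d), 1, 10)
  expect_warning(annualized_change_regression(d), "ill-conditioned")
})

test_that("group trajectories separate when one group's baseline stage is
           shifted and not otherwise", {
  base <- make_stage_table(n_subjects = 120, seed = 6)
  base$phenotype <- rep(c("RRMS", "PPMS"), length.out = nrow(base))
  base$phenotype <- ave(base$phenotype, base$subject_id,
                        FUN = function(x) x[1])
  g0 <- suppressMessages(group_stage_summary(base, "phenotype"))
  ic <- g0$contrasts[g0$contrasts$quantity == "intercept", ]
  expect_gt(ic$p, 0.05)
  shifted <- base
  shifted$stage <- shifted$stage + 4 * (shifted$phenotype == "PPMS")
  g1 <- suppressMessages(group_stage_summary(shifted, "phenotype"))
  ic1 <- g1$contrasts[g1$contrasts$quantity == "intercept", ]
  expect_lt(ic1$p, 0.001)
  top <- g1$groups$group[which.max(g1$groups$intercept)]
  expect_equal(top, "PPMS")
  solo <- base[base$phenotype == "RRMS", ]
  expect_error(suppressWarnings(group_stage_summary(solo, "phenotype")),
               "two groups")
})

test_that("on balanced single-visit data the mixed model agrees with
           ordinary least squares", {
  d <- make_stage_table(n_subjects = 150, visits = 1, seed = 7)
  a <- suppressMessages(mixed_effect_association(d, "lesion_load_ml",
                                                 random_slope = FALSE))
  ols <- coef(lm(stage ~ lesion_load_ml, data = d))[["lesion_load_ml"]]
  expect_equal(a$estimate[a$term == "lesion_load_ml"], ols,
               tolerance = 0.02)
})
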