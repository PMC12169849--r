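make_calibration <- function(ids, reps = 60) {
  data.frame(subject_id = ids, rep1 = reps - 2, rep2 = reps, rep3 = reps,
             post_clicks = reps - 2)
}

test_that("exclusion rules fire in order on a constructed cohort", {
  n <- 21
  ids <- 1:n
  cov <- data.frame(subject_id = ids, catch_easy_failed = 0L,
                    catch_hard_failed = 0L)
  cov$catch_easy_failed[2] <- 1L   # fails one easy catch question
  cov$catch_hard_failed[3] <- 2L   # fails both hard catch questions
  cov$catch_hard_failed[4] <- 1L   # one hard failure alone is tolerated
  cal <- make_calibration(ids)
  cal[cal$subject_id == 5, c("rep2", "rep3")] <- 6   # capacity 6 < 7
  cal[cal$subject_id == 6, "rep1"] <- 0              # spread 60 >> 3 SD
  trials <- do.call(rbind, lapply(ids, function(i) {
    data.frame(subject_id = i, effort_level = rep(1:4, 4),
               reward = rep(2:5, each = 4),
               decision = if (i == 1) "reject" else
                 rep(c("accept", "reject"), 8))
  }))
  rep_ <- apply_exclusions(trials, cov, cal)
  expect_identical(rep_$excluded$all_reject, 1L)
  expect_setequal(rep_$excluded$catch_questions, c(2L, 3L))
  expect_identical(rep_$excluded$calibration_min7, 5L)
  expect_identical(rep_$excluded$calibration_spread_3sd, 6L)
  expect_setequal(rep_$survivors, setdiff(ids, c(1, 2, 3, 5, 6)))
  expect_identical(sum(rep_$rules$n_excluded), 5L)
  # idempotence: reapplying to the survivors excludes no one
  keep <- rep_$survivors
  rep2 <- apply_exclusions(trials[trials$subject_id %in% keep, ],
                           cov[cov$subject_id %in% keep, ],
                           cal[cal$subject_id %in% keep, ])
  expect_identical(sum(rep2$rules$n_excluded), 0L)
  # missing calibration flags rather than crashes
  rep3 <- apply_exclusions(trials, cov, cal[cal$subject_id != 7, ])
  expect_identical(rep3$flagged, 7L)
})

test_that("acceptance matrices count cells and mark unoffered cells missing", {
  trials <- data.frame(
    subject_id = 1,
    effort_level = c(1, 1, 2, 2, 3),
    reward = c(2, 2, 3, 3, 4),
    decision = c("accept", "reject", "accept", "accept", "reject")
  )
  am <- acceptance_matrix(trials)
  expect_equal(am$matrix["1", "2"], 0.5)
  expect_equal(am$matrix["2", "3"], 1)
  expect_equal(am$matrix["3", "4"], 0)
  expect_true(is.na(am$matrix["4", "5"]))
  expect_equal(am$overall, 3 / 5)
  allacc <- trials; allacc$decision <- "accept"
  expect_equal(acceptance_matrix(allacc)$overall, 1)
})

test_that("strong effort discounting yields significant main effects", {
  drawn <- draw_agents(40, seed = 40)
  trials <- simulate_cohort(drawn$agents, seed = 40)
  res <- effort_reward_test(trials)
  expect_lt(res$anova$p[res$anova$term == "effort"], 0.001)
  expect_lt(res$anova$p[res$anova$term == "reward"], 0.001)
  expect_identical(res$anova$df1, rep(1L, 3))
  expect_true(all(res$posthoc_effort$p < 0.01))
  expect_true(all(res$posthoc_reward$p < 0.05))
})

test_that("min-max standardization maps to [0, 1] exactly", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_standardize(c(0, 0.3, 1)), c(0, 0.3, 1))
  set.seed(41)
  x <- rnorm(50)
  z <- minmax_standardize(x)
  expect_equal(range(z), c(0, 1))
  expect_error(minmax_standardize(rep(3, 5)), "constant")
})

test_that("chronotype classification follows the conjunction rule", {
  expect_identical(classify_chronotype(60, 2.0), "early")
  expect_identical(classify_chronotype(41, 6.0), "late")
  expect_identical(classify_chronotype(60, 3.0), "intermediate")
  expect_identical(classify_chronotype(40, 5.0), "intermediate")
  expect_identical(classify_chronotype(50, 4.0), "intermediate")
  expect_error(classify_chronotype(90, 3), "range")
  # exhaustive partition over a grid of valid inputs
  grid <- expand.grid(meq = seq(16, 86, by = 2), ms = seq(0, 12, by = 0.5))
  cls <- classify_chronotype(grid$meq, grid$ms)
  expect_true(all(cls %in% c("early", "late", "intermediate")))
})

test_that("the stopping rule is boundary-inclusive and rejects empty monitors", {
  g <- data.frame(term = c("(Intercept)", "late", "inter"),
                  mean = c(0.5, -0.12, 0.1),
                  hdi_low = c(0.4, -0.22, 0.0),
                  hdi_high = c(0.6, -0.02, 0.30))
  g$credible <- g$hdi_low > 0 | g$hdi_high < 0
  class(g) <- c("bayes_glm", "data.frame")
  expect_true(stopping_rule_met(g, monitor = "late"))     # width exactly 0.20
  expect_false(stopping_rule_met(g, monitor = "inter"))   # width 0.30
  expect_false(stopping_rule_met(g))                      # all non-intercept
  expect_error(stopping_rule_met(g, monitor = character(0)), "empty")
})

test_that("bayesian_glm recovers a known slope with small bias", {
  set.seed(42)
  biases <- replicate(40, {
    x <- runif(500)
    y <- 0.5 - 0.2 * x + rnorm(500, 0, 0.05)
    g <- bayesian_glm(y, data.frame(x = x))
    g$mean[g$term == "x"] + 0.2
  })
  expect_lt(abs(mean(biases)), 0.02)
  # single run: posterior mean in range and HDI excludes zero
  set.seed(43)
  x <- runif(500); y <- 0.5 - 0.2 * x + rnorm(500, 0, 0.05)
  g <- bayesian_glm(y, data.frame(x = x))
  expect_gt(g$mean[g$term == "x"], -0.25)
  expect_lt(g$mean[g$term == "x"], -0.15)
  expect_true(g$credible[g$term == "x"])
  expect_error(bayesian_glm(y, data.frame(x = x, x2 = 2 * x)), "rank")
})

test_that("null-slope HDIs cover zero at the nominal rate", {
  set.seed(44)
  cover <- replicate(100, {
    x <- runif(200)
    y <- 0.5 + rnorm(200, 0, 0.05)
    g <- bayesian_glm(y, data.frame(x = x))
    !g$credible[g$term == "x"]
  })
  expect_gt(mean(cover), 0.88)
})

test_that("chronotype and synchrony effects carry the expected signs", {
  # enriched chronotype sample, as in a screening-based collection
  pop <- generate_population(population_config(n_subjects = 600, p_early = 0.3,
                                               p_late = 0.3, seed = 45))
  sel <- pop$truth$chronotype != "intermediate"
  d <- data.frame(late = as.integer(pop$truth$chronotype[sel] == "late"),
                  evening = as.integer(pop$covariates$window[sel] == "evening"))
  d$late_x_evening <- d$late * d$evening
  y <- minmax_standardize(pop$truth$alpha[sel])
  g <- bayesian_glm(y, d,
                    covariates = data.frame(
                      age = minmax_standardize(pop$covariates$age[sel]),
                      male = as.integer(pop$covariates$gender[sel] == "male")))
  expect_lt(g$mean[g$term == "late"], 0)
  expect_gt(g$mean[g$term == "late_x_evening"], 0)
  expect_true(g$credible[g$term == "late_x_evening"])
})

test_that("PLS recovers the psychiatric loading pattern and permutation power", {
  pop <- generate_population(population_config(n_subjects = 500,
                                               psych_effect = -1.0, seed = 46))
  X <- questionnaire_matrix(pop$covariates)
  y <- minmax_standardize(pop$truth$alpha)
  pl <- pls_link(X, y, n_perm = 199, seed = 1)
  expect_gte(pl$n_components, 1)
  # SHAPS/AES/DARS carry the largest-magnitude loadings, all negative
  psych <- abs(pl$loadings[c("shaps", "dars", "aes")])
  other <- abs(pl$loadings[c("meq", "mctq", "bmi", "findrisc")])
  expect_gt(min(psych), max(other))
  expect_true(all(pl$loadings[c("shaps", "dars", "aes")] < 0))
  expect_lte(pl$perm_p, 0.05)
  expect_error(pls_link(cbind(X, const = 1), y), "constant")
})

test_that("ICC is exact on identical inputs and near zero on independent ones", {
  set.seed(47)
  x <- rnorm(30)
  r <- icc_consistency(x, x)
  expect_equal(r$icc, 1)
  iccs <- replicate(60, icc_consistency(rnorm(30), rnorm(30))$icc)
  expect_lt(abs(mean(iccs)), 0.12)
  expect_gt(mean(abs(iccs) < 0.35), 0.9)
  expect_error(icc_consistency(rnorm(5), rnorm(6)), "unpaired")
})

test_that("cross-session prediction uses session-A parameters on session-B data", {
  pop <- generate_population(population_config(n_subjects = 12, seed = 48))
  trt <- generate_testretest(pop, seed = 48)
  res <- test_retest(trt$params_a, trt$params_b, trt$session_a, trt$session_b)
  expect_identical(nrow(res$prediction), 12L)
  # generative parameters predict held-out choices far better than chance
  expect_true(all(res$prediction$loglik_own > res$prediction$loglik_chance))
  expect_gt(mean(res$prediction$acc_own), 0.6)
  expect_lt(res$tests$own_vs_chance$p.value, 0.001)
  bad <- trt$params_b; bad$subject_id <- bad$subject_id + 100
  expect_error(test_retest(trt$params_a, bad), "different subjects")
})

test_that("control matching pairs by gender and nearest age", {
  cases <- data.frame(subject_id = 1:2, age = c(30, 50),
                      gender = c("female", "male"))
  controls <- data.frame(subject_id = 3:6, age = c(29, 45, 52, 31),
                         gender = c("female", "male", "male", "female"))
  m <- match_controls(cases, controls)
  expect_identical(m$control_id, c(3L, 5L))
})
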