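#' Model-agnostic analyses, covariate linkage, and reliability
#'
#' Exclusion filters, acceptance matrices, effort-by-reward tests,
#' questionnaire linkage through partial least squares and Bayesian GLMs,
#' chronotype phenotyping with a precision-based stopping rule, and
#' test-retest reliability of model parameters.
#'
#' @name analysis_stats
NULL

#' Apply compliance and task-based exclusions
#'
#' Rules are applied sequentially in a fixed, documented order, each to the
#' survivors of the previous rule: (1) neurological-condition or
#' language-proficiency flags when present in the covariates; (2) catch
#' questions (failing at least one easy question or both harder
#' questions); (3) rejecting every offer; (4) clicking calibration score
#' below seven; (5) within-calibration spread of click counts more than 3
#' cohort SDs above the cohort mean spread; (6) absolute pre-to-post
#' capacity change more than 3 cohort SDs from the cohort mean change.
#' Subjects with missing calibration records are flagged, not excluded.
#'
#' @param trials multi-subject trial data.frame (may be `NULL` to skip the
#'   all-reject rule)
#' @param covariates covariate table; optional columns
#'   `neurological_flag`, `language_flag`, `catch_easy_failed`,
#'   `catch_hard_failed`
#' @param calibration data.frame with `subject_id`, `rep1`, `rep2`,
#'   `rep3`, `post_clicks`
#' @return list of class `"exclusion_report"` with `rules` (per-rule
#'   counts), `survivors`, `excluded` (per-rule subject ids), `flagged`
#' @export
apply_exclusions <- function(trials, covariates, calibration) {
  ids <- covariates$subject_id
  flagged <- setdiff(ids, calibration$subject_id)
  alive <- ids
  rules <- list()
  drop <- function(rule, bad) {
    bad <- intersect(bad, alive)
    rules[[length(rules) + 1L]] <<- data.frame(rule = rule,
                                               n_excluded = length(bad))
    excluded[[rule]] <<- bad
    alive <<- setdiff(alive, bad)
  }
  excluded <- list()

  bad <- integer(0)
  if (!is.null(covariates$neurological_flag)) {
    bad <- c(bad, ids[covariates$neurological_flag %in% TRUE])
  }
  if (!is.null(covariates$language_flag)) {
    bad <- c(bad, ids[covariates$language_flag %in% TRUE])
  }
  drop("neurological_language", unique(bad))

  easy <- if (is.null(covariates$catch_easy_failed)) rep(0L, length(ids)) else covariates$catch_easy_failed
  hard <- if (is.null(covariates$catch_hard_failed)) rep(0L, length(ids)) else covariates$catch_hard_failed
  drop("catch_questions", ids[easy >= 1L | hard >= 2L])

  if (!is.null(trials)) {
    rej <- tapply(trials$decision == "reject", trials$subject_id, all)
    drop("all_reject", ids[as.character(ids) %in% names(rej)[which(rej)]])
  } else {
    drop("all_reject", integer(0))
  }

  cal <- calibration[match(alive, calibration$subject_id), ]
  cal <- cal[!is.na(cal$subject_id), ]
  capacity <- (cal$rep2 + cal$rep3) / 2
  drop("calibration_min7", cal$subject_id[capacity < 7])

  cal <- calibration[match(alive, calibration$subject_id), ]
  cal <- cal[!is.na(cal$subject_id), ]
  spread <- apply(cal[, c("rep1", "rep2", "rep3")], 1, function(x) max(x) - min(x))
  if (length(spread) > 1 && stats::sd(spread) > 0) {
    lim <- mean(spread) + 3 * stats::sd(spread)
    drop("calibration_spread_3sd", cal$subject_id[spread > lim])
  } else drop("calibration_spread_3sd", integer(0))

  cal <- calibration[match(alive, calibration$subject_id), ]
  cal <- cal[!is.na(cal$subject_id) & !is.na(cal$post_clicks), ]
  if (nrow(cal) > 1) {
    change <- cal$post_clicks - (cal$rep2 + cal$rep3) / 2
    if (stats::sd(change) > 0) {
      z <- abs(change - mean(change)) / stats::sd(change)
      drop("prepost_change_3sd", cal$subject_id[z > 3])
    } else drop("prepost_change_3sd", integer(0))
  } else drop("prepost_change_3sd", integer(0))

  structure(list(rules = do.call(rbind, rules), survivors = alive,
                 excluded = excluded, flagged = flagged),
            class = "exclusion_report")
}

#' Acceptance proportions over the effort-by-reward grid
#'
#' @param trials trial data.frame (one or many subjects)
#' @return list with `matrix` (4 x 4 acceptance proportions, effort in
#'   rows, reward in columns; cells never offered are `NA`) and `overall`
#' @export
acceptance_matrix <- function(trials) {
  acc <- trials$decision == "accept"
  m <- matrix(NA_real_, 4, 4,
              dimnames = list(effort = 1:4, reward = 2:5))
  for (e in 1:4) for (r in 2:5) {
    sel <- trials$effort_level == e & trials$reward == r
    if (any(sel)) m[e, r - 1L] <- mean(acc[sel])
  }
  list(matrix = m, overall = mean(acc))
}

#' Effort and reward effects on acceptance
#'
#' Acceptance proportions are computed per subject and offered
#' effort-by-reward cell (the staircase design leaves the cell grid
#' unbalanced; cells a subject never saw contribute no row).  A linear
#' model with numeric effort, numeric reward and their product is fit to
#' the subject-by-cell proportions and each single-degree-of-freedom term
#' is F-tested.  Post-hoc tests fit the effort slope within each reward
#' level and the reward slope within each effort level.
#'
#' @param trials multi-subject trial data.frame
#' @return list of class `"effort_reward_test"` with `anova` (term, F,
#'   df1, df2, p), `posthoc_effort` (per reward level), `posthoc_reward`
#'   (per effort level), and `cells` (the proportions table)
#' @export
effort_reward_test <- function(trials) {
  if (length(unique(trials$subject_id)) < 2L) stop("at least two subjects required")
  cells <- stats::aggregate(list(prop = trials$decision == "accept"),
                            list(subject_id = trials$subject_id,
                                 effort = trials$effort_level,
                                 reward = trials$reward), mean)
  if (nrow(cells) < 5L) stop("insufficient cells for the model")
  fit <- stats::lm(prop ~ effort * reward, data = cells)
  an <- stats::anova(fit)
  terms <- c("effort", "reward", "effort:reward")
  res <- data.frame(term = terms,
                    F = an[terms, "F value"],
                    df1 = an[terms, "Df"],
                    df2 = an["Residuals", "Df"],
                    p = an[terms, "Pr(>F)"])
  ph_e <- do.call(rbind, lapply(sort(unique(cells$reward)), function(r) {
    sub <- cells[cells$reward == r, ]
    f <- stats::lm(prop ~ effort, data = sub)
    p <- stats::anova(f)["effort", "Pr(>F)"]
    data.frame(reward = r, p = p)
  }))
  ph_r <- do.call(rbind, lapply(sort(unique(cells$effort)), function(e) {
    sub <- cells[cells$effort == e, ]
    f <- stats::lm(prop ~ reward, data = sub)
    p <- stats::anova(f)["reward", "Pr(>F)"]
    data.frame(effort = e, p = p)
  }))
  structure(list(anova = res, posthoc_effort = ph_e, posthoc_reward = ph_r,
                 cells = cells),
            class = "effort_reward_test")
}

#' Min-max standardization to [0, 1]
#'
#' @param x numeric vector with at least two distinct values
#' @return `(x - min) / (max - min)`
#' @export
minmax_standardize <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (diff(rng) == 0) stop("cannot min-max standardize a constant vector")
  (x - rng[1]) / diff(rng)
}

#' Partial least squares linkage of questionnaires to a model parameter
#'
#' Questionnaire predictors are related to a parameter vector by PLS
#' regression.  Data are split into 75% training / 25% testing; the number
#' of components (an intercept-only model is a candidate and may win) is
#' chosen by 10-fold cross-validated RMSE on the training split; the
#' winning model's RMSE is evaluated out-of-sample on the held-out
#' testing data; its significance is a permutation p-value (proportion of
#' label-permuted out-of-sample RMSEs at least as good as the observed
#' one, with a floor of 1/(n_perm + 1)).
#'
#' @param X numeric predictor matrix (subjects x questionnaires), already
#'   standardized and direction-aligned
#' @param y parameter vector
#' @param max_components maximum number of PLS components considered
#' @param folds CV folds on the training split
#' @param n_perm number of permutations
#' @param train_frac training fraction
#' @param seed seed governing split, folds, and permutations
#' @return list of class `"pls_result"`: `n_components`, `loadings`
#'   (first-component predictor loadings), `test_rmse`, `perm_p`,
#'   `cv_rmse` (per candidate), `train_ids`, `test_ids`
#' @export
pls_link <- function(X, y, max_components = 3, folds = 10, n_perm = 1000,
                     train_frac = 0.75, seed = 1) {
  X <- as.matrix(X)
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor column")
  n <- nrow(X)
  if (n < 20L) stop("too few subjects for a train/test split")
  set.seed(seed)
  train <- sort(sample.int(n, round(train_frac * n)))
  test <- setdiff(seq_len(n), train)

  rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
  fit_predict <- function(xtr, ytr, xte, ncomp) {
    if (ncomp == 0L) return(rep(mean(ytr), nrow(xte)))
    fit <- mixOmics::pls(xtr, ytr, ncomp = ncomp, mode = "regression")
    pred <- stats::predict(fit, xte)
    pred$predict[, 1, ncomp]
  }

  fold_id <- sample(rep_len(seq_len(folds), length(train)))
  candidates <- 0:max_components
  cv_rmse <- vapply(candidates, function(nc) {
    errs <- vapply(seq_len(folds), function(k) {
      tr <- train[fold_id != k]; ho <- train[fold_id == k]
      rmse(y[ho], fit_predict(X[tr, , drop = FALSE], y[tr],
                              X[ho, , drop = FALSE], nc))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  names(cv_rmse) <- paste0("ncomp", candidates)
  ncomp <- candidates[which.min(cv_rmse)]

  test_rmse <- rmse(y[test], fit_predict(X[train, , drop = FALSE], y[train],
                                         X[test, , drop = FALSE], ncomp))
  # loadings always reported from the first component (fit with >= 1)
  lfit <- mixOmics::pls(X[train, , drop = FALSE], y[train],
                        ncomp = max(1L, ncomp), mode = "regression")
  loadings <- lfit$loadings$X[, 1]

  perm_rmse <- vapply(seq_len(n_perm), function(i) {
    yp <- y[sample.int(n)]
    rmse(yp[test], fit_predict(X[train, , drop = FALSE], yp[train],
                               X[test, , drop = FALSE], ncomp))
  }, numeric(1))
  perm_p <- max(1, sum(perm_rmse <= test_rmse)) / (n_perm + 1)

  structure(list(n_components = ncomp, loadings = loadings,
                 test_rmse = test_rmse, perm_p = perm_p, cv_rmse = cv_rmse,
                 train_ids = train, test_ids = test),
            class = "pls_result")
}

#' Bayesian Gaussian GLM with conjugate priors
#'
#' Linear Gaussian model with a weakly-informative conjugate
#' normal--inverse-gamma prior (coefficients Normal(0, `prior_scale`^2)
#' given the residual variance; variance InvGamma(0.01, 0.01)), yielding
#' exact Student-t coefficient marginals.  Reports posterior means and 95%
#' highest density intervals, and flags coefficients whose HDI excludes
#' zero.
#'
#' @param y response vector (conventionally min-max standardized)
#' @param predictors data.frame of predictors of interest
#' @param covariates optional data.frame of adjustment covariates
#'   (conventionally age and gender)
#' @param prior_scale prior SD of the coefficients relative to the
#'   residual SD
#' @param level HDI probability
#' @return data.frame of class `"bayes_glm"`: `term`, `mean`, `hdi_low`,
#'   `hdi_high`, `credible`
#' @export
bayesian_glm <- function(y, predictors, covariates = NULL, prior_scale = 10,
                         level = 0.95) {
  Xd <- as.data.frame(predictors)
  if (!is.null(covariates)) Xd <- cbind(Xd, as.data.frame(covariates))
  mm <- stats::model.matrix(~ ., data = Xd)
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design matrix")
  n <- length(y); p <- ncol(mm)
  V0inv <- diag(1 / prior_scale^2, p)
  a0 <- 0.01; b0 <- 0.01
  XtX <- crossprod(mm)
  Vn <- solve(V0inv + XtX)
  mn <- Vn %*% crossprod(mm, y)
  an <- a0 + n / 2
  bn <- as.numeric(b0 + 0.5 * (sum(y^2) - t(mn) %*% (V0inv + XtX) %*% mn))
  scale <- sqrt(bn / an * diag(Vn))
  tcrit <- stats::qt(1 - (1 - level) / 2, df = 2 * an)
  res <- data.frame(
    term = colnames(mm),
    mean = as.numeric(mn),
    hdi_low = as.numeric(mn) - tcrit * scale,
    hdi_high = as.numeric(mn) + tcrit * scale
  )
  res$credible <- res$hdi_low > 0 | res$hdi_high < 0
  class(res) <- c("bayes_glm", "data.frame")
  res
}

#' Classify chronotype from MEQ score and free-day mid-sleep
#'
#' Early chronotype requires MEQ sum > 58 and mid-sleep on free days
#' before 02:30; late chronotype requires MEQ sum < 42 and mid-sleep after
#' 05:30; everything else is intermediate.
#'
#' @param meq_sum MEQ sum score(s), valid range 16--86
#' @param midsleep_free mid-sleep on free days as decimal clock hours
#'   (e.g. 03:30 = 3.5)
#' @return character vector in `c("early", "late", "intermediate")`
#' @export
classify_chronotype <- function(meq_sum, midsleep_free) {
  if (any(meq_sum < 16 | meq_sum > 86)) stop("MEQ sum out of range 16..86")
  ifelse(meq_sum > 58 & midsleep_free < 2.5, "early",
         ifelse(meq_sum < 42 & midsleep_free > 5.5, "late", "intermediate"))
}

#' Precision-based stopping rule
#'
#' True when every monitored 95% HDI has width at most `width_target`
#' (boundary inclusive).
#'
#' @param glm a [bayesian_glm()] result
#' @param width_target maximum acceptable HDI width
#' @param monitor character vector of terms to monitor; defaults to all
#'   non-intercept terms
#' @return logical
#' @export
stopping_rule_met <- function(glm, width_target = 0.20, monitor = NULL) {
  if (is.null(monitor)) monitor <- setdiff(glm$term, "(Intercept)")
  if (length(monitor) == 0L) stop("empty set of monitored terms")
  rows <- glm[glm$term %in% monitor, ]
  if (nrow(rows) != length(monitor)) stop("monitored term not in the GLM")
  all(rows$hdi_high - rows$hdi_low <= width_target + 1e-12)
}

#' Intraclass correlation ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measure ICC for paired
#' measurements, with its F-test p-value.
#'
#' @param a,b paired numeric vectors (session A and B)
#' @return list with `icc` and `p`
#' @export
icc_consistency <- function(a, b) {
  if (length(a) != length(b)) stop("unpaired inputs")
  n <- length(a); k <- 2
  m <- cbind(a, b)
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  fstat <- msr / mse
  p <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = p)
}

#' Test-retest reliability of model parameters
#'
#' ICC(3,1) per parameter across the two sessions (the sensitivities are
#' assessed on the log scale, the scale on which they are modelled as
#' Normal) and, when sessions are supplied, cross-session predictive
#' accuracy: session-A parameter
#' estimates score session-B choices (summed log-likelihood and
#' proportion of correctly predicted decisions), compared against chance
#' (p = 0.5 per trial) and against prediction from the group-mean
#' parameters via paired t-tests.
#'
#' @param params_a,params_b per-subject parameter tables with columns
#'   `subject_id`, `alpha`, `beta_R`, `beta_E`
#' @param session_a,session_b optional paired trial data.frames
#' @param group_params optional named vector `c(alpha=, beta_R=, beta_E=)`
#'   used for the group-level comparison; defaults to the session-A means
#' @param model model name for choice scoring
#' @return list of class `"reliability_result"` with `icc` (per-parameter
#'   ICC and p), and if sessions were given `prediction` (per-subject
#'   log-likelihood and accuracy under own/group/chance parameters) and
#'   `tests` (paired comparisons)
#' @export
test_retest <- function(params_a, params_b, session_a = NULL,
                        session_b = NULL, group_params = NULL,
                        model = "full_parabolic") {
  if (!identical(sort(params_a$subject_id), sort(params_b$subject_id))) {
    stop("sessions contain different subjects")
  }
  pb <- params_b[match(params_a$subject_id, params_b$subject_id), ]
  # sensitivities are modelled Normal on the log scale; ICC (which assumes
  # normality) is computed there, alpha on its natural scale
  icc <- lapply(c("alpha", "beta_R", "beta_E"), function(pn) {
    tf <- if (pn == "alpha") identity else log
    r <- icc_consistency(tf(params_a[[pn]]), tf(pb[[pn]]))
    data.frame(parameter = pn, icc = r$icc, p = r$p)
  })
  icc <- do.call(rbind, icc)
  out <- list(icc = icc)

  if (!is.null(session_a) && !is.null(session_b)) {
    if (is.null(group_params)) {
      group_params <- c(alpha = mean(params_a$alpha),
                        beta_R = mean(params_a$beta_R),
                        beta_E = mean(params_a$beta_E))
    }
    score <- function(trials, alpha, beta_R, beta_E) {
      ll <- trial_loglik(trials, alpha, beta_R, beta_E, model)
      spec <- model_spec(model)
      par <- .effective_params(alpha, beta_R, beta_E, spec)
      std <- standardize_offer(trials$effort_level, trials$reward)
      p <- acceptance_probability(
        subjective_value(std$e, std$r, par$beta_R, par$beta_E, spec$cost),
        par$alpha)
      pred <- ifelse(p > 0.5, "accept", "reject")
      c(loglik = sum(ll), accuracy = mean(pred == trials$decision))
    }
    rows <- lapply(seq_len(nrow(params_a)), function(i) {
      sid <- params_a$subject_id[i]
      tb <- session_b[session_b$subject_id == sid, ]
      own <- score(tb, params_a$alpha[i], params_a$beta_R[i],
                   params_a$beta_E[i])
      grp <- score(tb, group_params["alpha"], group_params["beta_R"],
                   group_params["beta_E"])
      data.frame(subject_id = sid, n_trials = nrow(tb),
                 loglik_own = own["loglik"], acc_own = own["accuracy"],
                 loglik_group = grp["loglik"], acc_group = grp["accuracy"],
                 loglik_chance = nrow(tb) * log(0.5), row.names = NULL)
    })
    pred <- do.call(rbind, rows)
    tests <- list(
      own_vs_chance = stats::t.test(pred$loglik_own, pred$loglik_chance,
                                    paired = TRUE, alternative = "greater"),
      own_vs_group = stats::t.test(pred$loglik_own, pred$loglik_group,
                                   paired = TRUE, alternative = "greater"),
      accuracy_vs_chance = stats::t.test(pred$acc_own, mu = 0.5,
                                         alternative = "greater")
    )
    out$prediction <- pred
    out$tests <- tests
  }
  class(out) <- "reliability_result"
  out
}

#' Match controls to cases by gender and nearest age
#'
#' Small utility for diagnostic-group contrasts: for each case, picks the
#' unused control with the same gender and smallest age difference.
#'
#' @param cases,controls data.frames with `subject_id`, `age`, `gender`
#' @return data.frame pairing `case_id` with `control_id`
#' @export
match_controls <- function(cases, controls) {
  pool <- controls
  pairs <- lapply(seq_len(nrow(cases)), function(i) {
    cand <- pool[pool$gender == cases$gender[i], ]
    if (nrow(cand) == 0L) return(NULL)
    j <- cand$subject_id[which.min(abs(cand$age - cases$age[i]))]
    pool <<- pool[pool$subject_id != j, ]
    data.frame(case_id = cases$subject_id[i], control_id = j)
  })
  do.call(rbind, pairs)
}
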