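#' Hierarchical Bayesian inference for the subjective-value models
#'
#' Any model in the nine-model registry can be fit to multi-subject trial
#' data with a hierarchical (partial-pooling) structure: subject-level
#' acceptance bias is Normal around a group mean, and the positive
#' sensitivities are log-Normal around group means on the log scale.
#' Sampling is delegated to JAGS; the likelihood is exactly the per-trial
#' Bernoulli likelihood implemented in [trial_loglik()].  Group means have
#' Normal(0, 1) priors; group SDs have, by default, a conjugate
#' Gamma(2, 0.5) prior on the group precision (weakly informative on the
#' SD scale and efficiently Gibbs-sampled), with a half-Normal(0, 1) SD
#' prior available as an alternative.
#'
#' @name inference
NULL

#' MCMC configuration
#'
#' Defaults follow the task's fitting protocol (2000 warm-up and 6000
#' sampling iterations on four chains); smaller settings are appropriate
#' for desk-scale simulation studies.
#'
#' @param warmup warm-up (adaptation + burn-in) iterations
#' @param sampling sampling iterations per chain
#' @param chains number of chains
#' @param thin thinning interval applied to the sampling iterations
#' @param seed integer seed controlling chain initialization
#' @return list of class `"mcmc_config"`
#' @export
mcmc_config <- function(warmup = 2000, sampling = 6000, chains = 4,
                        thin = 1, seed = 1) {
  stopifnot(warmup > 0, sampling > 0, chains > 0, thin > 0)
  structure(list(warmup = as.integer(warmup), sampling = as.integer(sampling),
                 chains = as.integer(chains), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# JAGS model source for a given parameter configuration.  The cost function
# enters through the data (ce = cost-transformed standardized effort), so a
# single template per configuration covers all three cost kinds.  The
# group-SD prior is either a conjugate Gamma(2, 0.5) on the precision
# (default; Gibbs updates) or a half-Normal(0, 1) on the SD.
.sd_prior_lines <- function(stub, sd_prior) {
  if (sd_prior == "gamma") {
    paste0("tau_", stub, " ~ dgamma(2, 0.5)\n  sig_", stub,
           " <- pow(tau_", stub, ", -0.5)")
  } else {
    paste0("sig_", stub, " ~ dnorm(0, 1) T(0,)\n  tau_", stub,
           " <- pow(sig_", stub, ", -2)")
  }
}

.jags_source <- function(free_alpha, free_beta_R, sd_prior = "gamma") {
  alpha_group <- if (free_alpha) paste0("
  mu_a ~ dnorm(0, 1)
  ", .sd_prior_lines("a", sd_prior)) else ""
  alpha_subj <- if (free_alpha) "alpha[s] ~ dnorm(mu_a, tau_a)"
                else "alpha[s] <- 0"
  br_group <- if (free_beta_R) paste0("
  mu_br ~ dnorm(0, 1)
  ", .sd_prior_lines("br", sd_prior)) else ""
  br_subj <- if (free_beta_R) "lbr[s] ~ dnorm(mu_br, tau_br)\n    bR[s] <- exp(lbr[s])"
             else "bR[s] <- 1"
  paste0("model {", alpha_group, br_group, "
  mu_be ~ dnorm(0, 1)
  ", .sd_prior_lines("be", sd_prior), "
  for (s in 1:S) {
    ", alpha_subj, "
    ", br_subj, "
    lbe[s] ~ dnorm(mu_be, tau_be)
    bE[s] <- exp(lbe[s])
  }
  for (n in 1:N) {
    logit(p[n]) <- alpha[subj[n]] + bR[subj[n]] * r[n] - bE[subj[n]] * ce[n]
    y[n] ~ dbern(p[n])
  }
}")
}

# Lightweight order-independent fingerprint used to verify that fits being
# compared were computed on the same data.
.data_fingerprint <- function(y, subj, e, r) {
  c(n = length(y), n_subj = length(unique(subj)), y_sum = sum(y),
    chk = sum((y + 1) * (subj + 2) * (e * 7 + r * 13)))
}

#' Split R-hat convergence diagnostic
#'
#' Each chain is split in half and the potential scale reduction factor is
#' computed over the resulting half-chains.
#'
#' @param draws iterations x chains numeric matrix for one estimand
#' @return split R-hat (>= 1; values near 1 indicate convergence)
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  pieces <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[1:half, j], draws[(n - half + 1):n, j])
  }))
  m <- ncol(pieces); len <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- len * stats::var(means)
  if (W == 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

#' Highest density interval from samples
#'
#' Shortest interval containing `prob` of the draws.
#'
#' @param x numeric samples
#' @param prob coverage probability
#' @return numeric vector `c(lower, upper)`
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

.summarize_param <- function(draws) {
  h <- hdi(draws)
  c(mean = mean(draws), sd = stats::sd(draws), hdi_low = h[1], hdi_high = h[2])
}

#' Fit a subjective-value model hierarchically
#'
#' @param trials multi-subject trial data.frame (columns `subject_id`,
#'   `effort_level`, `reward`, `decision`)
#' @param model model name from [model_registry()]
#' @param config an [mcmc_config()]
#' @param max_loglik_draws cap on the number of posterior draws retained in
#'   the pointwise log-likelihood matrix used for LOO
#' @param sd_prior group-SD prior family: `"gamma"` (conjugate
#'   Gamma(2, 0.5) on the precision, default) or `"halfnormal"`
#'   (half-Normal(0, 1) on the SD)
#' @param quiet suppress JAGS progress output
#' @return object of class `"effort_fit"`: posterior draw matrices for the
#'   subject-level parameters (natural scale), group-level summaries,
#'   per-subject posterior summaries, split R-hat and effective sample size
#'   per estimand, and a pointwise log-likelihood matrix (draws x trials)
#' @export
fit_hierarchical <- function(trials, model = "full_parabolic",
                             config = mcmc_config(), max_loglik_draws = 2000,
                             sd_prior = c("gamma", "halfnormal"),
                             quiet = TRUE) {
  sd_prior <- match.arg(sd_prior)
  spec <- model_spec(model)
  subjects <- sort(unique(trials$subject_id))
  if (length(subjects) < 2L) stop("at least two subjects required")
  if (!all(trials$decision %in% c("accept", "reject"))) {
    stop("decisions must be 'accept' or 'reject'")
  }
  y <- as.integer(trials$decision == "accept")
  if (all(y == 1L) || all(y == 0L)) {
    stop("degenerate data: every decision is identical across all subjects; ",
         "the hierarchical model is not identified")
  }
  subj <- match(trials$subject_id, subjects)
  std <- standardize_offer(trials$effort_level, trials$reward)
  ce <- effort_cost(std$e, 1, spec$cost)

  dat <- list(S = length(subjects), N = length(y), subj = subj,
              r = std$r, ce = ce, y = y)
  monitors <- c("bE", "mu_be", "sig_be")
  if (spec$free_alpha) monitors <- c(monitors, "alpha", "mu_a", "sig_a")
  if (spec$free_beta_R) monitors <- c(monitors, "bR", "mu_br", "sig_br")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  chain_seeds <- sample.int(1e6, config$chains)
  inits <- lapply(chain_seeds, function(s) {
    list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = s)
  })
  jm <- rjags::jags.model(textConnection(.jags_source(spec$free_alpha,
                                                      spec$free_beta_R,
                                                      sd_prior)),
                          data = dat, inits = inits, n.chains = config$chains,
                          n.adapt = ceiling(config$warmup / 2), quiet = quiet)
  upd <- function() stats::update(jm, floor(config$warmup / 2),
                                  progress.bar = "none")
  upd()
  samp <- rjags::coda.samples(jm, monitors, n.iter = config$sampling,
                              thin = config$thin, progress.bar = "none")
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  vn <- coda::varnames(samp)
  draws_by_chain <- lapply(samp, as.matrix)
  all_draws <- do.call(rbind, draws_by_chain)

  rhat <- vapply(vn, function(v) {
    split_rhat(do.call(cbind, lapply(draws_by_chain, function(m) m[, v])))
  }, numeric(1))
  ess <- coda::effectiveSize(samp)
  converged <- all(rhat <= 1.05, na.rm = TRUE)
  if (!converged) {
    warning("fit did not converge: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3))
  }

  S <- length(subjects)
  pull <- function(stub) all_draws[, paste0(stub, "[", seq_len(S), "]"), drop = FALSE]
  n_draws <- nrow(all_draws)
  alpha_d <- if (spec$free_alpha) pull("alpha") else matrix(0, n_draws, S)
  bR_d <- if (spec$free_beta_R) pull("bR") else matrix(1, n_draws, S)
  bE_d <- pull("bE")

  subject_params <- do.call(rbind, lapply(seq_len(S), function(s) {
    rows <- list(alpha = alpha_d[, s], beta_R = bR_d[, s], beta_E = bE_d[, s])
    keep <- c(spec$free_alpha, spec$free_beta_R, TRUE)
    do.call(rbind, lapply(which(keep), function(k) {
      sm <- .summarize_param(rows[[k]])
      data.frame(subject_id = subjects[s], parameter = names(rows)[k],
                 mean = sm["mean"], sd = sm["sd"], hdi_low = sm["hdi_low"],
                 hdi_high = sm["hdi_high"], row.names = NULL)
    }))
  }))

  group_nodes <- setdiff(vn, c(paste0("alpha[", 1:S, "]"),
                               paste0("bR[", 1:S, "]"),
                               paste0("bE[", 1:S, "]")))
  group_params <- do.call(rbind, lapply(group_nodes, function(g) {
    sm <- .summarize_param(all_draws[, g])
    data.frame(parameter = g, mean = sm["mean"], sd = sm["sd"],
               hdi_low = sm["hdi_low"], hdi_high = sm["hdi_high"],
               row.names = NULL)
  }))

  keep <- if (n_draws > max_loglik_draws) {
    round(seq(1, n_draws, length.out = max_loglik_draws))
  } else seq_len(n_draws)
  x <- alpha_d[keep, subj, drop = FALSE] +
    bR_d[keep, subj, drop = FALSE] * matrix(std$r, length(keep), length(y), byrow = TRUE) -
    bE_d[keep, subj, drop = FALSE] * matrix(ce, length(keep), length(y), byrow = TRUE)
  sign <- matrix(ifelse(y == 1L, 1, -1), length(keep), length(y), byrow = TRUE)
  loglik <- stats::plogis(sign * x, log.p = TRUE)

  structure(list(
    model = spec, subjects = subjects, trials_per_subject = table(subj),
    draws = list(alpha = alpha_d, beta_R = bR_d, beta_E = bE_d),
    subject_params = subject_params, group_params = group_params,
    diagnostics = list(rhat = rhat, ess = ess, converged = converged,
                       max_rhat = max(rhat, na.rm = TRUE),
                       min_ess = min(ess)),
    loglik = loglik,
    data_info = .data_fingerprint(y, subj, trials$effort_level, trials$reward),
    config = config
  ), class = "effort_fit")
}

#' @export
print.effort_fit <- function(x, ...) {
  cat("Hierarchical fit of", x$model$name, "\n")
  cat("  subjects:", length(x$subjects),
      " trials:", x$data_info[["n"]], "\n")
  cat("  max split R-hat:", round(x$diagnostics$max_rhat, 4),
      " min ESS:", round(x$diagnostics$min_ess), "\n")
  invisible(x)
}

# Generalized Pareto fit to tail exceedances (profile-likelihood estimator
# of Zhang & Stephens 2009).  Returns shape k and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(t) -mean(log1p(-t * x)), numeric(1))
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  c(k = k, sigma = sigma)
}

.gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * -expm1(log1p(-p) * k) / k
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Computes the expected log pointwise predictive density (ELPD) from a
#' matrix of pointwise log-likelihood posterior draws.  Raw importance
#' ratios for each held-out point are stabilized by replacing the largest
#' 20% with quantiles of a generalized Pareto distribution fit to that
#' tail; the fitted shape parameter `khat` diagnoses reliability (values
#' above 0.7 are flagged).  With a single posterior draw the estimate
#' reduces exactly to the sum of pointwise log-likelihoods.
#'
#' @param loglik draws x observations matrix of log-likelihood values
#' @return list with `elpd_loo`, `se`, `looic` (= -2 elpd), `pointwise`,
#'   and `khat`
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  ndraw <- nrow(loglik); nobs <- ncol(loglik)
  if (ndraw == 1L) {
    pointwise <- as.numeric(loglik)
    elpd <- sum(pointwise)
    return(list(elpd_loo = elpd, se = sqrt(nobs * stats::var(pointwise)),
                looic = -2 * elpd, pointwise = pointwise,
                khat = rep(NA_real_, nobs)))
  }
  pointwise <- numeric(nobs)
  khat <- rep(NA_real_, nobs)
  tail_len <- ceiling(min(0.2 * ndraw, 3 * sqrt(ndraw)))
  for (i in seq_len(nobs)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    if (tail_len >= 5) {
      ord <- order(lw)
      tail_idx <- ord[(ndraw - tail_len + 1):ndraw]
      cutoff <- lw[ord[ndraw - tail_len]]
      exceed <- exp(lw[tail_idx]) - exp(cutoff)
      if (stats::sd(exceed) > 0) {
        fit <- .gpd_fit(exceed)
        khat[i] <- fit["k"]
        probs <- (seq_len(tail_len) - 0.5) / tail_len
        smoothed <- log(.gpd_quantile(probs, fit["k"], fit["sigma"]) +
                          exp(cutoff))
        lw[tail_idx[order(lw[tail_idx])]] <- pmin(smoothed, 0)
      }
    }
    pointwise[i] <- .logsumexp(lw + ll) - .logsumexp(lw)
  }
  elpd <- sum(pointwise)
  if (any(khat > 0.7, na.rm = TRUE)) {
    warning(sum(khat > 0.7, na.rm = TRUE),
            " observation(s) with Pareto khat > 0.7; ",
            "their LOO contributions may be unstable")
  }
  list(elpd_loo = elpd, se = sqrt(nobs * stats::var(pointwise)),
       looic = -2 * elpd, pointwise = pointwise, khat = khat)
}

#' Compare fitted models by PSIS-LOO
#'
#' @param fits named list of [fit_hierarchical()] fits of different models
#'   to the same data
#' @return data.frame of class `"loo_comparison"` sorted by ELPD (best
#'   first) with columns `model`, `elpd`, `se`, `looic`, `rank`,
#'   `elpd_diff` (difference to the best model) and `se_diff` (paired
#'   pointwise SE of that difference)
#' @export
loo_compare <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$name, character(1))
  }
  fps <- lapply(fits, function(f) f$data_info)
  if (length(unique(vapply(fps, paste, character(1), collapse = "|"))) != 1L) {
    stop("fits were not computed on identical data")
  }
  loos <- lapply(fits, function(f) psis_loo(f$loglik))
  res <- data.frame(
    model = names(fits),
    elpd = vapply(loos, `[[`, numeric(1), "elpd_loo"),
    se = vapply(loos, `[[`, numeric(1), "se"),
    looic = vapply(loos, `[[`, numeric(1), "looic"),
    row.names = NULL
  )
  res <- res[order(-res$elpd), ]
  res$rank <- seq_len(nrow(res))
  # paired SE of the ELPD difference to the best model (pointwise)
  best_pw <- loos[[res$model[1]]]$pointwise
  res$elpd_diff <- res$elpd - res$elpd[1]
  res$se_diff <- vapply(res$model, function(m) {
    d <- best_pw - loos[[m]]$pointwise
    if (all(d == 0)) 0 else sqrt(length(d) * stats::var(d))
  }, numeric(1))
  class(res) <- c("loo_comparison", "data.frame")
  res
}

#' Posterior predictive check
#'
#' For a thinned subset of posterior draws, decisions are re-simulated for
#' every trial; predicted per-subject acceptance proportions by effort
#' level and by reward level are compared with the observed proportions.
#' The check statistic is the squared Pearson correlation between observed
#' and predicted subject-by-level proportions on each marginal.
#'
#' @param fit an `"effort_fit"`
#' @param trials the data the fit was computed on
#' @param ndraws number of thinned posterior draws to simulate from
#' @param seed seed for the simulation draws
#' @return list of class `"ppc_result"` with `by_effort`, `by_reward`
#'   (data.frames of observed/predicted proportions) and `r2` (named
#'   vector for the two marginals)
#' @export
posterior_predictive <- function(fit, trials, ndraws = 500, seed = 1) {
  set.seed(seed)
  subjects <- fit$subjects
  subj <- match(trials$subject_id, subjects)
  std <- standardize_offer(trials$effort_level, trials$reward)
  ce <- effort_cost(std$e, 1, fit$model$cost)
  total <- nrow(fit$draws$beta_E)
  keep <- if (total > ndraws) round(seq(1, total, length.out = ndraws)) else seq_len(total)
  n <- nrow(trials)
  p <- stats::plogis(
    fit$draws$alpha[keep, subj, drop = FALSE] +
      fit$draws$beta_R[keep, subj, drop = FALSE] * matrix(std$r, length(keep), n, byrow = TRUE) -
      fit$draws$beta_E[keep, subj, drop = FALSE] * matrix(ce, length(keep), n, byrow = TRUE)
  )
  yrep <- matrix(stats::runif(length(p)), nrow(p)) < p
  pred_trial <- colMeans(yrep)
  obs <- as.integer(trials$decision == "accept")

  marginal <- function(level) {
    agg_o <- stats::aggregate(obs, list(subject_id = trials$subject_id,
                                        level = level), mean)
    agg_p <- stats::aggregate(pred_trial, list(subject_id = trials$subject_id,
                                               level = level), mean)
    data.frame(subject_id = agg_o$subject_id, level = agg_o$level,
               observed = agg_o$x, predicted = agg_p$x)
  }
  by_effort <- marginal(trials$effort_level)
  by_reward <- marginal(trials$reward)
  r2 <- c(effort = stats::cor(by_effort$observed, by_effort$predicted)^2,
          reward = stats::cor(by_reward$observed, by_reward$predicted)^2)
  structure(list(by_effort = by_effort, by_reward = by_reward, r2 = r2),
            class = "ppc_result")
}

#' Parameter recovery study
#'
#' Simulates a population of agents from known generating distributions,
#' runs full sessions, refits the model hierarchically, and compares the
#' per-subject posterior means with the generating values on the natural
#' scale.
#'
#' @param model model name (used both to generate and to fit)
#' @param n_subjects number of simulated agents
#' @param generating list with `alpha = c(mean, sd)`,
#'   `log_beta_R = c(mean, sd)`, `log_beta_E = c(mean, sd)` (normal
#'   distributions; sensitivities on the log scale)
#' @param config an [mcmc_config()]
#' @param seed simulation seed
#' @return list of class `"recovery_result"`: per free parameter the
#'   generating values, recovered posterior means, Pearson correlation,
#'   bias (mean recovered - generated), and RMSE; the simulated `trials`
#'   and the underlying `fit` are included
#' @export
parameter_recovery <- function(model = "full_parabolic", n_subjects = 100,
                               generating = list(alpha = c(1.2, 0.9),
                                                 log_beta_R = c(log(2), 0.4),
                                                 log_beta_E = c(log(2.5), 0.4)),
                               config = mcmc_config(), seed = 1) {
  set.seed(seed)
  spec <- model_spec(model)
  truth <- data.frame(
    subject_id = seq_len(n_subjects),
    alpha = stats::rnorm(n_subjects, generating$alpha[1], generating$alpha[2]),
    beta_R = exp(stats::rnorm(n_subjects, generating$log_beta_R[1],
                              generating$log_beta_R[2])),
    beta_E = exp(stats::rnorm(n_subjects, generating$log_beta_E[1],
                              generating$log_beta_E[2]))
  )
  agents <- lapply(seq_len(n_subjects), function(i) {
    make_agent(truth$alpha[i], truth$beta_R[i], truth$beta_E[i],
               subject_id = i)
  })
  trials <- simulate_cohort(agents, model = model)
  fit <- fit_hierarchical(trials, model = model, config = config)
  free <- c(alpha = spec$free_alpha, beta_R = spec$free_beta_R, beta_E = TRUE)
  per_param <- lapply(names(free)[free], function(pn) {
    sp <- fit$subject_params
    rec <- sp$mean[sp$parameter == pn][match(truth$subject_id,
                                             sp$subject_id[sp$parameter == pn])]
    gen <- truth[[pn]]
    list(parameter = pn, generating = gen, recovered = rec,
         correlation = stats::cor(gen, rec), bias = mean(rec - gen),
         rmse = sqrt(mean((rec - gen)^2)))
  })
  names(per_param) <- names(free)[free]
  structure(list(model = model, n_subjects = n_subjects,
                 trials_per_subject = 64L, seed = seed, truth = truth,
                 trials = trials, fit = fit, per_param = per_param),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Parameter recovery for", x$model, "(n =", x$n_subjects, ")\n")
  for (pp in x$per_param) {
    cat(sprintf("  %-7s cor = %.3f  bias = %+.3f  rmse = %.3f\n",
                pp$parameter, pp$correlation, pp$bias, pp$rmse))
  }
  invisible(x)
}
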