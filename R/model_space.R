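#' The nine-model subjective-value space
#'
#' Choice behaviour in the effort-expenditure task is modelled with an
#' economic subjective-value (SV) account: an offer with standardized reward
#' `r` and standardized effort `e` is valued as
#' \deqn{SV = \beta_R r - cost(e)}
#' where `cost(e)` is one of three effort-cost functions (linear
#' \eqn{\beta_E e}, parabolic \eqn{\beta_E e^2}, exponential
#' \eqn{\beta_E (\exp(e) - 1)}), and the SV is turned into an acceptance
#' probability through a softmax with acceptance bias \eqn{\alpha}:
#' \deqn{p(accept) = 1 / (1 + e^{-(\alpha + SV)})}
#'
#' The model space crosses the three cost functions with three parameter
#' configurations: effort sensitivity only (\eqn{\alpha = 0}, \eqn{\beta_R =
#' 1} fixed), effort + reward sensitivity (\eqn{\alpha = 0} fixed), and the
#' full three-parameter configuration.
#'
#' @name model_space
NULL

.COST_KINDS <- c("linear", "parabolic", "exponential")

#' Standardize offer levels
#'
#' Effort levels 1--4 and reward levels 2--5 are divided by their maxima so
#' that both lie in (0, 1], preserving zero and ratio structure.
#'
#' @param effort_level integer vector in 1..4
#' @param reward_points integer vector in 2..5
#' @return list with components `e` and `r`
#' @export
standardize_offer <- function(effort_level, reward_points) {
  if (any(effort_level < 1 | effort_level > 4)) stop("effort_level must be in 1..4")
  if (any(reward_points < 2 | reward_points > 5)) stop("reward_points must be in 2..5")
  list(e = effort_level / 4, r = reward_points / 5)
}

#' Effort cost
#'
#' @param e standardized effort in (0, 1]
#' @param beta_E effort sensitivity (> 0, or 0 at the boundary)
#' @param kind one of `"linear"`, `"parabolic"`, `"exponential"`
#' @return non-negative cost, strictly increasing in `e` for `beta_E > 0`
#' @export
effort_cost <- function(e, beta_E, kind = .COST_KINDS) {
  kind <- match.arg(kind)
  switch(kind,
    linear      = beta_E * e,
    parabolic   = beta_E * e^2,
    exponential = beta_E * (exp(e) - 1)
  )
}

#' Subjective value of an offer
#'
#' @param e,r standardized effort and reward (see [standardize_offer()])
#' @param beta_R reward sensitivity (> 0; fixed at 1 in reduced models)
#' @param beta_E effort sensitivity (> 0)
#' @param cost cost-function kind
#' @return SV, decreasing in `e` and increasing in `r`
#' @export
subjective_value <- function(e, r, beta_R, beta_E, cost = .COST_KINDS) {
  if (any(beta_R < 0) || any(beta_E < 0)) stop("sensitivities must be non-negative")
  beta_R * r - effort_cost(e, beta_E, match.arg(cost))
}

#' Softmax acceptance probability
#'
#' Numerically stable for arbitrarily large `|alpha + sv|`.
#'
#' @param sv subjective value
#' @param alpha acceptance bias (softmax intercept)
#' @return probability in (0, 1), strictly increasing in both arguments
#' @export
acceptance_probability <- function(sv, alpha) {
  stats::plogis(alpha + sv)
}

#' Registry of the nine models
#'
#' Three parameter configurations (`minimal` = beta_E only, `reward` =
#' beta_E + beta_R, `full` = beta_E + beta_R + alpha) crossed with three
#' cost functions.  `full_parabolic` carries the `preferred` flag: it is the
#' configuration found to win out-of-sample model comparison on this task.
#'
#' @return data.frame with one row per model: `name`, `cost`,
#'   `free_alpha`, `free_beta_R` (logical; `beta_E` is always free), and
#'   `preferred`
#' @export
model_registry <- function() {
  configs <- data.frame(
    config = c("minimal", "reward", "full"),
    free_alpha = c(FALSE, FALSE, TRUE),
    free_beta_R = c(FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  grid <- merge(configs, data.frame(cost = .COST_KINDS), by = NULL)
  grid$name <- paste(grid$config, grid$cost, sep = "_")
  grid$preferred <- grid$name == "full_parabolic"
  grid[order(grid$cost, grid$config),
       c("name", "cost", "free_alpha", "free_beta_R", "preferred")]
}

#' Look up one model specification
#'
#' @param name model name as listed by [model_registry()]
#' @return one-row data.frame (a `ModelSpec`)
#' @export
model_spec <- function(name) {
  reg <- model_registry()
  hit <- reg[reg$name == name, ]
  if (nrow(hit) != 1L) {
    stop("unknown model '", name, "'; see model_registry()$name")
  }
  hit
}

# Substitute fixed values for parameters a model does not free:
# alpha := 0, beta_R := 1.
.effective_params <- function(alpha, beta_R, beta_E, spec) {
  list(
    alpha = if (spec$free_alpha) alpha else 0,
    beta_R = if (spec$free_beta_R) beta_R else 1,
    beta_E = beta_E
  )
}

#' Per-trial Bernoulli log-likelihood
#'
#' Log-probability of each observed decision under a model and parameter
#' set.  Parameters may be scalars (one subject) or vectors aligned with
#' `trials` rows.  Parameters excluded by the model are overridden with
#' their fixed values (alpha = 0, beta_R = 1).
#'
#' @param trials data.frame with columns `effort_level`, `reward`, and
#'   `decision` (`"accept"`/`"reject"`)
#' @param alpha,beta_R,beta_E parameters on the natural scale
#' @param model model name or one-row spec from [model_registry()]
#' @return numeric vector of per-trial log-likelihood contributions
#' @export
trial_loglik <- function(trials, alpha, beta_R, beta_E, model = "full_parabolic") {
  spec <- if (is.character(model)) model_spec(model) else model
  if (!all(trials$decision %in% c("accept", "reject"))) {
    stop("decisions must be 'accept' or 'reject'")
  }
  par <- .effective_params(alpha, beta_R, beta_E, spec)
  std <- standardize_offer(trials$effort_level, trials$reward)
  x <- par$alpha + subjective_value(std$e, std$r, par$beta_R, par$beta_E, spec$cost)
  # log p(accept) = plogis(x, log = TRUE); log p(reject) = plogis(-x, log = TRUE)
  sign <- ifelse(trials$decision == "accept", 1, -1)
  stats::plogis(sign * x, log.p = TRUE)
}

#' Session log-likelihood
#'
#' @inheritParams trial_loglik
#' @return sum of per-trial log-likelihoods
#' @export
session_loglik <- function(trials, alpha, beta_R, beta_E, model = "full_parabolic") {
  sum(trial_loglik(trials, alpha, beta_R, beta_E, model))
}
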