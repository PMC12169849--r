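#' Effort-expenditure task simulator
#'
#' Deterministic-given-seed simulation of the gamified clicking task: a
#' calibration phase fixes each subject's maximum clicking capacity, four
#' effort levels are scaled to fractions of that capacity sustained for
#' increasing durations, and a 64-trial session presents offers drawn from
#' sixteen randomly interleaved adaptive staircases whose start offers
#' enumerate the full 4 x 4 effort-by-reward grid.
#'
#' @name task_engine
NULL

#' Effort level definitions
#'
#' Level k requires clicking at a fixed fraction of the calibrated maximum
#' capacity (30/50/70/90%) sustained for an increasing duration
#' (8/11/14/17 s).
#'
#' @return data.frame with columns `level`, `fraction`, `duration`
#' @export
effort_levels <- function() {
  data.frame(
    level = 1:4,
    fraction = c(0.30, 0.50, 0.70, 0.90),
    duration = c(8, 11, 14, 17)
  )
}

#' Calibrate clicking capacity
#'
#' Three 10-second maximal-clicking repetitions; the first warms up and is
#' ignored, the second and third are averaged into the capacity reference.
#'
#' @param rep_clicks numeric vector of exactly three non-negative click
#'   counts (clicks per 10 s)
#' @param post_task_clicks optional click count from the post-task repeat
#' @return object of class `"calibration"` with fields `rep_clicks`,
#'   `capacity`, `post_task_clicks`
#' @export
calibrate_capacity <- function(rep_clicks, post_task_clicks = NULL) {
  if (length(rep_clicks) != 3L) stop("exactly three calibration repetitions required")
  if (any(rep_clicks < 0)) stop("click counts must be non-negative")
  structure(
    list(
      rep_clicks = rep_clicks,
      capacity = mean(rep_clicks[2:3]),
      post_task_clicks = post_task_clicks
    ),
    class = "calibration"
  )
}

#' Clicks required to succeed at an effort level
#'
#' `fraction x (capacity / 10) x duration`, rounded with a configurable
#' convention (ceiling by default) and floored at one click.
#'
#' @param level effort level 1..4
#' @param capacity calibrated capacity (clicks per 10 s), must be >= 7
#' @param rounding `"ceiling"` (default), `"round"`, or `"floor"`
#' @return integer number of clicks
#' @export
required_clicks <- function(level, capacity,
                            rounding = c("ceiling", "round", "floor")) {
  rounding <- match.arg(rounding)
  spec <- effort_levels()
  if (!level %in% spec$level) stop("unknown effort level: ", level)
  if (capacity < 7) stop("capacity below the minimum calibration score of 7")
  row <- spec[spec$level == level, ]
  raw <- row$fraction * (capacity / 10) * row$duration
  n <- switch(rounding, ceiling = ceiling(raw), round = round(raw), floor = floor(raw))
  max(1L, as.integer(n))
}

#' Initialize the sixteen staircases
#'
#' Each of the sixteen effort-by-reward combinations serves as the start
#' offer of exactly one staircase; the set of start offers is therefore the
#' full grid regardless of seed (the seed only matters for interleaving at
#' session run time).
#'
#' @return data.frame with columns `id`, `start_effort`, `start_reward`,
#'   `effort`, `reward`, `visits` (current offer initialized at start)
#' @export
init_staircases <- function() {
  grid <- expand.grid(start_effort = 1:4, start_reward = 2:5)
  data.frame(
    id = 1:16,
    start_effort = grid$start_effort,
    start_reward = grid$start_reward,
    effort = grid$start_effort,
    reward = grid$start_reward,
    visits = 0L
  )
}

#' One staircase adjustment
#'
#' After acceptance the next offer on the staircase becomes harder (effort
#' + 1 or reward - 1); after rejection it becomes easier (effort - 1 or
#' reward + 1).  Exactly one dimension moves by one step.  At grid
#' boundaries the only feasible direction is taken; at the two corners with
#' no feasible direction (accept at effort 4 / reward 2, reject at effort
#' 1 / reward 5) the offer is unchanged.  When both directions are feasible
#' one is drawn with probability 1/2 from the session RNG.
#'
#' @param effort,reward current offer (effort 1..4, reward 2..5)
#' @param decision `"accept"` or `"reject"`
#' @return integer vector `c(effort, reward)` of the next offer
#' @export
staircase_update <- function(effort, reward, decision) {
  if (effort < 1 || effort > 4 || reward < 2 || reward > 5) {
    stop("offer out of bounds")
  }
  if (!decision %in% c("accept", "reject")) stop("decision must be accept/reject")
  effort <- as.integer(effort); reward <- as.integer(reward)
  if (decision == "accept") {
    moves <- list()
    if (effort < 4) moves <- c(moves, list(c(effort + 1L, reward)))
    if (reward > 2) moves <- c(moves, list(c(effort, reward - 1L)))
  } else {
    moves <- list()
    if (effort > 1) moves <- c(moves, list(c(effort - 1L, reward)))
    if (reward < 5) moves <- c(moves, list(c(effort, reward + 1L)))
  }
  if (length(moves) == 0L) return(c(as.integer(effort), as.integer(reward)))
  if (length(moves) == 1L) return(moves[[1L]])
  moves[[if (stats::runif(1) < 0.5) 1L else 2L]]
}

#' Motor model of clicking
#'
#' Gaussian trial-to-trial variability around a true clicking rate.  The
#' default variability (`rate_sd = 0.25 x true_rate`) places a capacity-
#' clicking agent in the observed high-success regime (~98% success of
#' accepted challenges, failures concentrated at the hardest level).
#'
#' @param true_rate true clicks per second (> 0)
#' @param rate_sd clicks-per-second SD of trial-to-trial variability
#' @param fatigue_drift expected pre-to-post change in the 10-s capacity
#'   check (clicks; negative = slowing)
#' @return list of class `"motor_model"`
#' @export
motor_model <- function(true_rate, rate_sd = 0.25 * true_rate,
                        fatigue_drift = -2.34) {
  if (true_rate <= 0) stop("true_rate must be positive")
  if (rate_sd < 0) stop("rate_sd must be non-negative")
  structure(list(true_rate = true_rate, rate_sd = rate_sd,
                 fatigue_drift = fatigue_drift),
            class = "motor_model")
}

#' Construct a task agent
#'
#' @param alpha acceptance bias
#' @param beta_R reward sensitivity (> 0)
#' @param beta_E effort sensitivity (> 0)
#' @param capacity calibrated clicking capacity (clicks per 10 s)
#' @param motor optional [motor_model()]; defaults to clicking at the
#'   calibrated capacity rate
#' @param subject_id identifier carried into trial records
#' @return list of class `"agent"`
#' @export
make_agent <- function(alpha, beta_R, beta_E, capacity = 60,
                       motor = NULL, subject_id = 1L) {
  if (beta_R <= 0 || beta_E <= 0) stop("sensitivities must be positive")
  if (is.null(motor)) motor <- motor_model(true_rate = capacity / 10)
  structure(list(subject_id = subject_id, alpha = alpha, beta_R = beta_R,
                 beta_E = beta_E, capacity = capacity, motor = motor),
            class = "agent")
}

#' Simulate the outcome of an accepted challenge
#'
#' Clicks made are drawn as `round(Normal(true_rate x duration,
#' rate_sd x sqrt(duration)))`, truncated at zero; the challenge succeeds
#' when the clicks reach the level's requirement.
#'
#' @param motor a [motor_model()]
#' @param level effort level 1..4
#' @param capacity calibrated capacity
#' @param rounding rounding convention for [required_clicks()]
#' @return list with `success` (logical) and `clicks` (integer)
#' @export
simulate_challenge_outcome <- function(motor, level, capacity,
                                       rounding = "ceiling") {
  dur <- effort_levels()$duration[level]
  need <- required_clicks(level, capacity, rounding)
  clicks <- round(stats::rnorm(1, motor$true_rate * dur,
                               motor$rate_sd * sqrt(dur)))
  clicks <- max(0L, as.integer(clicks))
  list(success = clicks >= need, clicks = clicks)
}

#' Simulate one 64-trial session
#'
#' Four blocks of sixteen trials; within each block every staircase is
#' visited exactly once in seeded-random order.  Decisions are Bernoulli
#' draws from the agent's acceptance probability under the given model;
#' accepted trials resolve a clicking challenge through the motor model.
#' Rejected trials always earn one point; accepted-and-failed trials earn
#' zero.
#'
#' @param agent an [make_agent()] agent
#' @param model model name from [model_registry()] used as the generative
#'   decision rule
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the session is fully reproducible
#' @param rounding rounding convention for [required_clicks()]
#' @return data.frame of 64 trial records with columns `subject_id`,
#'   `trial`, `block`, `staircase`, `effort_level`, `reward`, `decision`,
#'   `success`, `clicks`, `points`
#' @export
run_session <- function(agent, model = "full_parabolic", seed = NULL,
                        rounding = "ceiling") {
  if (!inherits(agent, "agent")) stop("agent must be created with make_agent()")
  if (!is.null(seed)) set.seed(seed)
  spec <- model_spec(model)
  sc <- init_staircases()
  out <- vector("list", 64L)
  trial <- 0L
  for (block in 1:4) {
    for (id in sample.int(16L)) {
      trial <- trial + 1L
      eff <- sc$effort[id]; rew <- sc$reward[id]
      par <- .effective_params(agent$alpha, agent$beta_R, agent$beta_E, spec)
      std <- standardize_offer(eff, rew)
      p <- acceptance_probability(
        subjective_value(std$e, std$r, par$beta_R, par$beta_E, spec$cost),
        par$alpha
      )
      accept <- stats::runif(1) < p
      if (accept) {
        res <- simulate_challenge_outcome(agent$motor, eff, agent$capacity,
                                          rounding)
        success <- res$success; clicks <- res$clicks
        points <- if (success) rew else 0L
        decision <- "accept"
      } else {
        success <- NA; clicks <- NA_integer_
        points <- 1L
        decision <- "reject"
      }
      out[[trial]] <- data.frame(
        subject_id = agent$subject_id, trial = trial, block = block,
        staircase = id, effort_level = eff, reward = rew,
        decision = decision, success = success, clicks = clicks,
        points = points
      )
      nxt <- staircase_update(eff, rew, decision)
      sc$effort[id] <- nxt[1L]; sc$reward[id] <- nxt[2L]
      sc$visits[id] <- sc$visits[id] + 1L
    }
  }
  do.call(rbind, out)
}

#' Simulate a cohort of sessions
#'
#' @param agents list of [make_agent()] agents
#' @param model generative model name
#' @param seed integer seed for the whole cohort
#' @param rounding rounding convention for [required_clicks()]
#' @return row-bound trial data.frame across agents
#' @export
simulate_cohort <- function(agents, model = "full_parabolic", seed = NULL,
                            rounding = "ceiling") {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(agents, run_session, model = model, seed = NULL,
                        rounding = rounding))
}
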