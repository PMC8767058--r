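#' Task configuration for the two-step decision task
#'
#' Builds and validates the configuration of the sequential two-stage task:
#' number of trials, probability of the common stage-1 to stage-2 transition,
#' the per-reward payout, and the Gaussian random-walk settings governing the
#' four second-stage reward probabilities.
#'
#' Defaults follow the original task variant: 201 trials, 70% common
#' transitions, 0.20 EUR per rewarded trial, walk increments with SD 0.025
#' reflected at 0.25 and 0.75.
#'
#' @param n_trials positive integer, number of trials per session.
#' @param p_common probability of the common transition, in (0.5, 1).
#' @param reward_magnitude payout (currency units) per rewarded trial. A
#'   reporting constant only; learning operates on the 0/1 reward indicator.
#' @param walk_sd standard deviation of the per-trial Gaussian increment of
#'   each reward probability.
#' @param walk_bounds length-2 numeric, reflecting bounds `[lo, hi]` for the
#'   reward probabilities, with `0 <= lo < hi <= 1`.
#' @param seed integer RNG seed recorded with the configuration.
#' @return an object of class `task_config` (a validated list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$n_trials
task_config <- function(n_trials = 201L, p_common = 0.7,
                        reward_magnitude = 0.20, walk_sd = 0.025,
                        walk_bounds = c(0.25, 0.75), seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L)
    stop("`n_trials` must be a positive integer", call. = FALSE)
  if (!is.numeric(p_common) || p_common <= 0.5 || p_common >= 1)
    stop("`p_common` must lie in (0.5, 1)", call. = FALSE)
  if (!is.numeric(walk_sd) || walk_sd <= 0)
    stop("`walk_sd` must be > 0", call. = FALSE)
  if (length(walk_bounds) != 2L || walk_bounds[1] < 0 ||
      walk_bounds[2] > 1 || walk_bounds[1] >= walk_bounds[2])
    stop("`walk_bounds` must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  structure(list(n_trials = n_trials, p_common = p_common,
                 reward_magnitude = reward_magnitude, walk_sd = walk_sd,
                 walk_bounds = as.numeric(walk_bounds),
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Generate reflecting Gaussian random walks for the reward probabilities
#'
#' Each of the four second-stage stimuli carries an independent reward
#' probability that starts uniform within `walk_bounds` and receives a
#' `N(0, walk_sd^2)` increment per trial, reflected at the bounds (reflection
#' rather than truncation preserves the walk variance near the edges).
#'
#' @param config a [task_config()].
#' @return numeric matrix `n_trials x 4` of reward probabilities, class
#'   `reward_walk`.
#' @export
generate_reward_walks <- function(config) {
  stopifnot(inherits(config, "task_config"))
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  n <- config$n_trials
  probs <- matrix(NA_real_, n, 4L)
  probs[1L, ] <- stats::runif(4L, lo, hi)
  if (n > 1L) {
    steps <- matrix(stats::rnorm((n - 1L) * 4L, 0, config$walk_sd), n - 1L, 4L)
    for (t in 2L:n) probs[t, ] <- reflect_into(probs[t - 1L, ] + steps[t - 1L, ], lo, hi)
  }
  structure(probs, class = c("reward_walk", "matrix", "array"))
}

# Reflect values into [lo, hi]; handles multiple bounces for large excursions.
reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  y <- (x - lo) %% (2 * width)
  lo + ifelse(y > width, 2 * width - y, y)
}

#' Sample the stage-1 to stage-2 transition
#'
#' Action `a` (0 or 1) leads to its "common" state (state `a`) with
#' probability `p_common` and to the other state otherwise. The returned
#' label is `"common"` iff the sampled state is the action's high-probability
#' state.
#'
#' @param choice1 stage-1 action, 0 or 1.
#' @param config a [task_config()].
#' @return list with `state2` (0/1) and `transition` ("common"/"rare").
#' @export
sample_transition <- function(choice1, config) {
  stopifnot(choice1 %in% c(0L, 1L))
  common <- stats::runif(1) < config$p_common
  state2 <- if (common) as.integer(choice1) else 1L - as.integer(choice1)
  list(state2 = state2, transition = if (common) "common" else "rare")
}

#' Label a transition given the realized state
#'
#' @param choice1 stage-1 action (0/1).
#' @param state2 second-stage state (0/1).
#' @return "common" if `state2` equals the action's common state, else "rare".
#' @export
transition_label <- function(choice1, state2) {
  ifelse(as.integer(state2) == as.integer(choice1), "common", "rare")
}

#' Run a full task session under an arbitrary choice policy
#'
#' Drives the environment loop: the policy is called once per stage with the
#' observable history and must return an action in `{0, 1}`. Outcomes are
#' Bernoulli draws from the reward walk at the chosen second-stage stimulus.
#' Reaction-time columns are filled with `NA` (response-time generation is
#' owned by the cohort generator).
#'
#' @param policy function `(stage, trial_index, state2_or_NA, history_df)`
#'   returning an action; `stage` is 1 or 2.
#' @param config a [task_config()].
#' @param walks a matrix from [generate_reward_walks()].
#' @param subject_id subject identifier for the returned dataset.
#' @return a `subject_dataset`: list with `subject_id`, `trials`
#'   (data.frame, one row per trial) and `covariates`.
#' @export
run_session <- function(policy, config, walks, subject_id = "s01") {
  n <- config$n_trials
  stopifnot(nrow(walks) == n)
  choice1 <- integer(n); state2 <- integer(n); choice2 <- integer(n)
  outcome <- integer(n); trans <- character(n)
  for (t in seq_len(n)) {
    hist <- if (t > 1L) list(choice1 = choice1[seq_len(t - 1L)],
                             outcome = outcome[seq_len(t - 1L)]) else NULL
    a1 <- policy(1L, t, NA_integer_, hist)
    if (!a1 %in% c(0L, 1L)) stop("policy returned invalid stage-1 action", call. = FALSE)
    tr <- sample_transition(a1, config)
    a2 <- policy(2L, t, tr$state2, hist)
    if (!a2 %in% c(0L, 1L)) stop("policy returned invalid stage-2 action", call. = FALSE)
    # stimulus index: state2 selects the pair, choice2 the stimulus within it
    stim <- 2L * tr$state2 + as.integer(a2) + 1L
    r <- as.integer(stats::runif(1) < walks[t, stim])
    choice1[t] <- a1; state2[t] <- tr$state2; choice2[t] <- a2
    outcome[t] <- r; trans[t] <- tr$transition
  }
  trials <- data.frame(trial = seq_len(n) - 1L, choice1 = choice1,
                       transition = trans, state2 = state2, choice2 = choice2,
                       outcome = outcome, rt1_ms = NA_real_, rt2_ms = NA_real_)
  new_subject_dataset(subject_id, trials)
}

#' Construct a subject dataset
#'
#' @param subject_id character id.
#' @param trials data.frame with columns trial, choice1, transition, state2,
#'   choice2, outcome, rt1_ms, rt2_ms.
#' @param covariates named numeric vector (cognitive speed, working memory,
#'   impulsivity) or NULL.
#' @return object of class `subject_dataset`.
#' @export
new_subject_dataset <- function(subject_id, trials, covariates = NULL) {
  required <- c("trial", "choice1", "transition", "state2", "choice2",
                "outcome", "rt1_ms", "rt2_ms")
  missing <- setdiff(required, names(trials))
  if (length(missing)) stop("trials lacks columns: ", paste(missing, collapse = ", "),
                            call. = FALSE)
  if (any(trials$trial != seq_len(nrow(trials)) - 1L))
    stop("trials must be sorted by trial index with no gaps", call. = FALSE)
  bad <- trials$transition != transition_label(trials$choice1, trials$state2)
  if (any(bad))
    stop("transition labels inconsistent with (choice1, state2) at trials: ",
         paste(utils::head(which(bad)), collapse = ", "), call. = FALSE)
  structure(list(subject_id = as.character(subject_id), trials = trials,
                 covariates = covariates),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset>", x$subject_id, "-", nrow(x$trials), "trials\n")
  invisible(x)
}
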