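#' Seven-parameter hybrid agent parameters
#'
#' The hybrid agent mixes model-free SARSA(lambda) values with model-based
#' values computed from the known transition structure. Parameters:
#' stage-wise learning rates `alpha1`, `alpha2` in \[0, 1\]; inverse
#' temperatures `beta1`, `beta2 >= 0`; eligibility trace `lam` in \[0, 1\]
#' (how strongly the stage-2 prediction error updates the stage-1 value);
#' model-based weight `w` in \[0, 1\] (0 = purely model-free, 1 = purely
#' model-based); perseveration strength `rho` (unbounded), a bonus for
#' repeating the previous stage-1 choice.
#'
#' @param alpha1,alpha2 learning rates in \[0, 1\].
#' @param beta1,beta2 softmax inverse temperatures, >= 0.
#' @param lam eligibility trace in \[0, 1\].
#' @param w model-based weight in \[0, 1\].
#' @param rho perseveration strength (any real).
#' @return object of class `agent_params` (named numeric vector).
#' @export
agent_params <- function(alpha1, alpha2, beta1, beta2, lam, w, rho) {
  p <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
         lam = lam, w = w, rho = rho)
  if (any(!is.finite(p))) stop("agent parameters must be finite", call. = FALSE)
  for (nm in c("alpha1", "alpha2", "lam", "w"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
  if (p[["beta1"]] < 0 || p[["beta2"]] < 0)
    stop("inverse temperatures must be >= 0", call. = FALSE)
  structure(p, class = "agent_params")
}

#' Model-based stage-1 action values
#'
#' Prospective planning under the known transition model:
#' `Q_MB(a) = p_common * max_b Q2(common_state(a), b) +
#' (1 - p_common) * max_b Q2(other_state, b)`, where action `a`'s common
#' state is state `a`.
#'
#' @param q_mf_stage2 2x2 matrix of stage-2 values (rows = states,
#'   cols = actions).
#' @param p_common common-transition probability.
#' @return numeric length-2 vector of stage-1 model-based values.
#' @export
mb_values <- function(q_mf_stage2, p_common) {
  stopifnot(p_common > 0.5, p_common < 1)
  m <- apply(q_mf_stage2, 1L, max)
  c(p_common * m[1] + (1 - p_common) * m[2],
    p_common * m[2] + (1 - p_common) * m[1])
}

#' Mix model-based and model-free stage-1 values
#'
#' `Q_net = w * Q_MB + (1 - w) * Q_MF`, elementwise.
#'
#' @param q_mb,q_mf_stage1 length-2 value vectors.
#' @param w model-based weight in \[0, 1\].
#' @return length-2 numeric vector.
#' @export
net_values <- function(q_mb, q_mf_stage1, w) {
  stopifnot(w >= 0, w <= 1)
  w * q_mb + (1 - w) * q_mf_stage1
}

#' Stage-1 choice probabilities (softmax with perseveration)
#'
#' Softmax over `beta1 * (Q_net(a) + rho * 1[a == prev_choice1])`. On the
#' first trial (`prev_choice1 = NA`) no perseveration bonus applies.
#'
#' @param q_net length-2 net values.
#' @param beta1 inverse temperature >= 0.
#' @param rho perseveration strength.
#' @param prev_choice1 previous stage-1 action (0/1) or `NA`.
#' @return length-2 probability vector summing to 1.
#' @export
choice_probs_stage1 <- function(q_net, beta1, rho, prev_choice1 = NA) {
  stopifnot(beta1 >= 0)
  bonus <- c(0, 0)
  if (!is.na(prev_choice1)) bonus[as.integer(prev_choice1) + 1L] <- rho
  softmax2(beta1 * (q_net + bonus))
}

#' Stage-2 choice probabilities (plain softmax)
#'
#' @param q_mf_row length-2 stage-2 values at the visited state.
#' @param beta2 inverse temperature >= 0.
#' @return length-2 probability vector.
#' @export
choice_probs_stage2 <- function(q_mf_row, beta2) {
  stopifnot(beta2 >= 0)
  softmax2(beta2 * q_mf_row)
}

softmax2 <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Initial agent state
#'
#' Values start at zero; no previous choice.
#' @return list with `q_mf` (3x2 matrix: row 1 stage-1 state, rows 2-3
#'   stage-2 states) and `prev_choice1` (`NA`).
#' @export
agent_init <- function() {
  list(q_mf = matrix(0, 3L, 2L), prev_choice1 = NA_integer_)
}

#' SARSA(lambda) value update for one trial
#'
#' Applies the hybrid model's learning rule given the observed events of one
#' trial: the stage-1 value moves toward the visited stage-2 value
#' (`delta1`), the stage-2 value moves toward the outcome (`delta2`), and a
#' fraction `lam` of `delta2` is credited back to the stage-1 action.
#'
#' @param state agent state from [agent_init()] or a previous update.
#' @param trial one-row list/data.frame with `choice1`, `state2`, `choice2`,
#'   `outcome`.
#' @param params an [agent_params()].
#' @return updated agent state.
#' @export
agent_update <- function(state, trial, params) {
  q <- state$q_mf
  a1 <- as.integer(trial$choice1) + 1L
  s2 <- as.integer(trial$state2) + 2L    # stage-2 states occupy rows 2:3
  a2 <- as.integer(trial$choice2) + 1L
  d1 <- q[s2, a2] - q[1L, a1]
  q[1L, a1] <- q[1L, a1] + params[["alpha1"]] * d1
  d2 <- trial$outcome - q[s2, a2]
  q[s2, a2] <- q[s2, a2] + params[["alpha2"]] * d2
  q[1L, a1] <- q[1L, a1] + params[["alpha1"]] * params[["lam"]] * d2
  list(q_mf = q, prev_choice1 = as.integer(trial$choice1))
}

#' Simulate a full session of the hybrid agent
#'
#' Closed-loop simulation: stage-1 choice from the net-value softmax with
#' perseveration, transition sampled from the task, stage-2 choice from the
#' stage-2 softmax, outcome Bernoulli from the reward walk, then the
#' SARSA(lambda) update.
#'
#' @param params an [agent_params()].
#' @param config a [task_config()].
#' @param walks reward-walk matrix (`n_trials x 4`).
#' @param subject_id id for the emitted dataset.
#' @return a `subject_dataset`.
#' @export
simulate_agent <- function(params, config, walks, subject_id = "s01") {
  n <- config$n_trials
  stopifnot(nrow(walks) == n)
  st <- agent_init()
  choice1 <- integer(n); state2 <- integer(n); choice2 <- integer(n)
  outcome <- integer(n); trans <- character(n)
  for (t in seq_len(n)) {
    qmb <- mb_values(st$q_mf[2:3, , drop = FALSE], config$p_common)
    qnet <- net_values(qmb, st$q_mf[1L, ], params[["w"]])
    p1 <- choice_probs_stage1(qnet, params[["beta1"]], params[["rho"]],
                              st$prev_choice1)
    a1 <- as.integer(stats::runif(1) >= p1[1])
    tr <- sample_transition(a1, config)
    p2 <- choice_probs_stage2(st$q_mf[tr$state2 + 2L, ], params[["beta2"]])
    a2 <- as.integer(stats::runif(1) >= p2[1])
    stim <- 2L * tr$state2 + a2 + 1L
    r <- as.integer(stats::runif(1) < walks[t, stim])
    st <- agent_update(st, list(choice1 = a1, state2 = tr$state2,
                                choice2 = a2, outcome = r), params)
    choice1[t] <- a1; state2[t] <- tr$state2; choice2[t] <- a2
    outcome[t] <- r; trans[t] <- tr$transition
  }
  trials <- data.frame(trial = seq_len(n) - 1L, choice1 = choice1,
                       transition = trans, state2 = state2, choice2 = choice2,
                       outcome = outcome, rt1_ms = NA_real_, rt2_ms = NA_real_)
  new_subject_dataset(subject_id, trials)
}

#' Stay probabilities by previous outcome and transition
#'
#' Tabulates the probability of repeating the previous stage-1 choice in the
#' four cells previous-outcome x previous-transition. This is the classic
#' behavioral signature: purely model-free agents stay more after reward
#' regardless of transition; purely model-based agents show the crossover
#' (reward after a rare transition favors switching).
#'
#' @param dataset a `subject_dataset` (or its `trials` data.frame).
#' @return data.frame with columns `prev_outcome` (0/1), `prev_transition`
#'   ("common"/"rare"), `p_stay`, `n`.
#' @export
stay_probabilities <- function(dataset) {
  tr <- if (inherits(dataset, "subject_dataset")) dataset$trials else dataset
  n <- nrow(tr)
  if (n < 2L) stop("need at least 2 trials", call. = FALSE)
  stay <- as.integer(tr$choice1[-1L] == tr$choice1[-n])
  po <- tr$outcome[-n]; pt <- tr$transition[-n]
  out <- expand.grid(prev_outcome = c(0L, 1L),
                     prev_transition = c("common", "rare"),
                     stringsAsFactors = FALSE)
  out$p_stay <- NA_real_; out$n <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- po == out$prev_outcome[i] & pt == out$prev_transition[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0L) out$p_stay[i] <- mean(stay[sel])
  }
  out
}
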