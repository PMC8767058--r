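# Independent brute-force oracle for the session likelihood: a naive,
# self-contained forward pass written directly from the model equations,
# sharing no code with the package implementation.
nll_oracle <- function(params, data, p_common = 0.7) {
  q1 <- c(0, 0)                       # stage-1 action values
  q2 <- matrix(0, 2, 2)               # stage-2 state x action values
  prev <- NA
  total <- 0
  for (t in seq_len(nrow(data$trials))) {
    tr <- data$trials[t, ]
    c1 <- tr$choice1 + 1; s2 <- tr$state2 + 1; c2 <- tr$choice2 + 1
    # model-based values by explicit enumeration over transitions
    qmb <- c(0, 0)
    for (a in 1:2) for (s in 1:2) {
      pr <- if (s == a) p_common else 1 - p_common
      qmb[a] <- qmb[a] + pr * max(q2[s, ])
    }
    qnet <- params[["w"]] * qmb + (1 - params[["w"]]) * q1
    if (!is.na(prev)) qnet[prev] <- qnet[prev] + params[["rho"]]
    num <- exp(params[["beta1"]] * qnet)
    p1 <- num / sum(num)
    num2 <- exp(params[["beta2"]] * q2[s2, ])
    p2 <- num2 / sum(num2)
    total <- total - log(p1[c1]) - log(p2[c2])
    d1 <- q2[s2, c2] - q1[c1]
    q1[c1] <- q1[c1] + params[["alpha1"]] * d1
    d2 <- tr$outcome - q2[s2, c2]
    q2[s2, c2] <- q2[s2, c2] + params[["alpha2"]] * d2
    q1[c1] <- q1[c1] + params[["alpha1"]] * params[["lam"]] * d2
    prev <- c1
  }
  total
}

# dataset with explicitly chosen events (vectors of equal length)
make_dataset <- function(choice1, state2, choice2, outcome, id = "toy") {
  n <- length(choice1)
  trials <- data.frame(
    trial = seq_len(n) - 1L, choice1 = as.integer(choice1),
    transition = ifelse(state2 == choice1, "common", "rare"),
    state2 = as.integer(state2), choice2 = as.integer(choice2),
    outcome = as.integer(outcome), rt1_ms = NA_real_, rt2_ms = NA_real_)
  new_subject_dataset(id, trials)
}

# small planted cohort for analysis tests
quick_cohort <- function(n_subjects, seed, coupling_b = -0.25,
                         n_trials = 201L) {
  spec <- cohort_spec(n_subjects = n_subjects, seed = seed,
                      coupling_b = coupling_b,
                      task = task_config(n_trials = n_trials))
  generate_cohort(spec)
}

random_params <- function() {
  agent_params(runif(1), runif(1), runif(1, 0, 8), runif(1, 0, 8),
               runif(1), runif(1), runif(1, -0.5, 0.5))
}
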