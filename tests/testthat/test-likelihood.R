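test_that("transforms round-trip interior points", {
  set.seed(5)
  for (i in 1:20) {
    z <- rnorm(7, 0, 2)
    expect_equal(unname(params_to_z(z_to_params(z))), z, tolerance = 1e-10)
  }
  p <- z_to_params(c(0, 0, 1, 1, 0, 0, 0.3))
  expect_equal(unname(p[c("alpha1", "lam", "w")]), rep(0.5, 3))
  expect_equal(unname(p[c("beta1", "beta2")]), rep(exp(1), 2))
  expect_equal(unname(p["rho"]), 0.3)
})

test_that("model restrictions pin the weight", {
  mf <- model_spec("mf"); mb <- model_spec("mb")
  expect_equal(expand_params(rep(0, 6), mf)[["w"]], 0)
  expect_equal(expand_params(rep(0, 6), mb)[["w"]], 1)
  expect_length(model_spec("hybrid")$free, 7L)
  expect_length(mf$free, 6L)
})

test_that("session_nll hits the uniform bound at zero temperature", {
  set.seed(13)
  d <- make_dataset(sample(0:1, 30, TRUE), sample(0:1, 30, TRUE),
                    sample(0:1, 30, TRUE), sample(0:1, 30, TRUE))
  p <- agent_params(0.5, 0.5, 0, 0, 0.5, 0.5, 0.7)
  expect_equal(session_nll(p, d), 2 * 30 * log(2), tolerance = 1e-12)
})

test_that("session_nll agrees with the independent oracle", {
  # 3-trial hand-constructed sessions and longer random ones
  d3 <- make_dataset(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(1, 0, 1))
  set.seed(17)
  for (i in 1:10) {
    p <- random_params()
    expect_equal(session_nll(p, d3), nll_oracle(p, d3), tolerance = 1e-8)
  }
  cfg <- task_config(n_trials = 60L)
  for (i in 1:5) {
    p <- random_params()
    walks <- generate_reward_walks(cfg)
    d <- simulate_agent(p, cfg, walks)
    expect_equal(session_nll(p, d), nll_oracle(p, d), tolerance = 1e-8)
  }
})

test_that("nll is additive over sessions and rejects bad labels", {
  set.seed(19)
  d <- make_dataset(sample(0:1, 20, TRUE), sample(0:1, 20, TRUE),
                    sample(0:1, 20, TRUE), sample(0:1, 20, TRUE))
  p <- random_params()
  expect_equal(sum(vapply(list(d, d), session_nll, numeric(1), params = p)),
               2 * session_nll(p, d))
  d_bad <- d
  d_bad$trials$transition[3] <- setdiff(c("common", "rare"),
                                        d_bad$trials$transition[3])
  expect_error(session_nll(p, d_bad), "inconsistent")
})

test_that("a tight prior dominates the MAP estimate", {
  set.seed(23)
  cfg <- task_config(n_trials = 50L)
  d <- simulate_agent(random_params(), cfg, generate_reward_walks(cfg))
  mu <- c(0.2, -0.3, 1, 1.2, 0.1, -0.2, 0.15)
  pr <- group_prior(mu, rep(1e-6, 7))
  f <- map_fit(d, pr, settings = fit_settings(n_starts = 1))
  expect_equal(unname(f$z_map), mu, tolerance = 0.05)
})

test_that("posterior penalty is nonnegative under the default prior", {
  set.seed(29)
  cfg <- task_config(n_trials = 100L)
  d <- simulate_agent(random_params(), cfg, generate_reward_walks(cfg))
  f <- map_fit(d, group_prior(), settings = fit_settings(n_starts = 2))
  expect_gte(f$neg_log_post, f$neg_log_lik)
  expect_true(f$converged)
  expect_equal(dim(f$laplace_cov), c(7L, 7L))
  # fitted parameters respect their bounds by construction
  expect_true(all(f$params[c("alpha1", "alpha2", "lam", "w")] >= 0))
  expect_true(all(f$params[c("alpha1", "alpha2", "lam", "w")] <= 1))
  expect_true(all(f$params[c("beta1", "beta2")] >= 0))
})

test_that("single-subject w recovery works at moderate temperature", {
  # data simulated from known params, flat-ish prior: w within +/- 0.25 of
  # truth in >= 80% of replicates
  cfg <- task_config()
  pr <- group_prior(c(0, 0, log(3), log(3), 0, 0, 0), rep(4, 7))
  set.seed(31)
  hits <- 0L; n_rep <- 50L
  for (r in seq_len(n_rep)) {
    w_true <- runif(1, 0.05, 0.95)
    pars <- agent_params(0.5, 0.5, 5, 5, 0.6, w_true, 0.1)
    d <- simulate_agent(pars, cfg, generate_reward_walks(cfg))
    f <- map_fit(d, pr, settings = fit_settings(n_starts = 2))
    if (abs(f$params[["w"]] - w_true) <= 0.25) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("one EM iteration equals independent MAP fits under the prior", {
  set.seed(37)
  gen <- quick_cohort(4, seed = 37, n_trials = 80L)
  s <- fit_settings(n_starts = 1, em_max_iter = 1)
  em1 <- em_fit(gen$cohort, settings = s)
  direct <- lapply(gen$cohort, map_fit, prior = group_prior(), settings = s)
  for (i in seq_along(direct))
    expect_equal(em1$subject_fits[[i]]$z_map, direct[[i]]$z_map,
                 tolerance = 1e-8)
})

test_that("EM recovers the group mean and is reproducible", {
  gen <- quick_cohort(40, seed = 41)
  s <- fit_settings(n_starts = 2, em_max_iter = 30)
  set.seed(1); fit1 <- em_fit(gen$cohort, settings = s)
  free <- fit1$model$free
  mu_true <- gen$truth$spec$prior$mu
  s2_true <- gen$truth$spec$prior$sigma2
  se <- sqrt(s2_true / 40)
  ok <- abs(fit1$prior$mu[free] - mu_true[free]) <= 2 * se[free]
  expect_gte(sum(ok), 5L)
  # penalized objective is non-increasing across iterations (tolerance
  # 1e-3 per subject)
  obj <- vapply(fit1$trace, function(x) x$penalized_nll, numeric(1))
  if (length(obj) > 1L)
    expect_true(all(diff(obj) <= 1e-3 * 40))
  # reproducibility under identical seeds
  set.seed(1); fit2 <- em_fit(gen$cohort, settings = s)
  expect_equal(fit1$prior$mu, fit2$prior$mu, tolerance = 1e-12)
})

test_that("iBIC prefers the generating model class", {
  # scaled down for runtime: 2 replicate cohorts per scenario, 20 subjects,
  # short sessions and capped EM
  cfg <- task_config(n_trials = 120L)
  s <- fit_settings(n_starts = 1, em_max_iter = 8)
  fit_both <- function(cohort, models) {
    vapply(models, function(m) {
      f <- em_fit(cohort, model_spec(m), s)
      ibic(f, cohort, n_samples = 300L)$ibic
    }, numeric(1))
  }
  # hybrid-generated data (w approx 0.6): hybrid wins
  wins_h <- 0L
  for (r in 1:2) {
    set.seed(100 + r)
    cohort <- lapply(1:20, function(i) {
      pars <- agent_params(runif(1, .3, .7), runif(1, .3, .7), 5, 5,
                          runif(1, .4, .8), 0.6, 0.1)
      simulate_agent(pars, cfg, generate_reward_walks(cfg),
                     sprintf("s%02d", i))
    })
    v <- fit_both(cohort, c("hybrid", "mf", "mb"))
    if (v["hybrid"] < min(v["mf"], v["mb"])) wins_h <- wins_h + 1L
  }
  expect_gte(wins_h, 1L)
  # pure model-free data: the restricted model is not worse
  set.seed(200)
  cohort0 <- lapply(1:20, function(i) {
    pars <- agent_params(runif(1, .3, .7), runif(1, .3, .7), 5, 5,
                        runif(1, .4, .8), 0, 0.1)
    simulate_agent(pars, cfg, generate_reward_walks(cfg), sprintf("s%02d", i))
  })
  v0 <- fit_both(cohort0, c("hybrid", "mf"))
  expect_lte(v0["mf"], v0["hybrid"] + 5)
})

test_that("marginal-likelihood sampling tightens with more samples", {
  gen <- quick_cohort(3, seed = 43, n_trials = 60L)
  fit <- em_fit(gen$cohort, settings = fit_settings(n_starts = 1,
                                                    em_max_iter = 2))
  spread <- function(n_samples) {
    vals <- vapply(1:6, function(i) {
      set.seed(1000 + i)
      ibic(fit, gen$cohort, n_samples = n_samples)$ibic
    }, numeric(1))
    sd(vals)
  }
  expect_lt(spread(400L), spread(20L))
  expect_error(posterior_predictive(fit, gen$cohort, n_sim = 0), "n_sim")
})

test_that("posterior predictive reproduces the stay pattern", {
  # scaled down from the 100-subject design for runtime; 40 subjects give
  # the same qualitative self-consistency
  gen <- quick_cohort(40, seed = 47)
  fit <- em_fit(gen$cohort, settings = fit_settings(n_starts = 1,
                                                    em_max_iter = 10))
  set.seed(47)
  pp <- posterior_predictive(fit, gen$cohort, task_config(), n_sim = 10L)
  expect_equal(nrow(pp), 40L * 4L)
  # subject-level reward x transition interaction correlates between
  # observed and simulated
  inter <- function(col) {
    vapply(split(pp, pp$subject_id), function(d) {
      v <- d[[col]]
      (v[d$prev_outcome == 1 & d$prev_transition == "common"] -
         v[d$prev_outcome == 1 & d$prev_transition == "rare"]) -
        (v[d$prev_outcome == 0 & d$prev_transition == "common"] -
           v[d$prev_outcome == 0 & d$prev_transition == "rare"])
    }, numeric(1))
  }
  expect_gt(cor(inter("observed"), inter("simulated")), 0.3)
})
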