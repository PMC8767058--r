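make_scores <- function(gen) score_items_table(gen$items)

test_that("stay table uses lag-1 construction with effect coding", {
  d <- make_dataset(c(0, 0, 1), c(0, 1, 1), c(1, 0, 0), c(1, 0, 1), id = "s001")
  d$covariates <- c(cognitive_speed = 11, working_memory = 10, impulsivity = 29)
  d2 <- make_dataset(c(1, 1, 1), c(1, 0, 1), c(0, 0, 1), c(0, 1, 1), id = "s002")
  d2$covariates <- c(cognitive_speed = 12, working_memory = 11, impulsivity = 27)
  scores <- data.frame(subject_id = c("s001", "s002"),
                       blatant_sum = c(12L, 20L), subtle_sum = c(30L, 28L))
  tab <- build_stay_table(list(d, d2), scores, "blatant")
  expect_equal(nrow(tab), 4L)  # sum of (n_trials - 1)
  expect_equal(tab$stay[tab$subject_id == "s001"], c(1L, 0L))
  expect_equal(tab$stay[tab$subject_id == "s002"], c(1L, 1L))
  # previous-trial coding: trial 1 of s001 was rewarded & common
  expect_equal(tab$prev_outcome[1], 0.5)
  expect_equal(tab$prev_transition[1], 0.5)
  # prejudice is log-transformed and centered across subjects
  expect_equal(mean(unique(tab$prejudice_log)), 0, tolerance = 1e-12)
  expect_equal(diff(unique(tab$prejudice_log)), log(20) - log(12),
               tolerance = 1e-12)
  # subjects without a score are dropped with a record
  tab2 <- build_stay_table(list(d, d2), scores[1, ], "blatant")
  expect_equal(attr(tab2, "dropped"), "s002")
})

test_that("RT filter drops strictly-faster-than-250 rows", {
  df <- data.frame(rt2 = c(200, 250, 300))
  out <- filter_rt(df)
  expect_equal(out$rt2, c(250, 300))
  expect_equal(attr(out, "n_removed"), 1L)
  ok <- data.frame(rt2 = c(260, 500))
  expect_equal(nrow(filter_rt(ok)), 2L)
  expect_error(filter_rt(data.frame(rt2 = c(100, 150))), "inspect")
})

test_that("RT model recovers the planted slowing and coding invariance holds", {
  gen <- quick_cohort(14, seed = 53)
  scores <- make_scores(gen)
  tab <- build_rt_table(gen$cohort, scores, "blatant")
  expect_true(all(tab$rt2 >= 250))
  res <- fit_rt_model(tab)
  # rare-trial slowing: negative transition coefficient under common=+0.5
  est <- function(r, term) r$estimate[r$term == term]
  expect_lt(est(res, "transition"), 0)
  # flipping the transition coding flips exactly the transition terms
  tab_f <- tab; tab_f$transition <- -tab_f$transition
  res_f <- fit_rt_model(tab_f)
  expect_equal(est(res_f, "transition"), -est(res, "transition"),
               tolerance = 1e-4)
  expect_equal(est(res_f, "transition:prejudice_log"),
               -est(res, "transition:prejudice_log"), tolerance = 1e-4)
  expect_equal(est(res_f, "prejudice_log"), est(res, "prejudice_log"),
               tolerance = 1e-4)
  expect_equal(est(res_f, "(Intercept)"), est(res, "(Intercept)"),
               tolerance = 1e-4)
  # residual summary returns finite shape statistics
  rs <- residual_summary(attr(res, "model"))
  expect_true(all(is.finite(rs)))
})

test_that("constant RTs give zero slope coefficients", {
  gen <- quick_cohort(6, seed = 59, n_trials = 60L)
  for (i in seq_along(gen$cohort)) gen$cohort[[i]]$trials$rt2_ms <- 600
  tab <- build_rt_table(gen$cohort, make_scores(gen), "blatant")
  res <- fit_rt_model(tab)
  slopes <- res$estimate[res$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-6))
})

test_that("stay GLMM detects the model-based signature", {
  # strongly model-based agents: high-w generating prior
  spec <- cohort_spec(n_subjects = 20, seed = 61,
                      prior = group_prior(
                        c(0, 0, log(5), log(5), 0, 2.5, 0.1),
                        c(0.5, 0.5, 0.04, 0.04, 0.5, 0.09, 0.01)))
  gen_mb <- generate_cohort(spec)
  scores <- score_items_table(gen_mb$items)
  tab <- build_stay_table(gen_mb$cohort, scores, "blatant")
  res <- fit_stay_glmm(tab, nAGQ = 0)
  expect_gt(res$estimate[res$term == "prev_transition:prev_outcome"], 0)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$ci_lo <= res$r2beta & res$r2beta <= res$ci_hi))
})

test_that("semipartial R2-beta is bounded and monotone in the statistic", {
  r <- twostepr:::r2beta_semipartial(c(0, 1, 3, 10), n = 500, rank_x = 8)
  expect_true(all(r$point >= 0 & r$point <= 1))
  expect_true(all(diff(r$point) > 0))          # grows with |t|
  expect_true(all(r$lo <= r$point & r$point <= r$hi))
  # attenuating a coefficient (smaller |t|) shrinks the effect size
  expect_lt(twostepr:::r2beta_semipartial(1.2, 500, 8)$point,
            twostepr:::r2beta_semipartial(2.4, 500, 8)$point)
})

test_that("parameter regressions find the planted coupling from true params", {
  gen <- quick_cohort(80, seed = 67, n_trials = 10L)
  scores <- make_scores(gen)
  truth <- gen$truth$params
  res <- fit_param_regressions(truth, scores, gen$covariates, "blatant")
  expect_equal(attr(res, "alpha_bonferroni"), 0.0125)
  expect_lt(res$w$estimate[res$w$term == "prejudice_log"], 0)
  expect_true(attr(res, "significant")[["w"]])
  # zero-variance parameter is skipped with a warning
  truth$alpha1 <- 0.5
  expect_warning(res2 <- fit_param_regressions(truth, scores, gen$covariates),
                 "zero variance")
  expect_null(res2$alpha1)
})

test_that("design diagnostics flag collinearity and outliers", {
  set.seed(71)
  X <- data.frame(a = rnorm(500), b = rnorm(500))
  d <- design_diagnostics(X)
  expect_true(all(d$vif < 1.2))
  expect_false(d$vif_flag)
  # duplicated predictor: infinite VIF
  X2 <- X; X2$c <- X2$a
  d2 <- design_diagnostics(X2)
  expect_true(d2$vif_flag)
  expect_true(d2$singular)
  # standard normal tail mass beyond 3 SD is about 0.27%
  set.seed(73)
  z <- data.frame(z = rnorm(10000))
  dz <- design_diagnostics(z)
  rate <- length(dz$outliers$z) / 10000
  expect_gt(rate, 0.0005)
  expect_lt(rate, 0.006)
})
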