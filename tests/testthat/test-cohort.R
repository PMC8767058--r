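test_that("cohort_spec validates the stated world", {
  spec <- cohort_spec()
  expect_equal(spec$n_subjects, 127L)
  expect_equal(spec$task$n_trials, 201L)
  expect_lt(spec$coupling_b, 0)
  expect_error(cohort_spec(n_subjects = 1), ">= 2")
  expect_error(cohort_spec(rt_base_ms = 300, rt_noise_sd = 120), "250")
})

test_that("subject parameter draws respect bounds and the prior mean", {
  spec <- cohort_spec(n_subjects = 10000, seed = 79)
  set.seed(79)
  draws <- draw_subject_params(spec)
  p <- draws$params
  expect_true(all(p[, c("alpha1", "alpha2", "lam", "w")] >= 0 &
                    p[, c("alpha1", "alpha2", "lam", "w")] <= 1))
  expect_true(all(p[, c("beta1", "beta2")] > 0))
  # Monte-Carlo mean of w matches the transformed-prior expectation
  mu_w <- spec$prior$mu[["w"]]; sd_w <- sqrt(spec$prior$sigma2[["w"]])
  expected <- mean(plogis(rnorm(200000, mu_w, sd_w)))
  expect_lt(abs(mean(p[, "w"]) - expected), 0.01)
  # near-degenerate prior collapses every subject onto the mean
  spec0 <- cohort_spec(n_subjects = 5,
                       prior = group_prior(rep(0, 7), rep(1e-12, 7)))
  set.seed(1)
  d0 <- draw_subject_params(spec0)
  expect_lt(max(apply(d0$params, 2, sd)), 1e-5)
})

test_that("prejudice generation plants the requested coupling", {
  spec <- cohort_spec(n_subjects = 1000, seed = 83)
  set.seed(83)
  z_w <- rnorm(1000, 0, 1.2)
  pr <- generate_prejudice(z_w, spec)
  expect_true(all(pr$scores$blatant_sum >= 10 & pr$scores$blatant_sum <= 50))
  expect_true(all(pr$scores$subtle_sum >= 10 & pr$scores$subtle_sum <= 50))
  expect_lt(cor(z_w, pr$scores$blatant_sum, method = "spearman"), -0.3)
  # item responses are consistent with the sums under the default key
  rescored <- score_items_table(pr$items[pr$items$subject_id %in%
                                           sprintf("s%03d", 1:50), ])
  m <- match(rescored$subject_id, pr$scores$subject_id)
  expect_equal(rescored$blatant_sum, pr$scores$blatant_sum[m])
  expect_equal(rescored$subtle_sum, pr$scores$subtle_sum[m])
  # null coupling: no association
  spec0 <- cohort_spec(coupling_b = 0)
  set.seed(85)
  pr0 <- generate_prejudice(z_w, spec0)
  expect_lt(abs(cor(z_w, pr0$scores$blatant_sum)), 0.1)
})

test_that("reaction-time law produces w-proportional rare slowing", {
  spec <- cohort_spec()
  set.seed(89)
  trans <- sample(c("common", "rare"), 20000, TRUE, prob = c(0.7, 0.3))
  rt1 <- generate_rts(1, trans, spec)
  gap <- mean(rt1[trans == "rare"]) - mean(rt1[trans == "common"])
  expect_lt(abs(gap - spec$rt_rare_slow_ms), 10)
  rt0 <- generate_rts(0, trans, spec)
  gap0 <- mean(rt0[trans == "rare"]) - mean(rt0[trans == "common"])
  expect_lt(abs(gap0), 10)
  # zero noise: deterministic values
  spec_d <- cohort_spec(rt_noise_sd = 1e-9)
  expect_equal(generate_rts(0.5, c("common", "rare"), spec_d),
               c(700, 850), tolerance = 1e-6)
})

test_that("generate_cohort is seeded, aligned and complete", {
  g1 <- quick_cohort(4, seed = 97, n_trials = 50L)
  g2 <- quick_cohort(4, seed = 97, n_trials = 50L)
  expect_identical(g1$cohort[[2]]$trials, g2$cohort[[2]]$trials)
  expect_identical(g1$scores, g2$scores)
  expect_equal(length(g1$cohort), 4L)
  expect_equal(nrow(g1$cohort[[1]]$trials), 50L)
  expect_equal(g1$truth$params$subject_id,
               vapply(g1$cohort, function(d) d$subject_id, character(1)))
  expect_true(all(is.finite(g1$cohort[[1]]$trials$rt2_ms)))
  # minimal two-subject run completes
  expect_silent(gmin <- quick_cohort(2, seed = 98, n_trials = 5L))
  expect_equal(length(gmin$cohort), 2L)
})

test_that("recovery_report scores alignment and planted signs", {
  gen <- quick_cohort(25, seed = 101, n_trials = 30L)
  # feed the truth back as a perfect fit
  perfect <- list(subject_fits = lapply(seq_len(25), function(i) {
    structure(list(subject_id = gen$truth$params$subject_id[i],
                   params = unlist(gen$truth$params[i, twostepr:::PARAM_NAMES]),
                   z_map = rep(0, 7)), class = "subject_fit")
  }))
  rep <- recovery_report(gen$truth, perfect)
  expect_true(all(abs(rep$param_recovery$pearson - 1) < 1e-12))
  # shuffling the fits destroys the correlations
  shuffled <- perfect
  set.seed(5)
  shuffled$subject_fits <- shuffled$subject_fits[sample(25)]
  for (i in seq_len(25))
    shuffled$subject_fits[[i]]$subject_id <- gen$truth$params$subject_id[i]
  rep_s <- recovery_report(gen$truth, shuffled)
  expect_lt(max(abs(rep_s$param_recovery$pearson)), 0.6)
  # misaligned ids raise
  bad <- perfect
  bad$subject_fits[[1]]$subject_id <- "zzz"
  expect_error(recovery_report(gen$truth, bad), "align")
})
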