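#' Session negative log-likelihood of the hybrid model
#'
#' Runs the agent's update equations forward over the observed trial events
#' and sums `-log P(choice1) - log P(choice2)` across trials. The transition
#' model (p_common / 1 - p_common) is fixed and known to the agent.
#'
#' @param params an [agent_params()] or named numeric vector with the seven
#'   parameter fields.
#' @param data a `subject_dataset`.
#' @param p_common common-transition probability of the task (default 0.7).
#' @return scalar negative log-likelihood.
#' @export
session_nll <- function(params, data, p_common = 0.7) {
  tr <- data$trials
  bad <- tr$transition != transition_label(tr$choice1, tr$state2)
  if (any(bad)) stop("dataset has inconsistent transition labels", call. = FALSE)
  nll_hybrid_cpp(as.numeric(params[PARAM_NAMES]),
                 as.integer(tr$choice1), as.integer(tr$state2),
                 as.integer(tr$choice2), as.integer(tr$outcome), p_common)
}

#' Group-level Gaussian prior in unconstrained space
#'
#' @param mu length-7 mean vector (order alpha1, alpha2, beta1, beta2, lam,
#'   w, rho).
#' @param sigma2 length-7 positive variance vector.
#' @return object of class `group_prior`.
#' @export
group_prior <- function(mu = rep(0, 7), sigma2 = rep(6.25, 7)) {
  stopifnot(length(mu) == 7L, length(sigma2) == 7L, all(sigma2 > 0))
  mu <- as.numeric(mu); sigma2 <- as.numeric(sigma2)
  names(mu) <- names(sigma2) <- PARAM_NAMES
  structure(list(mu = mu, sigma2 = sigma2), class = "group_prior")
}

#' Optimizer and EM settings
#'
#' @param n_starts random restarts per subject MAP fit (first start is the
#'   prior mean, or the warm start when one is supplied).
#' @param optim_reltol relative tolerance passed to `optim`.
#' @param optim_maxit maximum BFGS iterations.
#' @param em_tol EM stops when `max |delta mu| < em_tol`.
#' @param em_max_iter maximum EM iterations.
#' @param sigma2_floor lower bound applied to group variances in the M-step.
#' @param hess_h central-difference step for the Laplace Hessian.
#' @param hess_floor eigenvalue floor used to repair non-positive-definite
#'   Hessians.
#' @return list of settings.
#' @export
fit_settings <- function(n_starts = 4L, optim_reltol = 1e-6,
                         optim_maxit = 500L, em_tol = 1e-3,
                         em_max_iter = 200L, sigma2_floor = 1e-4,
                         hess_h = 1e-4, hess_floor = 1e-6) {
  list(n_starts = as.integer(n_starts), optim_reltol = optim_reltol,
       optim_maxit = as.integer(optim_maxit), em_tol = em_tol,
       em_max_iter = as.integer(em_max_iter), sigma2_floor = sigma2_floor,
       hess_h = hess_h, hess_floor = hess_floor)
}

# negative log posterior over the model's free dimensions, using the
# normalized Gaussian prior so the penalty is nonnegative up to the constant
neg_log_post <- function(z_free, data_tr, prior, model, p_common) {
  p <- expand_params(z_free, model)
  nll <- nll_hybrid_cpp(as.numeric(p), data_tr$choice1, data_tr$state2,
                        data_tr$choice2, data_tr$outcome, p_common)
  mu <- prior$mu[model$free]; s2 <- prior$sigma2[model$free]
  nll + 0.5 * sum((z_free - mu)^2 / s2 + log(2 * pi * s2))
}

# central-difference Hessian; f is scalar-valued
hessian_central <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(NA_real_, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1L) for (j in seq_len(i - 1L)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  H
}

# Laplace covariance with a principled positive-definiteness repair: the
# posterior Hessian is the likelihood Hessian plus the (diagonal) prior
# precision, so we PSD-project only the likelihood part and add the prior
# precision back. This caps the Laplace variance at the prior variance in
# every direction, which keeps the EM variance update stable when a
# subject's data are uninformative about some parameter.
laplace_cov_from_hessian <- function(H_post, prior_prec, floor = 1e-6) {
  H_lik <- (H_post + t(H_post)) / 2 - diag(prior_prec, length(prior_prec))
  eg <- eigen(H_lik, symmetric = TRUE)
  vals <- pmax(eg$values, floor)
  H_fixed <- eg$vectors %*% diag(vals, length(vals)) %*% t(eg$vectors) +
    diag(prior_prec, length(prior_prec))
  list(cov = solve(H_fixed), repaired = any(eg$values < floor))
}

#' Per-subject maximum a posteriori fit
#'
#' Minimizes the session negative log-likelihood plus the Gaussian negative
#' log prior in unconstrained space (BFGS, best of `n_starts`
#' initializations) and attaches a Laplace covariance from the inverted
#' central-difference Hessian at the optimum.
#'
#' @param data a `subject_dataset`.
#' @param prior a [group_prior()].
#' @param model a [model_spec()].
#' @param settings a [fit_settings()].
#' @param p_common task transition probability.
#' @param init optional warm-start vector in the full 7-dim unconstrained
#'   space; replaces the prior-mean start.
#' @return object of class `subject_fit`: `z_map` (length 7; fixed entries
#'   carry the pinning value's transform or NA), `params`, `neg_log_post`,
#'   `neg_log_lik`, `laplace_cov` (free dims), `converged`, `model`.
#' @export
map_fit <- function(data, prior, model = model_spec("hybrid"),
                    settings = fit_settings(), p_common = 0.7,
                    init = NULL) {
  tr <- data$trials
  dat <- list(choice1 = as.integer(tr$choice1), state2 = as.integer(tr$state2),
              choice2 = as.integer(tr$choice2), outcome = as.integer(tr$outcome))
  free <- model$free
  obj <- function(z) neg_log_post(z, dat, prior, model, p_common)
  starts <- vector("list", settings$n_starts)
  starts[[1L]] <- if (is.null(init)) prior$mu[free] else init[free]
  if (settings$n_starts > 1L)
    for (k in 2L:settings$n_starts)
      starts[[k]] <- stats::rnorm(length(free), prior$mu[free],
                                  sqrt(prior$sigma2[free]))
  best <- NULL; any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "BFGS",
                   control = list(reltol = settings$optim_reltol,
                                  maxit = settings$optim_maxit)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  z_free <- best$par
  H <- hessian_central(obj, z_free, settings$hess_h)
  inv <- laplace_cov_from_hessian(H, 1 / prior$sigma2[free],
                                  settings$hess_floor)
  params <- expand_params(z_free, model)
  z_map <- rep(NA_real_, 7L); names(z_map) <- PARAM_NAMES
  z_map[free] <- z_free
  nll <- nll_hybrid_cpp(as.numeric(params), dat$choice1, dat$state2,
                        dat$choice2, dat$outcome, p_common)
  structure(list(subject_id = data$subject_id, z_map = z_map, params = params,
                 neg_log_post = best$value, neg_log_lik = nll,
                 laplace_cov = inv$cov, hessian_repaired = inv$repaired,
                 converged = any_conv, model = model$name),
            class = "subject_fit")
}

#' Hierarchical empirical-Bayes expectation maximization
#'
#' Alternates an E-step (per-subject MAP fits with Laplace covariances under
#' the current group prior) with an M-step that re-estimates the Gaussian
#' prior: `mu <- mean(z_map)`, `sigma2 <- mean(z_map^2 + diag(cov)) - mu^2`
#' (floored). After the first iteration subject fits are warm-started from
#' their previous optimum and a single start is used.
#'
#' @param cohort list of `subject_dataset` (>= 2 subjects).
#' @param model a [model_spec()] or model name.
#' @param settings a [fit_settings()].
#' @param prior0 initial [group_prior()].
#' @param p_common task transition probability.
#' @param verbose print per-iteration progress.
#' @return object of class `model_fit_result`: final `prior`,
#'   `subject_fits`, `ibic` (NA until [ibic()] is called), `n_em_iterations`,
#'   `model_name`, `trace` (per-iteration mu and penalized objective).
#' @export
em_fit <- function(cohort, model = model_spec("hybrid"),
                   settings = fit_settings(), prior0 = group_prior(),
                   p_common = 0.7, verbose = FALSE) {
  if (is.character(model)) model <- model_spec(model)
  if (length(cohort) < 2L) stop("EM needs at least 2 subjects", call. = FALSE)
  prior <- prior0
  free <- model$free
  fits <- vector("list", length(cohort))
  warm <- vector("list", length(cohort))
  trace <- list()
  n_iter <- 0L
  for (iter in seq_len(settings$em_max_iter)) {
    n_iter <- iter
    iter_settings <- settings
    if (iter > 1L) iter_settings$n_starts <- 1L
    for (i in seq_along(cohort)) {
      fits[[i]] <- map_fit(cohort[[i]], prior, model, iter_settings,
                           p_common, init = warm[[i]])
      warm[[i]] <- fits[[i]]$z_map
    }
    Z <- do.call(rbind, lapply(fits, function(f) f$z_map[free]))
    V <- do.call(rbind, lapply(fits, function(f) diag(f$laplace_cov)))
    mu_new <- colMeans(Z)
    s2_new <- pmax(colMeans(Z^2 + V) - mu_new^2, settings$sigma2_floor)
    if (any(!is.finite(mu_new)) || any(!is.finite(s2_new)))
      stop("EM diverged (non-finite group prior) at iteration ", iter,
           call. = FALSE)
    obj <- sum(vapply(fits, function(f) f$neg_log_post, numeric(1)))
    trace[[iter]] <- list(mu = mu_new, sigma2 = s2_new, penalized_nll = obj)
    delta <- max(abs(mu_new - prior$mu[free]))
    mu_full <- prior$mu; s2_full <- prior$sigma2
    mu_full[free] <- mu_new; s2_full[free] <- s2_new
    prior <- group_prior(mu_full, s2_full)
    if (verbose)
      message(sprintf("EM iter %d: max|dmu| = %.5f, obj = %.2f",
                      iter, delta, obj))
    if (delta < settings$em_tol) break
  }
  structure(list(prior = prior, subject_fits = fits, ibic = NA_real_,
                 n_em_iterations = n_iter, model_name = model$name,
                 model = model, trace = trace, settings = settings,
                 p_common = p_common),
            class = "model_fit_result")
}

#' @export
print.model_fit_result <- function(x, ...) {
  cat("<model_fit_result>", x$model_name, "-", length(x$subject_fits),
      "subjects,", x$n_em_iterations, "EM iterations\n")
  if (is.finite(x$ibic)) cat("  iBIC:", format(x$ibic), "\n")
  invisible(x)
}

#' Integrated BIC for a hierarchical fit
#'
#' Approximates each subject's marginal likelihood under the fitted group
#' prior by Monte-Carlo sampling in unconstrained space, and penalizes the
#' group-level parameter count: `iBIC = -2 * sum_s log p_hat(data_s | prior)
#' + k * log(N)` with `k = 2 * (number of free parameters)` (a mean and a
#' variance per dimension) and `N` the total number of observed choices
#' (two per trial).
#'
#' @param result a `model_fit_result`.
#' @param cohort the list of `subject_dataset` the model was fitted to.
#' @param n_samples prior samples per subject (default 1000).
#' @return the `model_fit_result` with `ibic`, `ibic_n_samples` and
#'   `log_marginals` filled in.
#' @export
ibic <- function(result, cohort, n_samples = 1000L) {
  stopifnot(inherits(result, "model_fit_result"))
  model <- result$model
  free <- model$free
  prior <- result$prior
  n_obs <- sum(vapply(cohort, function(d) 2L * nrow(d$trials), integer(1)))
  logm <- numeric(length(cohort))
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]$trials
    c1 <- as.integer(tr$choice1); s2i <- as.integer(tr$state2)
    c2 <- as.integer(tr$choice2); oc <- as.integer(tr$outcome)
    ll <- numeric(n_samples)
    for (k in seq_len(n_samples)) {
      zf <- stats::rnorm(length(free), prior$mu[free], sqrt(prior$sigma2[free]))
      p <- expand_params(zf, model)
      ll[k] <- -nll_hybrid_cpp(as.numeric(p), c1, s2i, c2, oc, result$p_common)
    }
    mx <- max(ll)
    logm[i] <- mx + log(mean(exp(ll - mx)))
  }
  k_group <- 2L * length(free)
  result$ibic <- -2 * sum(logm) + k_group * log(n_obs)
  result$ibic_n_samples <- as.integer(n_samples)
  result$log_marginals <- logm
  result
}

#' Posterior predictive stay-probability check
#'
#' Simulates `n_sim` fresh sessions per subject from the fitted parameters
#' (new reward walks each time) and compares the simulated stay
#' probabilities in the four previous-outcome x previous-transition cells
#' with the observed ones.
#'
#' @param result a `model_fit_result`.
#' @param cohort observed `subject_dataset` list (same order as the fits).
#' @param config a [task_config()] used for the simulations.
#' @param n_sim simulations per subject (>= 1).
#' @return data.frame with one row per subject x cell: `subject_id`,
#'   `prev_outcome`, `prev_transition`, `observed`, `simulated`.
#' @export
posterior_predictive <- function(result, cohort, config = task_config(),
                                 n_sim = 20L) {
  if (n_sim < 1L) stop("`n_sim` must be >= 1", call. = FALSE)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    fit <- result$subject_fits[[i]]
    obs <- stay_probabilities(cohort[[i]])
    sims <- matrix(NA_real_, n_sim, 4L)
    for (k in seq_len(n_sim)) {
      walks <- generate_reward_walks(config)
      sim <- simulate_agent(do.call(agent_params, as.list(fit$params)),
                            config, walks)
      sims[k, ] <- stay_probabilities(sim)$p_stay
    }
    obs$simulated <- colMeans(sims, na.rm = TRUE)
    names(obs)[names(obs) == "p_stay"] <- "observed"
    obs$subject_id <- cohort[[i]]$subject_id
    rows[[i]] <- obs[, c("subject_id", "prev_outcome", "prev_transition",
                         "observed", "simulated")]
  }
  do.call(rbind, rows)
}
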