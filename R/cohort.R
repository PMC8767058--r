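#' Specification of a synthetic study cohort
#'
#' States the world the generator emulates: 127 subjects performing 201
#' trials, agent parameters drawn from a group prior whose transformed means
#' sit in the canonical range for this task (mean w near 0.5, inverse
#' temperatures near 4), an integer blatant prejudice sum in \[10, 50\]
#' whose log is negatively coupled to the subject's unconstrained
#' model-based weight, an uncoupled subtle sum, second-stage reaction times
#' slowed on rare transitions in proportion to w, and covariates matching
#' the reference sample (impulsivity 28.8 +/- 5.14, digit span backward
#' 10.77 +/- 2.84, digit-symbol substitution 11.45 +/- 2.67).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param task a [task_config()].
#' @param prior generating [group_prior()] in unconstrained space.
#' @param coupling_b slope of log blatant score on the unconstrained w
#'   (negative by default: higher prejudice, less model-based control).
#' @param coupling_noise_sd SD of the log-score noise.
#' @param coupling_intercept intercept of the log score (default `log(14)`,
#'   centering raw scores near the reference median split).
#' @param subtle_log_mean,subtle_log_sd log-normal settings of the
#'   uncoupled subtle score.
#' @param rt_base_ms,rt_rare_slow_ms,rt_noise_sd second-stage RT law:
#'   `rt2 = base + w * slow * 1[rare] + N(0, sd^2)`, floored at 50 ms.
#' @param rt1_base_ms,rt1_noise_sd first-stage RT law (base + noise).
#' @param covariate_means,covariate_sds named numeric vectors for
#'   `cognitive_speed`, `working_memory`, `impulsivity`.
#' @param seed RNG seed for the whole cohort.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 127L,
                        task = task_config(),
                        prior = default_generating_prior(),
                        coupling_b = -0.25,
                        coupling_noise_sd = 0.30,
                        coupling_intercept = log(14),
                        subtle_log_mean = log(30), subtle_log_sd = 0.25,
                        rt_base_ms = 700, rt_rare_slow_ms = 300,
                        rt_noise_sd = 120,
                        rt1_base_ms = 800, rt1_noise_sd = 150,
                        covariate_means = c(cognitive_speed = 11.45,
                                            working_memory = 10.77,
                                            impulsivity = 28.8),
                        covariate_sds = c(cognitive_speed = 2.67,
                                          working_memory = 2.84,
                                          impulsivity = 5.14),
                        seed = 20201L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (!is.finite(coupling_b) || !is.finite(coupling_noise_sd))
    stop("coupling settings must be finite", call. = FALSE)
  if (rt_base_ms <= 250 + 3 * rt_noise_sd)
    stop("rt_base_ms must exceed 250 + 3 * rt_noise_sd so the 250 ms filter ",
         "removes only a small tail", call. = FALSE)
  structure(list(n_subjects = n_subjects, task = task, prior = prior,
                 coupling_b = coupling_b,
                 coupling_noise_sd = coupling_noise_sd,
                 coupling_intercept = coupling_intercept,
                 subtle_log_mean = subtle_log_mean,
                 subtle_log_sd = subtle_log_sd,
                 rt_base_ms = rt_base_ms, rt_rare_slow_ms = rt_rare_slow_ms,
                 rt_noise_sd = rt_noise_sd, rt1_base_ms = rt1_base_ms,
                 rt1_noise_sd = rt1_noise_sd,
                 covariate_means = covariate_means,
                 covariate_sds = covariate_sds,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generating group prior with canonical transformed means
#'
#' Unconstrained means transform to alpha1 ~ 0.5, alpha2 ~ 0.4, betas ~ 4,
#' lam ~ 0.5, w ~ 0.5, rho ~ 0.2; SDs give realistic between-subject spread
#' (w covers most of the unit interval).
#'
#' @return a [group_prior()].
#' @export
default_generating_prior <- function() {
  mu <- c(alpha1 = 0, alpha2 = stats::qlogis(0.4), beta1 = log(4),
          beta2 = log(4), lam = 0, w = 0, rho = 0.2)
  sd <- c(alpha1 = 1.0, alpha2 = 1.0, beta1 = 0.35, beta2 = 0.35,
          lam = 1.0, w = 1.2, rho = 0.3)
  group_prior(mu, sd^2)
}

#' Draw per-subject agent parameters from the group prior
#'
#' @param spec a [cohort_spec()].
#' @return list with `z` (n x 7 matrix of unconstrained draws) and `params`
#'   (n x 7 matrix on the natural scale).
#' @export
draw_subject_params <- function(spec) {
  n <- spec$n_subjects
  mu <- spec$prior$mu; s <- sqrt(spec$prior$sigma2)
  z <- matrix(stats::rnorm(n * 7L), n, 7L)
  z <- sweep(sweep(z, 2L, s, "*"), 2L, mu, "+")
  colnames(z) <- PARAM_NAMES
  params <- t(apply(z, 1L, z_to_params))
  list(z = z, params = params)
}

#' Generate prejudice sums coupled to the model-based weight
#'
#' Plants the association under study: `log(blatant) = a + b * z_w + noise`,
#' exponentiated, rounded and clipped to \[10, 50\] (the clip at the scale
#' floor reproduces the strongly right-skewed empirical distribution). The
#' subtle sum is drawn uncoupled. Item-level responses consistent with each
#' sum are back-filled via [items_for_sum()].
#'
#' @param z_w vector of unconstrained model-based weights.
#' @param spec a [cohort_spec()].
#' @param key scoring key (defaults to the shipped key).
#' @return list with `scores` (data.frame subject_id, blatant_sum,
#'   subtle_sum) and `items` (long data.frame subject_id, item_id, level).
#' @export
generate_prejudice <- function(z_w, spec, key = default_scale_key()) {
  n <- length(z_w)
  log_blat <- spec$coupling_intercept + spec$coupling_b * z_w +
    stats::rnorm(n, 0, spec$coupling_noise_sd)
  blat <- pmin(pmax(round(exp(log_blat)), 10L), 50L)
  subt <- pmin(pmax(round(exp(stats::rnorm(n, spec$subtle_log_mean,
                                           spec$subtle_log_sd))), 10L), 50L)
  ids <- sprintf("s%03d", seq_len(n))
  kb <- key[key$scale == "blatant", ]
  ks <- key[key$scale == "subtle", ]
  items <- vector("list", n)
  for (i in seq_len(n)) {
    lb <- items_for_sum(blat[i], kb)
    ls <- items_for_sum(subt[i], ks)
    items[[i]] <- data.frame(subject_id = ids[i],
                             item_id = c(names(lb), names(ls)),
                             level = c(unname(lb), unname(ls)),
                             stringsAsFactors = FALSE)
  }
  list(scores = data.frame(subject_id = ids, blatant_sum = as.integer(blat),
                           subtle_sum = as.integer(subt),
                           stringsAsFactors = FALSE),
       items = do.call(rbind, items))
}

#' Generate second-stage reaction times
#'
#' `rt2 = rt_base_ms + w * rt_rare_slow_ms * 1[rare] + N(0, rt_noise_sd^2)`,
#' floored at 50 ms: subjects slow on rare transitions in proportion to
#' their model-based weight. A generative stand-in for the observed RT
#' pattern, not a mechanistic claim.
#'
#' @param w model-based weight of the subject.
#' @param transitions character vector of "common"/"rare" labels.
#' @param spec a [cohort_spec()].
#' @return numeric vector of RTs in milliseconds.
#' @export
generate_rts <- function(w, transitions, spec) {
  n <- length(transitions)
  rt <- spec$rt_base_ms + w * spec$rt_rare_slow_ms * (transitions == "rare") +
    stats::rnorm(n, 0, spec$rt_noise_sd)
  pmax(rt, 50)
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from the spec, draws agent parameters, simulates sessions,
#' attaches generated reaction times and covariates, plants the prejudice
#' coupling and back-fills item responses.
#'
#' @param spec a [cohort_spec()].
#' @param key questionnaire scoring key.
#' @return list with `cohort` (list of `subject_dataset`), `scores`,
#'   `items`, `covariates` (data.frame) and `truth` (list: `z`, `params`,
#'   `spec`).
#' @export
generate_cohort <- function(spec = cohort_spec(), key = default_scale_key()) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  ids <- sprintf("s%03d", seq_len(n))
  draws <- draw_subject_params(spec)
  prej <- generate_prejudice(draws$z[, "w"], spec, key)
  cm <- spec$covariate_means; cs <- spec$covariate_sds
  covs <- data.frame(
    subject_id = ids,
    cognitive_speed = stats::rnorm(n, cm[["cognitive_speed"]], cs[["cognitive_speed"]]),
    working_memory = stats::rnorm(n, cm[["working_memory"]], cs[["working_memory"]]),
    impulsivity = stats::rnorm(n, cm[["impulsivity"]], cs[["impulsivity"]]),
    stringsAsFactors = FALSE)
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- do.call(agent_params, as.list(draws$params[i, ]))
    walks <- generate_reward_walks(spec$task)
    ds <- simulate_agent(pars, spec$task, walks, subject_id = ids[i])
    ds$trials$rt2_ms <- generate_rts(draws$params[i, "w"],
                                     ds$trials$transition, spec)
    ds$trials$rt1_ms <- pmax(spec$rt1_base_ms +
                               stats::rnorm(spec$task$n_trials, 0,
                                            spec$rt1_noise_sd), 50)
    ds$covariates <- c(cognitive_speed = covs$cognitive_speed[i],
                       working_memory = covs$working_memory[i],
                       impulsivity = covs$impulsivity[i])
    cohort[[i]] <- ds
  }
  truth_params <- as.data.frame(draws$params)
  truth_params$subject_id <- ids
  truth_z <- as.data.frame(draws$z)
  truth_z$subject_id <- ids
  list(cohort = cohort, scores = prej$scores, items = prej$items,
       covariates = covs,
       truth = list(params = truth_params, z = truth_z, spec = spec))
}

#' Recovery report for a fitted synthetic cohort
#'
#' Compares generating and recovered parameters (Pearson and Spearman
#' correlations per parameter) and collects the sign and p-value of the
#' planted prejudice effect in each supplied analysis: the stay-GLMM
#' three-way interaction, the RT transition-by-prejudice interaction, and
#' the w-on-prejudice regression.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param fit_result a `model_fit_result` on the same subjects (same order).
#' @param analyses optional named list with entries `stay`, `rt`
#'   (`regression_result`s) and `param` (list from
#'   [fit_param_regressions()]).
#' @return list with `param_recovery` (data.frame), `effects` (data.frame
#'   of term, estimate, p, sign per analysis) and `signs_agree` (logical:
#'   every reported effect matches the generative coupling direction).
#' @export
recovery_report <- function(truth, fit_result, analyses = NULL) {
  fitted <- fits_to_df(fit_result)
  if (!identical(sort(fitted$subject_id), sort(truth$params$subject_id)))
    stop("subject ids of truth and fits do not align", call. = FALSE)
  m <- match(truth$params$subject_id, fitted$subject_id)
  rec <- do.call(rbind, lapply(PARAM_NAMES, function(par) {
    tv <- truth$params[[par]]; fv <- fitted[[par]][m]
    data.frame(param = par,
               pearson = suppressWarnings(stats::cor(tv, fv)),
               spearman = suppressWarnings(stats::cor(tv, fv, method = "spearman")),
               stringsAsFactors = FALSE)
  }))
  effects <- NULL
  if (!is.null(analyses)) {
    pick <- function(res, term, label) {
      row <- res[res$term == term, , drop = FALSE]
      if (!nrow(row)) return(NULL)
      data.frame(analysis = label, term = term, estimate = row$estimate,
                 p = row$p, sign = sign(row$estimate),
                 stringsAsFactors = FALSE)
    }
    effects <- rbind(
      if (!is.null(analyses$stay))
        pick(analyses$stay, "prev_transition:prev_outcome:prejudice_log", "stay_glmm"),
      if (!is.null(analyses$rt))
        pick(analyses$rt, "transition:prejudice_log", "rt_model"),
      if (!is.null(analyses$param))
        pick(analyses$param$w, "prejudice_log", "w_regression"))
  }
  expected <- c(stay_glmm = sign(truth$spec$coupling_b),
                rt_model = -sign(truth$spec$coupling_b),
                w_regression = sign(truth$spec$coupling_b))
  agree <- if (is.null(effects)) NA else
    all(effects$sign == expected[effects$analysis])
  list(param_recovery = rec, effects = effects, signs_agree = agree,
       coupling_b = truth$spec$coupling_b)
}
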