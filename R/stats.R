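#' Build the lag-1 stay/switch table
#'
#' For every trial after the first, records whether the stage-1 choice
#' repeated the previous trial's choice, together with the previous trial's
#' outcome and transition (effect-coded: reward/common = +0.5,
#' no-reward/rare = -0.5), the subject's log-transformed, mean-centered
#' prejudice sum, and the three covariates (z-scored across subjects).
#'
#' @param cohort list of `subject_dataset` with >= 2 trials each and a
#'   `covariates` entry holding `cognitive_speed`, `working_memory`,
#'   `impulsivity`.
#' @param scores data.frame with `subject_id`, `blatant_sum`, `subtle_sum`.
#' @param scale which prejudice scale enters the model.
#' @return data.frame (class `stay_table`) with columns `subject_id`,
#'   `stay`, `prev_outcome`, `prev_transition`, `prejudice_log`,
#'   `cognitive_speed`, `working_memory`, `impulsivity`. Subjects without a
#'   score are dropped (ids recorded in `attr(, "dropped")`).
#' @export
build_stay_table <- function(cohort, scores, scale = c("blatant", "subtle")) {
  scale <- match.arg(scale)
  score_col <- paste0(scale, "_sum")
  ids <- vapply(cohort, function(d) d$subject_id, character(1))
  keep <- ids %in% scores$subject_id
  dropped <- ids[!keep]
  cohort <- cohort[keep]; ids <- ids[keep]
  sums <- scores[[score_col]][match(ids, scores$subject_id)]
  prej <- log_scale(sums)
  prej <- prej - mean(prej)
  cov_mat <- t(vapply(cohort, function(d) {
    cv <- d$covariates
    c(cv[["cognitive_speed"]], cv[["working_memory"]], cv[["impulsivity"]])
  }, numeric(3)))
  cov_mat <- base::scale(cov_mat)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]$trials
    n <- nrow(tr)
    if (n < 2L) stop("subject ", ids[i], " has fewer than 2 trials", call. = FALSE)
    rows[[i]] <- data.frame(
      subject_id = ids[i],
      stay = as.integer(tr$choice1[-1L] == tr$choice1[-n]),
      prev_outcome = ifelse(tr$outcome[-n] == 1L, 0.5, -0.5),
      prev_transition = ifelse(tr$transition[-n] == "common", 0.5, -0.5),
      prejudice_log = prej[i],
      cognitive_speed = cov_mat[i, 1L],
      working_memory = cov_mat[i, 2L],
      impulsivity = cov_mat[i, 3L],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  attr(out, "scale") <- scale
  class(out) <- c("stay_table", class(out))
  out
}

# random-effect ladder used when a mixed model fails to converge
stay_random_ladder <- c(
  "(1 + prev_outcome + prev_transition + prev_outcome:prev_transition | subject_id)",
  "(1 + prev_outcome + prev_transition + prev_outcome:prev_transition || subject_id)",
  "(1 + prev_outcome + prev_transition || subject_id)")

has_converged <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  is.null(msgs) || !any(grepl("failed to converge", msgs))
}

#' Mixed-effects logistic regression of stay behavior
#'
#' Fits `stay ~ prev_transition * prev_outcome * prejudice_log +
#' cognitive_speed + working_memory + impulsivity` with within-subject
#' random effects for the intercept, both main effects and their
#' interaction. On non-convergence the random structure is simplified
#' stepwise (drop correlations, then the interaction slope); every
#' simplification is recorded in the result metadata.
#'
#' @param table a `stay_table`.
#' @param nAGQ integration setting passed to [lme4::glmer()]; 0 gives a
#'   much faster penalized-likelihood approximation.
#' @param include_prejudice set `FALSE` for the within-subject-only model.
#' @return a `regression_result` data.frame (term, estimate, se, stat, p,
#'   r2beta, ci_lo, ci_hi) with metadata attributes `formula`, `n`,
#'   `converged`, `random_structure`, `simplified`, and the fitted model in
#'   `attr(, "model")`.
#' @export
fit_stay_glmm <- function(table, nAGQ = 1L, include_prejudice = TRUE) {
  fixed <- if (include_prejudice)
    "stay ~ prev_transition * prev_outcome * prejudice_log + cognitive_speed + working_memory + impulsivity"
  else
    "stay ~ prev_transition * prev_outcome + cognitive_speed + working_memory + impulsivity"
  fit <- NULL; used <- NA_character_; simplified <- FALSE
  for (k in seq_along(stay_random_ladder)) {
    form <- stats::as.formula(paste(fixed, "+", stay_random_ladder[k]))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::glmer(form, data = table, family = stats::binomial,
                    nAGQ = nAGQ))),
      error = function(e) NULL)
    if (!is.null(cand)) {
      fit <- cand; used <- stay_random_ladder[k]; simplified <- k > 1L
      if (has_converged(cand)) break
    }
  }
  if (is.null(fit)) stop("stay GLMM failed at every random-effects structure",
                         call. = FALSE)
  tidy_mixed(fit, n = nrow(table), random_structure = used,
             simplified = simplified)
}

#' Remove implausibly fast second-stage responses
#'
#' Drops rows whose second-stage reaction time is strictly below `min_rt`
#' milliseconds (the conventional 250 ms floor); the boundary value itself
#' is retained. The removal count is stored in `attr(, "n_removed")`.
#'
#' @param table data.frame with an `rt2` column (milliseconds).
#' @param min_rt exclusion threshold in ms.
#' @return filtered data.frame; errors if nothing survives.
#' @export
filter_rt <- function(table, min_rt = 250) {
  keep <- table$rt2 >= min_rt
  out <- table[keep, , drop = FALSE]
  if (!nrow(out))
    stop("all rows removed by the RT filter; inspect the input RTs",
         call. = FALSE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Build the second-stage reaction-time table
#'
#' One row per retained trial: raw rt2 in milliseconds, transition
#' effect-coded (common = +0.5, rare = -0.5, so rare-trial slowing appears
#' as a negative coefficient), centered log prejudice and z-scored
#' covariates. Trials faster than 250 ms are excluded via [filter_rt()].
#'
#' @inheritParams build_stay_table
#' @param min_rt exclusion threshold in ms.
#' @return data.frame (class `rt_table`).
#' @export
build_rt_table <- function(cohort, scores, scale = c("blatant", "subtle"),
                           min_rt = 250) {
  scale <- match.arg(scale)
  score_col <- paste0(scale, "_sum")
  ids <- vapply(cohort, function(d) d$subject_id, character(1))
  keep <- ids %in% scores$subject_id
  cohort <- cohort[keep]; ids <- ids[keep]
  sums <- scores[[score_col]][match(ids, scores$subject_id)]
  prej <- log_scale(sums); prej <- prej - mean(prej)
  cov_mat <- t(vapply(cohort, function(d) {
    cv <- d$covariates
    c(cv[["cognitive_speed"]], cv[["working_memory"]], cv[["impulsivity"]])
  }, numeric(3)))
  cov_mat <- base::scale(cov_mat)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    tr <- cohort[[i]]$trials
    rows[[i]] <- data.frame(
      subject_id = ids[i], rt2 = tr$rt2_ms,
      transition = ifelse(tr$transition == "common", 0.5, -0.5),
      prejudice_log = prej[i],
      cognitive_speed = cov_mat[i, 1L], working_memory = cov_mat[i, 2L],
      impulsivity = cov_mat[i, 3L], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- filter_rt(out, min_rt)
  attr(out, "scale") <- scale
  class(out) <- c("rt_table", class(out))
  out
}

rt_random_ladder <- c("(1 + transition | subject_id)",
                      "(1 + transition || subject_id)",
                      "(1 | subject_id)")

#' Linear mixed model of second-stage reaction times
#'
#' Fits `rt2 ~ transition * prejudice_log + cognitive_speed +
#' working_memory + impulsivity` with a by-subject random intercept and
#' transition slope, on raw milliseconds. Falls back along a simplification
#' ladder on non-convergence. Tests are Wald z (normal approximation).
#'
#' @param table an `rt_table`.
#' @return a `regression_result` (see [fit_stay_glmm()]).
#' @export
fit_rt_model <- function(table) {
  fixed <- "rt2 ~ transition * prejudice_log + cognitive_speed + working_memory + impulsivity"
  fit <- NULL; used <- NA_character_; simplified <- FALSE
  for (k in seq_along(rt_random_ladder)) {
    form <- stats::as.formula(paste(fixed, "+", rt_random_ladder[k]))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = table, REML = TRUE))),
      error = function(e) NULL)
    if (!is.null(cand)) {
      fit <- cand; used <- rt_random_ladder[k]; simplified <- k > 1L
      if (has_converged(cand)) break
    }
  }
  if (is.null(fit)) stop("RT model failed at every random-effects structure",
                         call. = FALSE)
  tidy_mixed(fit, n = nrow(table), random_structure = used,
             simplified = simplified)
}

# Wald summary table + semipartial R2-beta for a merMod fit
tidy_mixed <- function(fit, n, random_structure, simplified) {
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  stat <- est / se
  p <- 2 * stats::pnorm(-abs(stat))
  rank_x <- ncol(lme4::getME(fit, "X"))
  r2 <- r2beta_semipartial(stat, n, rank_x)
  out <- data.frame(term = rownames(co), estimate = est, se = se,
                    stat = stat, p = p, r2beta = r2$point,
                    ci_lo = r2$lo, ci_hi = r2$hi, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "formula") <- deparse1(stats::formula(fit))
  attr(out, "n") <- n
  attr(out, "converged") <- has_converged(fit)
  attr(out, "random_structure") <- random_structure
  attr(out, "simplified") <- simplified
  attr(out, "model") <- fit
  class(out) <- c("regression_result", class(out))
  out
}

# Semipartial R2-beta for single-df fixed effects, Wald form:
# R2 = t^2 / (t^2 + nu) with nu = n - rank(X). The 95% CI shifts the
# statistic by +/- 1.96 (a Wald interval on the noncentrality), clamped at
# zero; an approximation to the mixed-model R2-beta procedures.
r2beta_semipartial <- function(stat, n, rank_x) {
  nu <- max(n - rank_x, 1L)
  f <- function(t) t^2 / (t^2 + nu)
  a <- abs(stat)
  list(point = f(a), lo = f(pmax(a - 1.96, 0)), hi = f(a + 1.96))
}

#' Regress fitted learning parameters on prejudice
#'
#' For each reinforcement-learning parameter (alpha1, alpha2, w, lam),
#' z-scales the per-subject estimate and regresses it on the
#' log-transformed prejudice sum plus the three covariates. Significance of
#' the prejudice term is judged at the Bonferroni-corrected threshold
#' alpha = 0.05 / 4 = 0.0125. Parameters with (numerically) zero variance
#' across subjects are skipped with a warning.
#'
#' @param param_df data.frame with `subject_id` and columns `alpha1`,
#'   `alpha2`, `w`, `lam` (e.g. from [fits_to_df()]).
#' @param scores data.frame with `subject_id` and `<scale>_sum`.
#' @param covariates data.frame with `subject_id`, `cognitive_speed`,
#'   `working_memory`, `impulsivity`.
#' @param scale which prejudice scale.
#' @return named list of `regression_result` tables (one per parameter),
#'   with attributes `alpha_bonferroni` (0.0125) and `significant` (logical
#'   per parameter, prejudice term).
#' @export
fit_param_regressions <- function(param_df, scores, covariates,
                                  scale = c("blatant", "subtle")) {
  scale <- match.arg(scale)
  score_col <- paste0(scale, "_sum")
  d <- merge(param_df, scores[, c("subject_id", score_col)], by = "subject_id")
  d <- merge(d, covariates, by = "subject_id")
  d$prejudice_log <- log_scale(d[[score_col]])
  d$prejudice_log <- d$prejudice_log - mean(d$prejudice_log)
  alpha_bonf <- 0.05 / 4
  out <- list(); sig <- logical(0)
  for (par in c("alpha1", "alpha2", "w", "lam")) {
    y <- d[[par]]
    if (stats::sd(y) < 1e-12) {
      warning("parameter ", par, " has zero variance; regression skipped")
      next
    }
    d$.y <- as.numeric(base::scale(y))
    fit <- stats::lm(.y ~ prejudice_log + cognitive_speed + working_memory +
                       impulsivity, data = d)
    co <- summary(fit)$coefficients
    nu <- fit$df.residual
    tt <- co[, "t value"]
    f <- function(t) t^2 / (t^2 + nu)
    a <- abs(tt)
    res <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                      se = co[, "Std. Error"], stat = tt,
                      p = co[, "Pr(>|t|)"], r2beta = f(a),
                      ci_lo = f(pmax(a - 1.96, 0)), ci_hi = f(a + 1.96),
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(res, "n") <- nrow(d)
    class(res) <- c("regression_result", class(res))
    out[[par]] <- res
    sig[par] <- res$p[res$term == "prejudice_log"] < alpha_bonf
  }
  attr(out, "alpha_bonferroni") <- alpha_bonf
  attr(out, "significant") <- sig
  out
}

#' Extract per-subject parameter estimates from a hierarchical fit
#'
#' @param result a `model_fit_result`.
#' @param space `"constrained"` (default; MAP values on the natural scale)
#'   or `"unconstrained"` (z values).
#' @return data.frame with `subject_id` and the seven parameter columns.
#' @export
fits_to_df <- function(result, space = c("constrained", "unconstrained")) {
  space <- match.arg(space)
  rows <- lapply(result$subject_fits, function(f) {
    v <- if (space == "constrained") f$params else f$z_map
    c(list(subject_id = f$subject_id), as.list(v))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Design diagnostics: collinearity and outliers
#'
#' Variance inflation factors (each predictor regressed on the others;
#' VIF = 1 / (1 - R^2), infinite under exact collinearity) flagged at
#' VIF > 10, and per-predictor outlier flags at |x - mean| > 3 SD.
#'
#' @param design data.frame or matrix of numeric predictors.
#' @return list with `vif` (named vector), `vif_flag`, `outliers` (list of
#'   row indices per predictor), `outlier_flag`, `singular`.
#' @export
design_diagnostics <- function(design) {
  X <- as.matrix(design)
  storage.mode(X) <- "double"
  p <- ncol(X)
  vif <- rep(NA_real_, p)
  names(vif) <- colnames(X)
  singular <- FALSE
  for (j in seq_len(p)) {
    if (stats::sd(X[, j]) == 0) { vif[j] <- Inf; singular <- TRUE; next }
    if (p == 1L) { vif[j] <- 1; next }
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    vif[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    if (!is.finite(vif[j])) singular <- TRUE
  }
  outliers <- lapply(seq_len(p), function(j) {
    m <- mean(X[, j]); s <- stats::sd(X[, j])
    if (s == 0) integer(0) else which(abs(X[, j] - m) > 3 * s)
  })
  names(outliers) <- colnames(X)
  list(vif = vif, vif_flag = any(vif > 10, na.rm = TRUE),
       outliers = outliers,
       outlier_flag = any(lengths(outliers) > 0L), singular = singular)
}

#' Residual summary for a fitted linear mixed model
#'
#' Skewness, excess kurtosis and a location-spread slope (residual absolute
#' value on fitted value) for eyeballing normality and homogeneity.
#'
#' @param fit a merMod object (e.g. `attr(result, "model")`).
#' @return named numeric vector.
#' @export
residual_summary <- function(fit) {
  r <- stats::residuals(fit)
  m <- mean(r); s <- stats::sd(r)
  z <- (r - m) / s
  slope <- stats::coef(stats::lm(abs(r) ~ stats::fitted(fit)))[2]
  c(skewness = mean(z^3), excess_kurtosis = mean(z^4) - 3,
    spread_slope = unname(slope))
}
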