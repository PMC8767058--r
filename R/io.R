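#' Write a cohort's trial data as tab-delimited text
#'
#' One row per trial with columns `subject_id, trial, choice1, transition,
#' state2, choice2, outcome, rt1_ms, rt2_ms` (header, UTF-8, tab-delimited).
#'
#' @param cohort list of `subject_dataset`.
#' @param path output file.
#' @export
write_trials_tsv <- function(cohort, path) {
  rows <- lapply(cohort, function(d) cbind(subject_id = d$subject_id, d$trials))
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read trial data from a tab-delimited file
#'
#' @param path trials TSV as written by [write_trials_tsv()].
#' @param covariates optional data.frame (`subject_id`, `cognitive_speed`,
#'   `working_memory`, `impulsivity`) to attach per subject.
#' @return list of `subject_dataset` in file order of first appearance.
#' @export
read_trials_tsv <- function(path, covariates = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$subject_id)
  lapply(ids, function(id) {
    tr <- df[df$subject_id == id, setdiff(names(df), "subject_id")]
    tr <- tr[order(tr$trial), ]
    rownames(tr) <- NULL
    cv <- NULL
    if (!is.null(covariates)) {
      row <- covariates[covariates$subject_id == id, , drop = FALSE]
      if (nrow(row))
        cv <- c(cognitive_speed = row$cognitive_speed[1],
                working_memory = row$working_memory[1],
                impulsivity = row$impulsivity[1])
    }
    new_subject_dataset(id, tr, cv)
  })
}

#' Score a long item-response table
#'
#' @param items data.frame `subject_id, item_id, level`.
#' @param key scoring key.
#' @return data.frame `subject_id, blatant_sum, subtle_sum` plus subscale
#'   columns.
#' @export
score_items_table <- function(items, key = default_scale_key()) {
  ids <- unique(items$subject_id)
  rows <- lapply(ids, function(id) {
    r <- items[items$subject_id == id, ]
    sc <- score_bsps(stats::setNames(r$level, r$item_id), key)
    cbind(data.frame(subject_id = id, blatant_sum = sc$blatant_sum,
                     subtle_sum = sc$subtle_sum, stringsAsFactors = FALSE),
          as.data.frame(sc$subscale_sums))
  })
  do.call(rbind, rows)
}

#' Read a questionnaire scoring key from YAML
#'
#' The file holds a list of 20 records with fields `item_id`, `scale`,
#' `subscale`, `reverse_keyed`.
#'
#' @param path YAML file; defaults to the key shipped with the package.
#' @return validated key data.frame.
#' @export
read_scale_key <- function(path = system.file("extdata", "bsps_key.yaml",
                                              package = "twostepr")) {
  raw <- yaml::read_yaml(path)
  key <- do.call(rbind, lapply(raw$items, function(it)
    data.frame(item_id = it$item_id, scale = it$scale,
               subscale = it$subscale,
               reverse_keyed = isTRUE(it$reverse_keyed),
               stringsAsFactors = FALSE)))
  validate_scale_key(key)
  key
}

#' Serialize a hierarchical fit to JSON
#'
#' Records the group prior, per-subject constrained and unconstrained MAP
#' estimates with likelihoods, the iBIC (if computed) and the fit settings.
#'
#' @param result a `model_fit_result`.
#' @param path output JSON file.
#' @export
write_fit_json <- function(result, path) {
  subj <- lapply(result$subject_fits, function(f)
    list(subject_id = f$subject_id, params = as.list(f$params),
         z_map = as.list(f$z_map), neg_log_lik = f$neg_log_lik,
         neg_log_post = f$neg_log_post, converged = f$converged))
  obj <- list(model = result$model_name,
              prior = list(mu = as.list(result$prior$mu),
                           sigma2 = as.list(result$prior$sigma2)),
              n_em_iterations = result$n_em_iterations,
              ibic = result$ibic,
              ibic_n_samples = result$ibic_n_samples,
              settings = result$settings, p_common = result$p_common,
              subjects = subj)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read per-subject parameters from a fit JSON
#'
#' @param path file written by [write_fit_json()].
#' @return data.frame with `subject_id` and the seven parameter columns.
#' @export
read_fit_params_json <- function(path) {
  obj <- jsonlite::read_json(path)
  do.call(rbind, lapply(obj$subjects, function(s)
    as.data.frame(c(list(subject_id = s$subject_id), s$params),
                  stringsAsFactors = FALSE)))
}

#' Write a tidy regression result table
#'
#' @param result a `regression_result` (or plain data.frame).
#' @param path output TSV.
#' @export
write_result_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
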