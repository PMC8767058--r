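#' Default scoring key for the blatant/subtle prejudice scale
#'
#' Twenty items, ten per scale. Blatant = threat/rejection (6) + intimacy
#' (4); subtle = traditional values (4) + cultural differences (4) +
#' positive emotions (2). The reverse-keyed set is not fixed by the
#' instrument description available here, so the key is configurable; the
#' shipped default reverse-keys the positively worded subscales (intimacy
#' and positive emotions). A YAML copy lives in
#' `inst/extdata/bsps_key.yaml` and can be edited and loaded with
#' [read_scale_key()].
#'
#' @return data.frame with columns `item_id`, `scale`, `subscale`,
#'   `reverse_keyed`.
#' @export
default_scale_key <- function() {
  data.frame(
    item_id = c(sprintf("b%02d", 1:10), sprintf("s%02d", 1:10)),
    scale = rep(c("blatant", "subtle"), each = 10L),
    subscale = c(rep("threat_reject", 6L), rep("intimacy", 4L),
                 rep("traditional_values", 4L), rep("cultural_differences", 4L),
                 rep("positive_emotions", 2L)),
    reverse_keyed = c(rep(FALSE, 6L), rep(TRUE, 4L),
                      rep(FALSE, 8L), rep(TRUE, 2L)),
    stringsAsFactors = FALSE)
}

validate_scale_key <- function(key) {
  stopifnot(is.data.frame(key),
            all(c("item_id", "scale", "subscale", "reverse_keyed") %in% names(key)))
  if (nrow(key) != 20L) stop("scale key must have 20 items", call. = FALSE)
  tab <- table(key$scale)
  if (!all(tab == 10L)) stop("each scale must have 10 items", call. = FALSE)
  invisible(key)
}

#' Score a single Likert response
#'
#' Responses on the 4-point agreement scale (1 = strongly disagree ...
#' 4 = strongly agree) are rescaled before summation so that higher scores
#' mean greater prejudice: forward items map (1,2,3,4) -> (1,2,4,5);
#' reverse-keyed items mirror this, (1,2,3,4) -> (5,4,2,1).
#'
#' @param level integer response level in 1..4 (vectorized).
#' @param reverse logical, reverse-keyed item?
#' @return integer item score in \{1, 2, 4, 5\}.
#' @export
score_item <- function(level, reverse = FALSE) {
  if (any(!level %in% 1:4))
    stop("Likert level out of range 1..4", call. = FALSE)
  fwd <- c(1L, 2L, 4L, 5L)
  s <- fwd[level]
  if (length(reverse) == 1L) reverse <- rep(reverse, length(s))
  s[reverse] <- 6L - s[reverse]
  s
}

#' Score a full questionnaire response sheet
#'
#' Sums rescaled item scores per scale and subscale. All 20 items must be
#' present; incomplete respondents are rejected (the analysis policy is to
#' exclude them).
#'
#' @param responses named integer vector (names = item ids, values = Likert
#'   levels 1..4) or a data.frame with columns `item_id`, `level`.
#' @param key scoring key from [default_scale_key()] or [read_scale_key()].
#' @return object of class `bsps_scores`: list with `blatant_sum`,
#'   `subtle_sum`, `subscale_sums`.
#' @export
score_bsps <- function(responses, key = default_scale_key()) {
  validate_scale_key(key)
  if (is.data.frame(responses)) {
    responses <- stats::setNames(responses$level, responses$item_id)
  }
  missing <- setdiff(key$item_id, names(responses))
  if (length(missing))
    stop("missing item responses: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lev <- as.integer(responses[key$item_id])
  sc <- score_item(lev, key$reverse_keyed)
  sub <- tapply(sc, key$subscale, sum)
  blat <- sum(sc[key$scale == "blatant"])
  subt <- sum(sc[key$scale == "subtle"])
  structure(list(blatant_sum = as.integer(blat), subtle_sum = as.integer(subt),
                 subscale_sums = as.list(sub)),
            class = "bsps_scores")
}

#' Log transform of a prejudice sum score
#'
#' Natural log of the raw sum, used to reduce the impact of the strongly
#' right-skewed score distribution before regression.
#'
#' @param sum_score integer sum score, >= 10.
#' @return numeric log score.
#' @export
log_scale <- function(sum_score) {
  if (any(sum_score < 10)) stop("sum scores start at 10", call. = FALSE)
  log(sum_score)
}

#' Split scores into low/high groups
#'
#' `"low"` iff score < threshold. The default threshold is the sample
#' median; pass `threshold = 14` to reproduce the reference split
#' (low < 14, high >= 14).
#'
#' @param scores numeric vector of sum scores.
#' @param threshold cut point; defaults to `median(scores)`.
#' @return character vector of labels "low"/"high".
#' @export
median_split <- function(scores, threshold = stats::median(scores)) {
  if (!length(scores)) stop("empty score vector", call. = FALSE)
  ifelse(scores < threshold, "low", "high")
}

#' Build item responses consistent with target sum scores
#'
#' Inverse of [score_bsps()] for the synthetic generator: given a target sum
#' in \[10, 50\] for one 10-item scale, returns Likert levels whose scored
#' sum equals the target under the supplied key. Any integer target is
#' representable because per-item scores come from \{1, 2, 4, 5\}.
#'
#' @param target integer target sum in \[10, 50\].
#' @param key_rows the 10 key rows of one scale.
#' @return integer vector of 10 Likert levels (named by item id).
#' @export
items_for_sum <- function(target, key_rows) {
  stopifnot(nrow(key_rows) == 10L, target >= 10, target <= 50)
  rem <- as.integer(target) - 10L           # increments above the all-1 floor
  inc <- integer(10L)                       # per-item increment in {0,1,3,4}
  k4 <- rem %/% 4L; r <- rem %% 4L
  if (r == 0L) {
    inc[seq_len(k4)] <- 4L
  } else if (r == 1L) {
    inc[seq_len(k4)] <- 4L; inc[k4 + 1L] <- 1L
  } else if (r == 3L) {
    inc[seq_len(k4)] <- 4L; inc[k4 + 1L] <- 3L
  } else {                                  # r == 2: 4+... -> 3+3 or 1+1
    if (k4 >= 1L) {
      if (k4 > 1L) inc[seq_len(k4 - 1L)] <- 4L
      inc[k4:(k4 + 1L)] <- 3L
    } else inc[1:2] <- 1L
  }
  score <- 1L + inc                         # item scores in {1,2,4,5}
  fwd <- c(1L, 2L, 4L, 5L)
  lev <- match(score, fwd)
  lev[key_rows$reverse_keyed] <- 5L - lev[key_rows$reverse_keyed]
  stats::setNames(lev, key_rows$item_id)
}
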