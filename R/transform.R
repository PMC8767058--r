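#' @useDynLib twostepr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# canonical parameter order used throughout the fitting code
PARAM_NAMES <- c("alpha1", "alpha2", "beta1", "beta2", "lam", "w", "rho")
SIGMOID_IDX <- c(1L, 2L, 5L, 6L)  # alpha1, alpha2, lam, w
EXP_IDX     <- c(3L, 4L)          # beta1, beta2

#' Map an unconstrained vector to agent parameters
#'
#' Fitting operates in an unconstrained 7-dimensional space `z` under
#' independent Gaussian priors: a logistic sigmoid maps to the unit-interval
#' parameters (alpha1, alpha2, lam, w), an exponential to the inverse
#' temperatures, and rho passes through unchanged.
#'
#' @param z numeric length-7 unconstrained vector (order alpha1, alpha2,
#'   beta1, beta2, lam, w, rho).
#' @return named numeric vector of constrained parameters.
#' @export
z_to_params <- function(z) {
  stopifnot(length(z) == 7L)
  p <- as.numeric(z)
  p[SIGMOID_IDX] <- stats::plogis(p[SIGMOID_IDX])
  p[EXP_IDX] <- exp(p[EXP_IDX])
  names(p) <- PARAM_NAMES
  p
}

#' Map agent parameters to the unconstrained space
#'
#' Inverse of [z_to_params()]; interior points round-trip to within 1e-10.
#'
#' @param params named numeric vector (or [agent_params()]).
#' @return numeric length-7 unconstrained vector.
#' @export
params_to_z <- function(params) {
  p <- as.numeric(params[PARAM_NAMES])
  z <- p
  z[SIGMOID_IDX] <- stats::qlogis(p[SIGMOID_IDX])
  z[EXP_IDX] <- log(p[EXP_IDX])
  names(z) <- PARAM_NAMES
  z
}

#' Model variants for comparison
#'
#' The comparison set holds the hybrid model and its two single-system
#' restrictions: `"mf"` pins the model-based weight at 0, `"mb"` pins it
#' at 1. Restricted parameters are excluded from the prior and from the
#' group-parameter count used by the integrated BIC.
#'
#' @param name one of "hybrid", "mf", "mb".
#' @return list with `name`, `fixed` (named constrained values) and
#'   `free` (integer indices of free parameters).
#' @export
model_spec <- function(name = c("hybrid", "mf", "mb")) {
  name <- match.arg(name)
  fixed <- switch(name, hybrid = numeric(0), mf = c(w = 0), mb = c(w = 1))
  free <- setdiff(seq_len(7L), match(names(fixed), PARAM_NAMES))
  list(name = name, fixed = fixed, free = free)
}

# expand a free-dimensional z vector into constrained parameters,
# overriding fixed entries
expand_params <- function(z_free, model) {
  z <- numeric(7L)
  z[model$free] <- z_free
  p <- z_to_params(z)
  if (length(model$fixed)) p[names(model$fixed)] <- model$fixed
  p
}
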