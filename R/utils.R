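#' Geometric mean
#'
#' @param x numeric vector of strictly positive values.
#' @return The geometric mean of `x`.
#' @keywords internal
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values")
  }
  exp(mean(log(x)))
}

#' Convert a signed fold regulation to a multiplicative T/TA ratio
#'
#' Fold regulation (FR) is the field's signed effect size: the tumour /
#' adjacent ratio when it is at least 1, otherwise the negative inverse of
#' that ratio (so -4 means 4-fold down). This maps FR back to the ratio
#' scale: `f` for `f >= 1`, `-1/f` for `f <= -1`.
#'
#' @param f signed fold regulation, `|f| >= 1`.
#' @return The corresponding multiplicative ratio (> 0).
#' @export
fr_to_ratio <- function(f) {
  if (any(abs(f) < 1)) stop("fold regulation must satisfy |f| >= 1")
  ifelse(f >= 1, f, -1 / f)
}

#' Convert a multiplicative ratio to a signed fold regulation
#'
#' @param rho positive ratio.
#' @return `rho` if `rho >= 1`, else `-1/rho`.
#' @export
ratio_to_fr <- function(rho) {
  if (any(rho <= 0)) stop("ratio must be positive")
  ifelse(rho >= 1, rho, -1 / rho)
}

# derive a child RNG seed from a base seed and a stream index, kept < 2^31
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L
}
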