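#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik Maximised log-likelihood (ML, not REML).
#' @param k Number of estimated parameters (fixed effects including the
#'   intercept plus variance parameters).
#' @param n Number of observations.
#' @return AICc value.
#' @export
regression_aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0)
  if (n <= k + 1)
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' `w_i = exp(-dAICc_i / 2) / sum_j exp(-dAICc_j / 2)`, computed on
#' differences from the minimum so large spreads do not underflow.
#'
#' @param aicc Numeric vector of AICc values (finite, nonempty).
#' @return Weights summing to 1, in the input order.
#' @export
akaike_weights <- function(aicc) {
  if (!length(aicc) || any(!is.finite(aicc)))
    stop("aicc must be a nonempty finite vector", call. = FALSE)
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}
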