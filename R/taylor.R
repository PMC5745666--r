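#' Second-order Taylor machinery for the expected inverse ridge matrix
#'
#' The exact reliability involves \eqn{E_X[(X'X + \Lambda)^{-1}]}, which has
#' no simple closed form. Writing \eqn{X'X + \Lambda = D + E} with
#' \eqn{D = E[X'X] + \Lambda} (diagonal under linkage equilibrium) and
#' \eqn{E = X'X - E[X'X]} (zero-mean), a Taylor expansion gives, at second
#' order, \eqn{E_X[(X'X+\Lambda)^{-1}] = D^{-1} + E_X[D^{-1} E D^{-1} E]
#' D^{-1}}. Only the diagonal of \eqn{P = D^{-1} E D^{-1} E} is needed for
#' the precision trace, and under Hardy-Weinberg sampling of unlinked
#' binomial genotype columns it has the closed form implemented here.
#'
#' @name taylor_terms
NULL

check_panel_vectors <- function(sigma_k2, N, lambda_k) {
  if (length(sigma_k2) != length(lambda_k)) {
    stop("`sigma_k2` and `lambda_k` must have the same length.",
         call. = FALSE)
  }
  if (any(!is.finite(sigma_k2)) || any(sigma_k2 <= 0) || any(sigma_k2 > 0.5)) {
    stop("genotype variances must lie in (0, 0.5].", call. = FALSE)
  }
  if (any(!is.finite(lambda_k)) || any(lambda_k <= 0)) {
    stop("shrinkage values `lambda_k` must be strictly positive.",
         call. = FALSE)
  }
  if (!is.numeric(N) || length(N) != 1L || N < 1) {
    stop("`N` must be a positive count.", call. = FALSE)
  }
}

#' Diagonal of the expected second-order Taylor term
#'
#' Computes, for each SNP k,
#' \deqn{E_X[P_{kk}] = \frac{N \sigma_k^2}{\delta_k}\left\{
#'   \frac{1 - 2\sigma_k^2}{\delta_k} +
#'   \sum_t \frac{\sigma_t^2}{\delta_t}\right\},}
#' with \eqn{\delta_k = N \sigma_k^2 + \lambda_k} the diagonal of D.
#'
#' @param sigma_k2 per-SNP genotype variances \eqn{2 f_k (1 - f_k)},
#'   entries in (0, 0.5\].
#' @param N reference population size.
#' @param lambda_k per-SNP shrinkage \eqn{\lambda_k =
#'   \sigma_e^2/\sigma_{\beta_k}^2}, strictly positive, same length as
#'   `sigma_k2`.
#' @return Numeric vector of \eqn{E_X[P_{kk}]}, non-negative whenever
#'   \eqn{\sigma_k^2 \le 0.5}.
#' @export
expected_P_diagonal <- function(sigma_k2, N, lambda_k) {
  check_panel_vectors(sigma_k2, N, lambda_k)
  delta <- N * sigma_k2 + lambda_k
  S <- sum(sigma_k2 / delta)
  N * sigma_k2 / delta * ((1 - 2 * sigma_k2) / delta + S)
}

#' General second-order precision for an arbitrary shrinkage diagonal
#'
#' Evaluates \eqn{\hat r^2 = 1 - \lambda (\mathrm{tr}[F D^{-1}] +
#' \mathrm{tr}[F\, E_X[P]\, D^{-1}])} with diagonal F and D, i.e.
#' \eqn{1 - \lambda \sum_k \sigma_k^2/\delta_k (1 + E_X[P_{kk}])}.
#' With the equal-contribution shrinkage \eqn{\lambda_k = M \lambda
#' \sigma_k^2} this reduces algebraically to the scalar second-order formula
#' of [second_order_from_variances()].
#'
#' @inheritParams expected_P_diagonal
#' @param h2 heritability in (0, 1\] (sets \eqn{\lambda = (1 - h2)/h2}).
#' @return A [precision_estimate()] with method `"eq6"` lineage (tagged
#'   `eq6`).
#' @export
precision_second_order_general <- function(sigma_k2, N, lambda_k, h2) {
  check_panel_vectors(sigma_k2, N, lambda_k)
  if (!is.numeric(h2) || length(h2) != 1L || h2 <= 0 || h2 > 1) {
    stop("`h2` must lie in (0, 1].", call. = FALSE)
  }
  lambda <- (1 - h2) / h2
  if (lambda == 0) return(precision_estimate(1, "eq6"))
  delta <- N * sigma_k2 + lambda_k
  EP <- expected_P_diagonal(sigma_k2, N, lambda_k)
  v <- 1 - lambda * (sum(sigma_k2 / delta) + sum(sigma_k2 * EP / delta))
  precision_estimate(v, "eq6")
}
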