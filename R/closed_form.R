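#' Closed-form predictors of GEBV precision
#'
#' All scalar deterministic formulas for the expected reliability of genomic
#' estimated breeding values under the idealised design (unrelated reference
#' individuals, SNPs in linkage equilibrium, all genetic variance on the
#' panel, phenotypic variance 1). Each takes a [design_spec()] and returns a
#' [precision_estimate()].
#'
#' @name closed_form
#' @details
#' * `daetwyler_basic` -- single-SNP regression with the full phenotypic
#'   variance as error variance: \eqn{N h^2 / (N h^2 + M)}. Conservative;
#'   systematically underestimates.
#' * `daetwyler_corrected` -- the same derivation with the error variance
#'   shrunk for the part explained by the other SNPs, giving a quadratic
#'   whose root at or below 1 is
#'   \eqn{(M + N h^2 - \sqrt{(M + N h^2)^2 - 4 N M h^4})/(2 M h^2)}.
#' * `first_order` -- first-order Taylor expansion of the expected inverse
#'   ridge matrix under the equal-contribution prior:
#'   \eqn{N/(N + M\lambda)}. Optimistic; overestimates at finite N.
#' * `second_order_*` -- second-order Taylor correction, subtracting
#'   \eqn{\lambda N M (N + M\lambda)^{-3} (M - 2 + \overline{1/\sigma_k^2})}
#'   where the mean inverse genotype variance comes from realised panel
#'   variances (`second_order_from_variances`), from the uniform-frequency
#'   moment (`second_order_uniform`), or from the U-shape approximation that
#'   replaces the moment term by \eqn{\lambda (M/N)^2 (N/(N+M\lambda))^3}
#'   (`second_order_ushape`).
#' * `goddard_comparator` -- Goddard's (2009) closed form, parameterised with
#'   \eqn{\lambda_G = \lambda M / (-\log f_{min})} and unlinked SNPs
#'   (effective loci = M).
#' * `single_variance_first_order` -- first-order formula when all SNP
#'   effects share one prior variance (GBLUP prior) instead of contributing
#'   equally to the genetic variance.
#' * `adjust_for_marker_coverage` -- markers capture only a fraction `b` of
#'   the genetic variance: heritability is reduced to `b * h2` and the
#'   resulting precision regressed by `b`.
NULL

#' @rdname closed_form
#' @param design a [design_spec()].
#' @export
daetwyler_basic <- function(design) {
  stopifnot_design(design)
  with(design, precision_estimate(N * h2 / (N * h2 + M), "eq2"))
}

#' @rdname closed_form
#' @export
daetwyler_corrected <- function(design) {
  stopifnot_design(design)
  with(design, {
    disc <- (M + N * h2)^2 - 4 * N * M * h2^2   # >= 0 by AM-GM with h2 <= 1
    precision_estimate((M + N * h2 - sqrt(disc)) / (2 * M * h2), "eq3")
  })
}

#' @rdname closed_form
#' @export
first_order <- function(design) {
  stopifnot_design(design)
  with(design, precision_estimate(N / (N + M * lambda), "eq5"))
}

# shared second-order core: first-order value minus the Taylor correction
# lambda*N*M/(N+M*lambda)^3 * (M - 2 + mean_inv_sigma2)
second_order_value <- function(design, mean_inv_sigma2) {
  with(design, {
    if (lambda == 0) return(1)
    N / (N + M * lambda) -
      lambda * N * M / (N + M * lambda)^3 * (M - 2 + mean_inv_sigma2)
  })
}

#' @rdname closed_form
#' @param sigma_k2 vector of per-SNP genotype variances
#'   \eqn{\sigma_k^2 = 2 f_k (1 - f_k)}, length `M`, entries in (0, 0.5\].
#' @export
second_order_from_variances <- function(design, sigma_k2) {
  stopifnot_design(design)
  if (length(sigma_k2) != design$M) {
    stop("`sigma_k2` must have length M = ", design$M, ".", call. = FALSE)
  }
  if (any(!is.finite(sigma_k2)) || any(sigma_k2 <= 0) || any(sigma_k2 > 0.5)) {
    stop("genotype variances must lie in (0, 0.5].", call. = FALSE)
  }
  precision_estimate(second_order_value(design, mean(1 / sigma_k2)), "eq6")
}

#' @rdname closed_form
#' @param f_min minimum minor allele frequency in (0, 0.5).
#' @export
second_order_uniform <- function(design, f_min) {
  stopifnot_design(design)
  E <- expected_inv_variance(freq_dist("uniform", f_min))
  precision_estimate(second_order_value(design, E), "eq7")
}

#' @rdname closed_form
#' @export
second_order_ushape <- function(design) {
  stopifnot_design(design)
  with(design, {
    if (lambda == 0) return(precision_estimate(1, "eq8"))
    v <- N / (N + M * lambda) -
      lambda * (M / N)^2 * (N / (N + M * lambda))^3
    precision_estimate(v, "eq8")
  })
}

#' @rdname closed_form
#' @export
goddard_comparator <- function(design, f_min) {
  stopifnot_design(design)
  freq_dist("ushape", f_min)                 # validate f_min
  with(design, {
    if (lambda == 0) return(precision_estimate(1, "goddard"))
    lam_g <- lambda * M / (-log(f_min))
    a <- 1 + 2 * lam_g / N
    v <- 1 - lam_g / (2 * N * sqrt(a)) *
      log((1 + a + 2 * sqrt(a)) / (1 + a - 2 * sqrt(a)))
    precision_estimate(v, "goddard")
  })
}

#' @rdname closed_form
#' @export
single_variance_first_order <- function(design, f_min) {
  stopifnot_design(design)
  freq_dist("uniform", f_min)                # validate f_min
  with(design, {
    if (lambda == 0) return(precision_estimate(1, "eq9"))
    lam_b <- M * expected_variance_uniform(f_min) * lambda
    s <- sqrt(1 + 2 * lam_b / N)
    num <- 2 * f_min - 1 + s
    den <- 1 - 2 * f_min + s
    if (num <= 0 || den <= 0) {
      stop(sprintf(paste0("log argument (2*f_min - 1 + s)/(1 - 2*f_min + s) ",
                          "non-positive (num = %g, den = %g): N too small ",
                          "relative to the shrinkage constant."), num, den),
           call. = FALSE)
    }
    v <- 1 - lambda * M / N *
      (1 + 1 / (1 - 2 * f_min) * lam_b / (N * s) * log(num / den))
    precision_estimate(v, "eq9")
  })
}

#' @rdname closed_form
#' @param b fraction of the genetic variance captured by the markers, in
#'   \[0, 1\].
#' @param method a closed-form predictor taking `design` as first argument
#'   (e.g. [first_order()]); further arguments are passed through `...`.
#' @param ... extra arguments for `method` (e.g. `f_min`).
#' @export
adjust_for_marker_coverage <- function(design, b, method, ...) {
  stopifnot_design(design)
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b > 1) {
    stop("`b` must lie in [0, 1].", call. = FALSE)
  }
  if (b == 0) {
    est <- method(design, ...)
    est$value <- 0
    return(est)
  }
  est <- method(design_spec(design$N, design$M, b * design$h2), ...)
  est$value <- b * est$value
  est
}
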