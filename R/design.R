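#' Single-trait genomic evaluation design
#'
#' Bundles the three scalars that determine the expected precision of GEBV in
#' the idealised single-trait setting: the size `N` of the reference
#' population, the number `M` of (causal, unlinked) SNPs on the panel, and
#' the heritability `h2` of the trait. Phenotypic variance is normalised to
#' 1 throughout the package, so the genetic variance is `h2`, the residual
#' variance is `1 - h2`, and the variance ratio
#' \eqn{\lambda = \sigma_e^2/\sigma_g^2 = (1 - h2)/h2} is derived here once.
#'
#' @param N reference population size (>= 1).
#' @param M number of SNPs (>= 1).
#' @param h2 heritability in (0, 1\]. `h2 = 1` is allowed (\eqn{\lambda = 0});
#'   the closed forms then short-circuit to a precision of 1.
#' @return An object of class `design_spec` with fields `N`, `M`, `h2`,
#'   `lambda`.
#' @examples
#' design_spec(N = 5000, M = 500, h2 = 0.3)
#' @export
design_spec <- function(N, M, h2) {
  for (nm in c("N", "M")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop("`", nm, "` must be a positive integer.", call. = FALSE)
    }
  }
  if (!is.numeric(h2) || length(h2) != 1L || !is.finite(h2) ||
      h2 <= 0 || h2 > 1) {
    stop("`h2` must lie in (0, 1].", call. = FALSE)
  }
  structure(list(N = as.numeric(N), M = as.numeric(M), h2 = h2,
                 lambda = (1 - h2) / h2),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> N = %g, M = %g, h2 = %g (lambda = %g)\n",
              x$N, x$M, x$h2, x$lambda))
  invisible(x)
}

stopifnot_design <- function(design) {
  if (!inherits(design, "design_spec")) {
    stop("expected a `design_spec` object; see design_spec().", call. = FALSE)
  }
}

#' Precision estimate container
#'
#' Result type shared by every predictor in the package: a precision value
#' (the GEBV reliability \eqn{r^2}) tagged with the method that produced it.
#' Stochastic methods (`eq1_mc`, `empirical`) also carry the Monte-Carlo
#' standard error, the replicate count and the seed.
#'
#' @param value precision in \[0, 1\].
#' @param method one of `"eq1_mc"`, `"eq2"`, `"eq3"`, `"eq5"`, `"eq6"`,
#'   `"eq7"`, `"eq8"`, `"eq9"`, `"eq10_index"`, `"goddard"`, `"empirical"`.
#' @param mc_se Monte-Carlo standard error (stochastic methods only).
#' @param replicates replicate count (stochastic methods only).
#' @param seed seed used (stochastic methods only).
#' @return An object of class `precision_estimate`.
#' @export
precision_estimate <- function(value, method, mc_se = NULL, replicates = NULL,
                               seed = NULL) {
  methods <- c("eq1_mc", "eq2", "eq3", "eq5", "eq6", "eq7", "eq8", "eq9",
               "eq10_index", "goddard", "empirical")
  method <- match.arg(method, methods)
  stochastic <- method %in% c("eq1_mc", "empirical")
  if (stochastic && is.null(mc_se)) {
    stop("stochastic method `", method, "` requires `mc_se`.", call. = FALSE)
  }
  if (!stochastic && !is.null(mc_se)) {
    stop("closed-form method `", method, "` must not carry `mc_se`.",
         call. = FALSE)
  }
  structure(list(value = value, method = method, mc_se = mc_se,
                 replicates = replicates, seed = seed),
            class = "precision_estimate")
}

#' @export
print.precision_estimate <- function(x, ...) {
  if (is.null(x$mc_se)) {
    cat(sprintf("r2 = %.4f  [%s]\n", x$value, x$method))
  } else {
    cat(sprintf("r2 = %.4f (mc_se = %.4g, %d replicates)  [%s]\n",
                x$value, x$mc_se, x$replicates, x$method))
  }
  invisible(x)
}
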