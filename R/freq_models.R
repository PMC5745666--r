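#' Allele-frequency distribution of a SNP panel
#'
#' Constructs a distribution for the B-allele frequency of the SNPs retained
#' on a genotyping panel, truncated to the symmetric support
#' \eqn{[f_{min}, 1 - f_{min}]} where \eqn{f_{min}} is the minimum minor
#' allele frequency (MAF) applied when filtering the panel.
#'
#' Two laws are supported:
#' \describe{
#'   \item{\code{uniform}}{constant density \eqn{1/(1 - 2 f_{min})}, the
#'     generic a-priori assumption for a commercial SNP chip.}
#'   \item{\code{ushape}}{density \eqn{C / (2 f (1 - f))} with
#'     \eqn{C = 1/\log((1 - f_{min})/f_{min})}, the neutral-drift equilibrium
#'     spectrum truncated at the MAF bound. The drift bound
#'     \eqn{\alpha = 1/(2 N_e)} is obtained by passing
#'     \code{f_min = 1/(2 * Ne)}.}
#' }
#'
#' @param kind `"uniform"` or `"ushape"`.
#' @param f_min minimum minor allele frequency, strictly inside (0, 0.5).
#'   `f_min = 0` is rejected: the moments of `1/(2 f (1 - f))` diverge.
#' @return An object of class `freq_dist` with fields `kind` and `f_min`.
#' @examples
#' d <- freq_dist("uniform", f_min = 0.05)
#' freq_density(d, 0.5)
#' expected_inv_variance(d)
#' @seealso [freq_density()], [sample_freqs()], [expected_inv_variance()]
#' @export
freq_dist <- function(kind = c("uniform", "ushape"), f_min) {
  kind <- match.arg(kind)
  if (!is.numeric(f_min) || length(f_min) != 1L || !is.finite(f_min) ||
      f_min <= 0 || f_min >= 0.5) {
    stop("`f_min` must be a single number strictly inside (0, 0.5); ",
         "f_min = 0 makes E[1/(2f(1-f))] diverge.", call. = FALSE)
  }
  structure(list(kind = kind, f_min = f_min), class = "freq_dist")
}

#' @export
print.freq_dist <- function(x, ...) {
  cat(sprintf("<freq_dist> %s on [%g, %g]\n", x$kind, x$f_min, 1 - x$f_min))
  invisible(x)
}

# normalising constant of the truncated U-shape: C = 1/log((1-a)/a)
ushape_C <- function(f_min) 1 / log((1 - f_min) / f_min)

stopifnot_freq_dist <- function(dist) {
  if (!inherits(dist, "freq_dist")) {
    stop("expected a `freq_dist` object; see freq_dist().", call. = FALSE)
  }
}

#' Density of an allele-frequency distribution
#'
#' @param dist a [freq_dist()] object.
#' @param f vector of frequencies; every value must lie in the support
#'   \eqn{[f_{min}, 1 - f_{min}]}.
#' @return Density values (vectorised over `f`).
#' @export
freq_density <- function(dist, f) {
  stopifnot_freq_dist(dist)
  a <- dist$f_min
  if (any(!is.finite(f)) || any(f < a) || any(f > 1 - a)) {
    stop(sprintf("frequency outside the support [%g, %g].", a, 1 - a),
         call. = FALSE)
  }
  switch(dist$kind,
    uniform = rep(1 / (1 - 2 * a), length(f)),
    ushape  = ushape_C(a) / (2 * f * (1 - f))
  )
}

#' Cumulative distribution function of an allele-frequency distribution
#'
#' Closed form in both cases; the U-shape CDF is
#' \eqn{C/2 (\mathrm{logit}(f) - \mathrm{logit}(f_{min}))}.
#'
#' @inheritParams freq_density
#' @return CDF values in \[0, 1\].
#' @export
freq_cdf <- function(dist, f) {
  stopifnot_freq_dist(dist)
  a <- dist$f_min
  f <- pmin(pmax(f, a), 1 - a)
  switch(dist$kind,
    uniform = (f - a) / (1 - 2 * a),
    ushape  = ushape_C(a) / 2 * (stats::qlogis(f) - stats::qlogis(a))
  )
}

#' Sample SNP allele frequencies
#'
#' Draws `M` independent frequencies. The U-shape uses the closed-form
#' inverse CDF (a logistic transform of a uniform draw), which is exact --
#' no rejection step.
#'
#' @inheritParams freq_density
#' @param M number of SNPs to draw.
#' @param seed optional integer seed; a fixed seed gives a bit-identical
#'   vector.
#' @return Numeric vector of length `M` inside the support.
#' @export
sample_freqs <- function(dist, M, seed = NULL) {
  stopifnot_freq_dist(dist)
  if (!is.numeric(M) || length(M) != 1L || M < 1 || M != round(M)) {
    stop("`M` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- dist$f_min
  u <- stats::runif(M)
  switch(dist$kind,
    uniform = a + u * (1 - 2 * a),
    # invert u = C/2 (logit f - logit a):  f = plogis(logit a + 2u/C)
    ushape  = stats::plogis(stats::qlogis(a) + 2 * u / ushape_C(a))
  )
}

#' Expected inverse genotype variance E\[1/(2f(1-f))\]
#'
#' The moment of the inverse per-SNP genotype variance
#' \eqn{\sigma_k^2 = 2 f_k (1 - f_k)} that enters the second-order precision
#' corrections. Closed forms:
#' uniform, \eqn{\log((1-f_{min})/f_{min}) / (1 - 2 f_{min})};
#' U-shape, \eqn{1 + (1 - 2 f_{min}) / (2 f_{min} (1 - f_{min})
#' \log((1-f_{min})/f_{min}))}.
#' Both are bounded below by 2 (value of \eqn{1/\sigma^2} at f = 0.5).
#'
#' @inheritParams freq_density
#' @return A single number, at least 2.
#' @export
expected_inv_variance <- function(dist) {
  stopifnot_freq_dist(dist)
  a <- dist$f_min
  L <- log((1 - a) / a)
  switch(dist$kind,
    uniform = L / (1 - 2 * a),
    ushape  = 1 + (1 - 2 * a) / (2 * a * (1 - a) * L)
  )
}

#' Mean genotype variance factor for the single-prior shrinkage constant
#'
#' Returns the factor \eqn{(1 - 6 f_{min}^2 + 2 f_{min}^3) / (3 (1 - 2
#' f_{min}))} used to build the shared shrinkage constant
#' \eqn{\hat\lambda_\beta = M \cdot \mathrm{factor} \cdot \lambda} of the
#' single-prior-variance (GBLUP-style) first-order formula
#' ([single_variance_first_order()]).
#'
#' Note: direct integration of \eqn{2 f (1 - f)} over the uniform support
#' gives \eqn{(1 - 6 f_{min}^2 + 4 f_{min}^3)/(3(1 - 2 f_{min}))}, which
#' differs from this factor at order \eqn{f_{min}^3}. This function returns
#' the constant used by the published formula; [expected_variance_quadrature()]
#' returns the exact integral for comparison.
#'
#' @param f_min minimum MAF in (0, 0.5).
#' @return A single number in (0, 0.5\].
#' @export
expected_variance_uniform <- function(f_min) {
  d <- freq_dist("uniform", f_min)   # reuse validation
  a <- d$f_min
  (1 - 6 * a^2 + 2 * a^3) / (3 * (1 - 2 * a))
}

#' Exact mean genotype variance E\[2f(1-f)\] by quadrature
#'
#' @inheritParams freq_density
#' @return E\[2f(1-f)\] under `dist`, by adaptive quadrature.
#' @export
expected_variance_quadrature <- function(dist) {
  stopifnot_freq_dist(dist)
  a <- dist$f_min
  stats::integrate(function(f) 2 * f * (1 - f) * freq_density(dist, f),
                   lower = a, upper = 1 - a, rel.tol = 1e-10)$value
}

#' Read / write allele-frequency vectors
#'
#' Plain-text interchange: one decimal fraction per line, `#` comment lines
#' ignored.
#'
#' @param path file path.
#' @return `read_freqs` returns a numeric vector; `write_freqs` returns
#'   `path` invisibly.
#' @export
read_freqs <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- suppressWarnings(as.numeric(lines))
  if (any(is.na(f))) stop("non-numeric frequency line in ", path, call. = FALSE)
  if (any(f <= 0) || any(f >= 1)) {
    stop("frequencies must lie strictly inside (0, 1).", call. = FALSE)
  }
  f
}

#' @param freqs numeric vector of frequencies in (0, 1).
#' @rdname read_freqs
#' @export
write_freqs <- function(freqs, path) {
  stopifnot(is.numeric(freqs), all(freqs > 0), all(freqs < 1))
  writeLines(c("# allele frequencies, one per line",
               format(freqs, digits = 15, trim = TRUE, scientific = FALSE)),
             path)
  invisible(path)
}
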