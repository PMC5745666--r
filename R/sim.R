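#' Prior on SNP-effect variances
#'
#' Two priors link per-SNP effect variances \eqn{\sigma_{\beta_k}^2} to the
#' genetic variance \eqn{\sigma_g^2}:
#' \describe{
#'   \item{`equal_contribution`}{each SNP contributes the same share,
#'     \eqn{\sigma_k^2 \sigma_{\beta_k}^2 = \sigma_g^2/M}, so the shrinkage
#'     diagonal is \eqn{\lambda_k = M \lambda \sigma_k^2}.}
#'   \item{`single_prior`}{one shared variance
#'     \eqn{\sigma_\beta^2 = \sigma_g^2 / \sum_k \sigma_k^2} (GBLUP prior),
#'     so \eqn{\lambda_k = \lambda \sum_t \sigma_t^2} for every k.}
#' }
#'
#' @param kind `"equal_contribution"` or `"single_prior"`.
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(kind = c("equal_contribution", "single_prior")) {
  structure(list(kind = match.arg(kind)), class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat("<variance_model>", x$kind, "\n")
  invisible(x)
}

stopifnot_vmodel <- function(model) {
  if (!inherits(model, "variance_model")) {
    stop("expected a `variance_model` object; see variance_model().",
         call. = FALSE)
  }
}

#' Shrinkage diagonal and effect variances implied by a variance model
#'
#' @param model a [variance_model()].
#' @param design a [design_spec()].
#' @param sigma_k2 per-SNP genotype variances.
#' @return `snp_lambda` gives the ridge diagonal \eqn{\lambda_k}
#'   (requires `lambda > 0`); `snp_effect_variance` the per-SNP effect
#'   variances \eqn{\sigma_{\beta_k}^2}.
#' @export
snp_lambda <- function(model, design, sigma_k2) {
  stopifnot_vmodel(model); stopifnot_design(design)
  switch(model$kind,
    equal_contribution = design$M * design$lambda * sigma_k2,
    single_prior       = rep(design$lambda * sum(sigma_k2), length(sigma_k2))
  )
}

#' @rdname snp_lambda
#' @export
snp_effect_variance <- function(model, design, sigma_k2) {
  stopifnot_vmodel(model); stopifnot_design(design)
  sg2 <- design$h2
  switch(model$kind,
    equal_contribution = sg2 / (design$M * sigma_k2),
    single_prior       = rep(sg2 / sum(sigma_k2), length(sigma_k2))
  )
}

#' Simulate a Hardy-Weinberg genotype panel in linkage equilibrium
#'
#' Draws allele frequencies from `dist` (or uses the supplied `freqs`), then
#' genotype counts \eqn{n_{ik} \sim \mathrm{Binomial}(2, f_k)} independently
#' across individuals and SNPs, and centres by the true frequency:
#' \eqn{X_{ik} = n_{ik} - 2 f_k}.
#'
#' @param N number of individuals.
#' @param dist a [freq_dist()]; ignored when `freqs` is supplied.
#' @param M number of SNPs; ignored when `freqs` is supplied.
#' @param seed optional integer seed (bit-identical panel for a fixed seed).
#' @param freqs optional frequency vector to reuse (e.g. to genotype
#'   selection candidates at the same frequencies as the reference panel).
#' @return An object of class `genotype_panel`: list with the centred `N x M`
#'   matrix `X`, `freqs`, and `sigma_k2 = 2 f (1 - f)`.
#' @export
simulate_genotypes <- function(N, dist = NULL, M = NULL, seed = NULL,
                               freqs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(freqs)) {
    stopifnot_freq_dist(dist)
    freqs <- sample_freqs(dist, M)
  }
  M <- length(freqs)
  n <- matrix(stats::rbinom(N * M, 2L, rep(freqs, each = N)), nrow = N)
  X <- sweep(n, 2L, 2 * freqs)
  structure(list(X = X, freqs = freqs, sigma_k2 = 2 * freqs * (1 - freqs)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

# independent per-replicate seeds spawned from one master seed, so results
# are order-independent across replicates
replicate_seeds <- function(seed, replicates) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max, replicates)
}

#' Exact Monte-Carlo precision of GEBV
#'
#' Estimates the marginal reliability
#' \eqn{r^2 = 1 - \lambda\, \mathrm{tr}[F\, E_X[(X'X + \Lambda)^{-1}]]}
#' by simulation: per replicate, allele frequencies are redrawn, a genotype
#' panel is simulated, \eqn{\Lambda} is built from the variance model, and
#' the trace is evaluated from the realised \eqn{(X'X+\Lambda)^{-1}} via a
#' symmetric (Cholesky) factorisation. The mean over replicates is returned
#' with its Monte-Carlo standard error.
#'
#' @param design a [design_spec()].
#' @param dist a [freq_dist()].
#' @param model a [variance_model()].
#' @param replicates number of replicates (>= 2).
#' @param seed master seed; spawns one independent sub-seed per replicate.
#' @param freeze_freqs if `TRUE`, frequencies are drawn once and reused in
#'   every replicate (variance-decomposition studies); default redraws them
#'   each replicate.
#' @return A [precision_estimate()] with method `"eq1_mc"`.
#' @export
true_precision_mc <- function(design, dist, model = variance_model(),
                              replicates = 100, seed = NULL,
                              freeze_freqs = FALSE) {
  stopifnot_design(design); stopifnot_freq_dist(dist); stopifnot_vmodel(model)
  if (replicates < 2) stop("`replicates` must be >= 2.", call. = FALSE)
  if (design$lambda == 0) {   # h2 = 1: Lambda = 0 and r2 = 1 exactly
    return(precision_estimate(1, "eq1_mc", mc_se = 0,
                              replicates = replicates, seed = seed))
  }
  seeds <- replicate_seeds(seed, replicates)
  frozen <- if (freeze_freqs) sample_freqs(dist, design$M) else NULL
  r2 <- vapply(seq_len(replicates), function(i) {
    set.seed(seeds[i])
    panel <- simulate_genotypes(design$N, dist, design$M, freqs = frozen)
    lam_k <- snp_lambda(model, design, panel$sigma_k2)
    A <- crossprod(panel$X)
    diag(A) <- diag(A) + lam_k
    inv_diag <- tryCatch(diag(chol2inv(chol(A))), error = function(e) {
      stop("singular ridge system in replicate ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
    1 - design$lambda * sum(panel$sigma_k2 * inv_diag)
  }, numeric(1))
  precision_estimate(mean(r2), "eq1_mc",
                     mc_se = stats::sd(r2) / sqrt(replicates),
                     replicates = replicates, seed = seed)
}

#' SNP-BLUP solutions
#'
#' Solves the ridge system \eqn{(X'X + \Lambda)\hat\beta = X'y} by a
#' symmetric positive-definite (Cholesky) solve.
#'
#' @param panel a `genotype_panel` from [simulate_genotypes()] (or any list
#'   with a matrix `X`).
#' @param y phenotype vector, length `nrow(panel$X)`.
#' @param lambda_k strictly positive shrinkage diagonal, length
#'   `ncol(panel$X)`.
#' @return Vector of M estimated SNP effects.
#' @export
snp_blup <- function(panel, y, lambda_k) {
  X <- panel$X
  if (length(y) != nrow(X)) {
    stop("`y` must have length nrow(X) = ", nrow(X), ".", call. = FALSE)
  }
  if (length(lambda_k) != ncol(X) || any(lambda_k <= 0)) {
    stop("`lambda_k` must be a positive vector of length ncol(X).",
         call. = FALSE)
  }
  A <- crossprod(X)
  diag(A) <- diag(A) + lambda_k
  drop(chol2inv(chol(A)) %*% crossprod(X, y))
}

#' Empirical GEBV precision from full phenotype simulation
#'
#' Simulates the entire evaluation per replicate: reference panel, SNP
#' effects (independent zero-mean normal draws with the variance-model
#' variances), residuals, phenotypes, SNP-BLUP fit, then a candidate panel
#' at the same allele frequencies. Reports the empirical reliability
#' \eqn{v(\hat g)/\sigma_g^2} (primary definition) and, as attribute
#' `r2_corr`, the mean squared correlation \eqn{\mathrm{cor}(g, \hat g)^2}.
#'
#' @inheritParams true_precision_mc
#' @param N_cand number of selection candidates per replicate (default 1000,
#'   chosen so candidate-side sampling noise stays below reference-side
#'   noise at the reference scales).
#' @return A [precision_estimate()] with method `"empirical"` and attribute
#'   `r2_corr`.
#' @export
empirical_precision <- function(design, N_cand = 1000, dist,
                                model = variance_model(), replicates = 100,
                                seed = NULL) {
  stopifnot_design(design); stopifnot_freq_dist(dist); stopifnot_vmodel(model)
  if (replicates < 2) stop("`replicates` must be >= 2.", call. = FALSE)
  if (N_cand < 2) stop("`N_cand` must be >= 2.", call. = FALSE)
  seeds <- replicate_seeds(seed, replicates)
  sg2 <- design$h2
  se2 <- 1 - design$h2
  res <- vapply(seq_len(replicates), function(i) {
    set.seed(seeds[i])
    panel <- simulate_genotypes(design$N, dist, design$M)
    sb2 <- snp_effect_variance(model, design, panel$sigma_k2)
    beta <- stats::rnorm(design$M, 0, sqrt(sb2))
    e <- stats::rnorm(design$N, 0, sqrt(se2))
    y <- drop(panel$X %*% beta) + e
    lam_k <- snp_lambda(model, design, panel$sigma_k2)
    # snp_lambda needs lambda > 0; at h2 = 1 shrinkage vanishes, use tiny ridge
    if (design$lambda == 0) lam_k <- rep(1e-8, design$M)
    beta_hat <- snp_blup(panel, y, lam_k)
    cand <- simulate_genotypes(N_cand, freqs = panel$freqs)
    g <- drop(cand$X %*% beta)
    g_hat <- drop(cand$X %*% beta_hat)
    c(stats::var(g_hat) / sg2, stats::cor(g, g_hat)^2)
  }, numeric(2))
  est <- precision_estimate(mean(res[1, ]), "empirical",
                            mc_se = stats::sd(res[1, ]) / sqrt(replicates),
                            replicates = replicates, seed = seed)
  attr(est, "r2_corr") <- mean(res[2, ])
  attr(est, "r2_corr_se") <- stats::sd(res[2, ]) / sqrt(replicates)
  est
}
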