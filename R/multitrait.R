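#' Multi-trait genomic evaluation design
#'
#' Design of a multivariate SNP-BLUP evaluation of `n_c` traits recorded on
#' the same `N` reference individuals, aimed at a selection index
#' \eqn{\gamma = a'g} with economic weights `a`. `Vg` and `Ve` are the
#' genetic and residual covariance matrices of the traits.
#'
#' @param Vg genetic covariance matrix (symmetric positive-definite).
#' @param Ve residual covariance matrix (symmetric positive-definite).
#' @param a vector of economic weights (not all zero).
#' @param N reference population size.
#' @param M number of SNPs.
#' @return An object of class `multitrait_design`.
#' @export
multitrait_design <- function(Vg, Ve, a, N, M) {
  Vg <- as.matrix(Vg); Ve <- as.matrix(Ve); a <- as.numeric(a)
  n_c <- length(a)
  check_spd <- function(V, nm) {
    if (nrow(V) != n_c || ncol(V) != n_c) {
      stop("`", nm, "` must be ", n_c, " x ", n_c,
           " to match the weight vector.", call. = FALSE)
    }
    if (max(abs(V - t(V))) > 1e-12 * max(1, max(abs(V)))) {
      stop("`", nm, "` is not symmetric.", call. = FALSE)
    }
    if (min(eigen(V, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("`", nm, "` is not positive-definite.", call. = FALSE)
    }
  }
  check_spd(Vg, "Vg"); check_spd(Ve, "Ve")
  if (all(a == 0)) stop("`a` must not be the zero vector.", call. = FALSE)
  if (N < 1 || M < 1) stop("`N` and `M` must be positive.", call. = FALSE)
  structure(list(n_traits = n_c, Vg = Vg, Ve = Ve, a = a,
                 N = as.numeric(N), M = as.numeric(M)),
            class = "multitrait_design")
}

#' @export
print.multitrait_design <- function(x, ...) {
  cat(sprintf("<multitrait_design> %d traits, N = %g, M = %g\n",
              x$n_traits, x$N, x$M))
  invisible(x)
}

stopifnot_mt <- function(design) {
  if (!inherits(design, "multitrait_design")) {
    stop("expected a `multitrait_design`; see multitrait_design().",
         call. = FALSE)
  }
}

#' First-order variance of the multivariate GEBV vector
#'
#' \deqn{\widehat{v(\hat g)} = N\, V_g (N V_g + M V_e)^{-1} V_g,}
#' the multivariate analogue of the first-order single-trait formula. The
#' inverse is applied through a symmetric factorisation and the result is
#' symmetrised to machine precision; it is positive-semidefinite and
#' dominated by `Vg`.
#'
#' @param design a [multitrait_design()].
#' @return The `n_c x n_c` predicted covariance matrix of the GEBV.
#' @export
gebv_variance_multitrait <- function(design) {
  stopifnot_mt(design)
  with(design, {
    Vhat <- N * Vg %*% solve(N * Vg + M * Ve, Vg)
    (Vhat + t(Vhat)) / 2
  })
}

#' Reliability of a linear selection index
#'
#' For \eqn{\gamma = a'g} and its BLUP \eqn{\hat\gamma = a'\hat g}, the
#' reliability \eqn{r^2 = \mathrm{cov}(\gamma,\hat\gamma)^2 /
#' (v(\gamma) v(\hat\gamma))} reduces, by the best-linear-predictor identity
#' \eqn{\mathrm{cov}(\gamma, \hat\gamma) = v(\hat\gamma)}, to the ratio of
#' quadratic forms \eqn{(a' \hat V a)/(a' V_g a)} with
#' \eqn{\hat V} from [gebv_variance_multitrait()]. Invariant to rescaling
#' of `a`; with one trait it equals the single-trait first-order formula.
#'
#' @param design a [multitrait_design()].
#' @return A [precision_estimate()] with method `"eq10_index"`.
#' @export
index_precision <- function(design) {
  stopifnot_mt(design)
  Vhat <- gebv_variance_multitrait(design)
  a <- design$a
  precision_estimate(drop(a %*% Vhat %*% a) / drop(a %*% design$Vg %*% a),
                     "eq10_index")
}

#' Empirical index reliability from a multivariate SNP-BLUP simulation
#'
#' Validation counterpart of [index_precision()]: per replicate, SNP effect
#' vectors are drawn per SNP from a zero-mean multivariate normal with
#' covariance \eqn{V_g / (M \sigma_k^2)} (the multi-trait extension of the
#' equal-contribution prior), phenotypes from residual covariance `Ve`, and
#' all traits are evaluated jointly by the full multivariate mixed-model
#' system. Reports \eqn{v(\hat\gamma)/v(\gamma)} with
#' \eqn{v(\gamma) = a' V_g a}.
#'
#' @param design a [multitrait_design()].
#' @param dist a [freq_dist()] for the panel frequencies.
#' @param N_cand candidates per replicate.
#' @param replicates number of replicates (>= 2).
#' @param seed master seed.
#' @return A [precision_estimate()] with method `"empirical"`.
#' @export
empirical_index_precision <- function(design, dist, N_cand = 1000,
                                      replicates = 20, seed = NULL) {
  stopifnot_mt(design); stopifnot_freq_dist(dist)
  if (replicates < 2) stop("`replicates` must be >= 2.", call. = FALSE)
  n_c <- design$n_traits; M <- design$M; N <- design$N
  a <- design$a
  seeds <- replicate_seeds(seed, replicates)
  Rg <- chol(design$Vg)        # for per-SNP effect draws
  Re <- chol(design$Ve)
  Vg_inv <- chol2inv(Rg)
  Ve_inv <- chol2inv(Re)
  v_gamma <- drop(a %*% design$Vg %*% a)
  r2 <- vapply(seq_len(replicates), function(i) {
    set.seed(seeds[i])
    panel <- simulate_genotypes(N, dist, M)
    s2 <- panel$sigma_k2
    # effects: beta[k, ] ~ MVN(0, Vg / (M * sigma_k2)); trait-major stacking
    beta <- (matrix(stats::rnorm(M * n_c), M) %*% Rg) / sqrt(M * s2)
    e <- matrix(stats::rnorm(N * n_c), N) %*% Re
    Y <- panel$X %*% beta + e                       # N x n_c
    # multivariate MME for stacked effects b = vec(beta) (trait-major):
    # (Ve^-1 (x) X'X + Vg^-1 (x) diag(M s2)) b = (Ve^-1 (x) X') vec(Y)
    XtX <- crossprod(panel$X)
    LHS <- kronecker(Ve_inv, XtX) + kronecker(Vg_inv, diag(M * s2, M))
    RHS <- as.vector(crossprod(panel$X, Y %*% Ve_inv))
    beta_hat <- matrix(solve(LHS, RHS), M, n_c)
    cand <- simulate_genotypes(N_cand, freqs = panel$freqs)
    gamma <- drop(cand$X %*% beta %*% a)
    gamma_hat <- drop(cand$X %*% beta_hat %*% a)
    stats::var(gamma_hat) / v_gamma
  }, numeric(1))
  precision_estimate(mean(r2), "empirical",
                     mc_se = stats::sd(r2) / sqrt(replicates),
                     replicates = replicates, seed = seed)
}

#' Read a multi-trait design from a structured text config
#'
#' Format: section headers `[Vg]`, `[Ve]`, `[a]` followed by matrix rows as
#' comma-separated numbers, plus `N = <int>` and `M = <int>` lines anywhere
#' outside sections. `#` comment lines are ignored. Symmetry and positive
#' definiteness are validated on load.
#'
#' @param path file path.
#' @return A [multitrait_design()].
#' @export
read_multitrait_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sections <- list()
  scalars <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      sections[[current]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && is.null(current)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      scalars[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
    } else if (!is.null(current)) {
      sections[[current]] <- c(sections[[current]],
                               list(as.numeric(strsplit(ln, ",")[[1]])))
    } else {
      stop("unparseable config line: ", ln, call. = FALSE)
    }
  }
  need <- function(nm) {
    if (is.null(sections[[nm]])) stop("missing [", nm, "] section.",
                                      call. = FALSE)
    do.call(rbind, sections[[nm]])
  }
  for (nm in c("N", "M")) {
    if (is.null(scalars[[nm]])) stop("missing `", nm, " = ...` line.",
                                     call. = FALSE)
  }
  multitrait_design(Vg = need("Vg"), Ve = need("Ve"),
                    a = drop(need("a")), N = scalars$N, M = scalars$M)
}
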