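#' Closed-form prediction grid
#'
#' Evaluates a set of closed-form predictors over the Cartesian grid of
#' design parameters and returns one tidy row per design x method
#' combination, in the package's single TSV dialect (columns `method, N, M,
#' h2, fmin, dist, var_model, replicates, seed, r2, mc_se`).
#'
#' @param N,M,h2,fmin vectors of design values (expanded as a grid).
#' @param dist `"uniform"` or `"ushape"` (tag only for closed forms; used by
#'   the frequency-dependent methods).
#' @param methods character vector among `eq2, eq3, eq5, eq7, eq8, eq9,
#'   goddard`.
#' @return A `data.frame`, stable-sorted by `(fmin, h2, method)`.
#' @export
run_predict <- function(N, M, h2, fmin = 0.05, dist = "uniform",
                        methods = c("eq2", "eq3", "eq5", "eq7")) {
  known <- c("eq2", "eq3", "eq5", "eq7", "eq8", "eq9", "goddard")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "),
         "; choose from ", paste(known, collapse = ", "), ".", call. = FALSE)
  }
  grid <- expand.grid(N = N, M = M, h2 = h2, fmin = fmin, method = methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$r2 <- vapply(seq_len(nrow(grid)), function(i) {
    d <- design_spec(grid$N[i], grid$M[i], grid$h2[i])
    fm <- grid$fmin[i]
    switch(grid$method[i],
      eq2     = daetwyler_basic(d)$value,
      eq3     = daetwyler_corrected(d)$value,
      eq5     = first_order(d)$value,
      eq7     = second_order_uniform(d, fm)$value,
      eq8     = second_order_ushape(d)$value,
      eq9     = single_variance_first_order(d, fm)$value,
      goddard = goddard_comparator(d, fm)$value
    )
  }, numeric(1))
  out <- data.frame(method = grid$method, N = grid$N, M = grid$M,
                    h2 = grid$h2, fmin = grid$fmin, dist = dist,
                    var_model = "equal_contribution", replicates = NA_integer_,
                    seed = NA_integer_, r2 = grid$r2, mc_se = NA_real_,
                    stringsAsFactors = FALSE)
  out[order(out$fmin, out$h2, out$method), , drop = FALSE]
}

# the reference grid of the result tables: two MAF bounds x four heritabilities
table_grid <- function() {
  expand.grid(fmin = c(0.05, 0.025), h2 = c(0.1, 0.3, 0.5, 0.7),
              KEEP.OUT.ATTRS = FALSE)[order(rep(c(1, 2), 4)), c("fmin", "h2")]
}

#' Reproduce the uniform-frequency reference grid
#'
#' The 8-row grid (`fmin` in \{0.05, 0.025\} x `h2` in \{0.1, 0.3, 0.5,
#' 0.7\}) at `N = 5000`, `M = 500` under the uniform allele-frequency law:
#' Monte-Carlo true precision plus the closed forms `eq2, eq3, eq5, eq7`.
#'
#' @param replicates Monte-Carlo replicates for the `true_mc` column.
#' @param seed master seed for the Monte-Carlo column.
#' @param N,M design scale (defaults: the reference grid scale).
#' @param mc set `FALSE` to skip the Monte-Carlo column (closed forms only).
#' @return A `data.frame` with columns `fmin, h2, true_mc, true_mc_se, eq2,
#'   eq3, eq5, eq7`.
#' @export
reproduce_table2 <- function(replicates = 100, seed = NULL, N = 5000, M = 500,
                             mc = TRUE) {
  if (replicates < 2) stop("`replicates` must be >= 2.", call. = FALSE)
  g <- table_grid()
  rows <- lapply(seq_len(nrow(g)), function(i) {
    fm <- g$fmin[i]; h2 <- g$h2[i]
    d <- design_spec(N, M, h2)
    tm <- if (mc) {
      true_precision_mc(d, freq_dist("uniform", fm), variance_model(),
                        replicates = replicates,
                        seed = if (is.null(seed)) NULL else seed + i)
    } else NULL
    data.frame(fmin = fm, h2 = h2,
               true_mc = if (mc) tm$value else NA_real_,
               true_mc_se = if (mc) tm$mc_se else NA_real_,
               eq2 = daetwyler_basic(d)$value,
               eq3 = daetwyler_corrected(d)$value,
               eq5 = first_order(d)$value,
               eq7 = second_order_uniform(d, fm)$value)
  })
  do.call(rbind, rows)
}

#' Reproduce the U-shaped-frequency reference grid
#'
#' Same 8-row grid under the U-shaped allele-frequency law: Monte-Carlo true
#' precision plus `eq8`, `eq3` and the Goddard comparator.
#'
#' @inheritParams reproduce_table2
#' @return A `data.frame` with columns `fmin, h2, true_mc, true_mc_se, eq8,
#'   eq3, goddard`.
#' @export
reproduce_table3 <- function(replicates = 100, seed = NULL, N = 5000, M = 500,
                             mc = TRUE) {
  if (replicates < 2) stop("`replicates` must be >= 2.", call. = FALSE)
  g <- table_grid()
  rows <- lapply(seq_len(nrow(g)), function(i) {
    fm <- g$fmin[i]; h2 <- g$h2[i]
    d <- design_spec(N, M, h2)
    tm <- if (mc) {
      true_precision_mc(d, freq_dist("ushape", fm), variance_model(),
                        replicates = replicates,
                        seed = if (is.null(seed)) NULL else seed + 100 + i)
    } else NULL
    data.frame(fmin = fm, h2 = h2,
               true_mc = if (mc) tm$value else NA_real_,
               true_mc_se = if (mc) tm$mc_se else NA_real_,
               eq8 = second_order_ushape(d)$value,
               eq3 = daetwyler_corrected(d)$value,
               goddard = goddard_comparator(d, fm)$value)
  })
  do.call(rbind, rows)
}

#' Precision sweep over reference population size
#'
#' Closed-form precision along `N = 1000, 2000, ..., 10000` (the standard
#' design-exploration range) for fixed `M`, `h2`, `fmin`.
#'
#' @param M,h2,fmin scalars.
#' @param N vector of population sizes.
#' @param methods methods to include (see [run_predict()]).
#' @return A tidy `data.frame` as in [run_predict()].
#' @export
run_sweep <- function(M = 500, h2 = 0.3, fmin = 0.05,
                      N = seq(1000, 10000, by = 1000),
                      methods = c("eq2", "eq3", "eq5", "eq7", "eq8")) {
  out <- run_predict(N = N, M = M, h2 = h2, fmin = fmin, methods = methods)
  out[order(out$N, out$method), , drop = FALSE]
}

#' Write a results data.frame as TSV
#'
#' Tab-separated, header row, `.` decimal separator, no quoting or locale
#' effects.
#'
#' @param df a `data.frame`.
#' @param path output path, or `""` for standard output.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path = "") {
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
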