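d_ref <- function(h2) design_spec(5000, 500, h2)

test_that("design_spec validates and derives lambda", {
  d <- d_ref(0.3)
  expect_equal(d$lambda, 0.7 / 0.3)
  expect_equal(design_spec(10, 10, 1)$lambda, 0)
  expect_error(design_spec(0, 500, 0.3), "positive integer")
  expect_error(design_spec(5000, 500, 0), "0, 1")
  expect_error(design_spec(5000, 500, 1.2), "0, 1")
})

test_that("precision_estimate enforces the mc_se contract", {
  expect_error(precision_estimate(0.5, "eq1_mc"), "mc_se")
  expect_error(precision_estimate(0.5, "eq2", mc_se = 0.1), "must not")
  est <- precision_estimate(0.5, "eq1_mc", mc_se = 0.01, replicates = 10)
  expect_s3_class(est, "precision_estimate")
})

test_that("closed forms match independent plug-in arithmetic", {
  N <- 5000; M <- 500
  for (h2 in c(0.1, 0.3, 0.5, 0.7)) {
    lam <- (1 - h2) / h2
    expect_equal(daetwyler_basic(d_ref(h2))$value, N * h2 / (N * h2 + M),
                 tolerance = 1e-12)
    expect_equal(daetwyler_corrected(d_ref(h2))$value,
                 (M + N * h2 - sqrt((M + N * h2)^2 - 4 * N * M * h2^2)) /
                   (2 * M * h2), tolerance = 1e-12)
    expect_equal(first_order(d_ref(h2))$value, N * h2 / (N * h2 + M * (1 - h2)),
                 tolerance = 1e-12)
    expect_equal(second_order_ushape(d_ref(h2))$value,
                 N / (N + M * lam) - lam * (M / N)^2 * (N / (N + M * lam))^3,
                 tolerance = 1e-12)
  }
  # second order at sigma_k2 = 0.5 for all k (f = 0.5): hand plug-in
  d <- d_ref(0.3)
  hand <- 5000 / (5000 + 500 * 7 / 3) -
    (7 / 3) * 5000 * 500 / (5000 + 500 * 7 / 3)^3 * (500 - 2 + 2)
  expect_equal(second_order_from_variances(d, rep(0.5, 500))$value, hand,
               tolerance = 1e-12)
  expect_equal(hand, 0.798373, tolerance = 1e-5)
})

test_that("limits and short-circuits at h2 = 1 and N -> infinity", {
  expect_equal(daetwyler_basic(design_spec(1e12, 500, 0.3))$value, 1,
               tolerance = 1e-8)
  dh1 <- design_spec(5000, 500, 1)
  expect_equal(daetwyler_corrected(dh1)$value, 1)
  expect_equal(first_order(dh1)$value, 1)
  expect_equal(second_order_from_variances(dh1, rep(0.4, 500))$value, 1)
  expect_equal(second_order_uniform(dh1, 0.05)$value, 1)
  expect_equal(second_order_ushape(dh1)$value, 1)
  expect_equal(single_variance_first_order(dh1, 0.05)$value, 1)
  expect_equal(goddard_comparator(dh1, 0.05)$value, 1)
  # (M/N)^2 decay: the ushape form converges to the first order as N grows
  dN <- design_spec(1e8, 500, 0.3)
  expect_lt(abs(second_order_ushape(dN)$value - first_order(dN)$value), 1e-6)
})

test_that("eq6 equals eq7 when realised variances carry the uniform moment", {
  d <- d_ref(0.5)
  E <- expected_inv_variance(freq_dist("uniform", 0.05))
  # all sigma_k2 set to the harmonic value 1/E so mean(1/sigma^2) = E
  expect_equal(second_order_from_variances(d, rep(1 / E, 500))$value,
               second_order_uniform(d, 0.05)$value, tolerance = 1e-12)
  # law of large numbers: realised variances from sampled frequencies
  set.seed(31)
  reps <- vapply(1:200, function(i) {
    f <- sample_freqs(freq_dist("uniform", 0.05), 500)
    second_order_from_variances(d, 2 * f * (1 - f))$value
  }, numeric(1))
  expect_lt(abs(mean(reps) - second_order_uniform(d, 0.05)$value),
            3 * sd(reps) / sqrt(length(reps)))
  expect_error(second_order_from_variances(d, rep(0.6, 500)), "0, 0.5")
  expect_error(second_order_from_variances(d, rep(0.4, 10)), "length")
})

test_that("eq9 matches the quadrature oracle for its expectation", {
  # Eq9's closed form is the exact evaluation of
  # 1 - lambda*M*E_f[sigma^2/(N sigma^2 + lambda_beta)] under the uniform law
  for (h2 in c(0.3, 0.5)) {
    for (fm in c(0.025, 0.05)) {
      d <- d_ref(h2)
      lam_b <- d$M * expected_variance_uniform(fm) * d$lambda
      dist <- freq_dist("uniform", fm)
      E <- quad_moment(dist, function(f) {
        s2 <- 2 * f * (1 - f)
        s2 / (d$N * s2 + lam_b)
      }, rel.tol = 1e-12)
      expect_equal(single_variance_first_order(d, fm)$value,
                   1 - d$lambda * d$M * E, tolerance = 1e-9)
    }
  }
  v <- single_variance_first_order(d_ref(0.5), 0.05)$value
  expect_true(v > 0 && v <= 1)
})

test_that("marker-coverage adjustment b*method(b*h2)", {
  d <- d_ref(0.3)
  expect_equal(adjust_for_marker_coverage(d, 1, first_order)$value,
               first_order(d)$value)
  expect_equal(adjust_for_marker_coverage(d, 0, first_order)$value, 0)
  expect_equal(adjust_for_marker_coverage(d, 0.8, first_order)$value,
               0.8 * (5000 * 0.24) / (5000 * 0.24 + 500 * 0.76),
               tolerance = 1e-12)
  # works with frequency-dependent methods too
  expect_equal(adjust_for_marker_coverage(d, 0.8, second_order_uniform,
                                          f_min = 0.05)$value,
               0.8 * second_order_uniform(design_spec(5000, 500, 0.24),
                                          0.05)$value, tolerance = 1e-12)
})

test_that("ordering and monotonicity hold across the design grid", {
  for (N in c(1000, 5000, 10000)) {
    for (M in c(500, 1000)) {
      for (h2 in c(0.1, 0.3, 0.5, 0.7)) {
        d <- design_spec(N, M, h2)
        eq2 <- daetwyler_basic(d)$value
        eq5 <- first_order(d)$value
        eq7 <- second_order_uniform(d, 0.05)$value
        expect_lte(eq2, eq5)
        expect_lte(eq7, eq5)
        vals <- c(eq2, daetwyler_corrected(d)$value, eq5, eq7,
                  second_order_ushape(d)$value,
                  goddard_comparator(d, 0.05)$value,
                  single_variance_first_order(d, 0.05)$value)
        expect_true(all(vals >= 0 & vals <= 1))
      }
    }
  }
  # monotone in N and h2, antitone in M, for each method
  methods <- list(
    function(d) daetwyler_basic(d)$value,
    function(d) daetwyler_corrected(d)$value,
    function(d) first_order(d)$value,
    function(d) second_order_uniform(d, 0.05)$value,
    function(d) second_order_ushape(d)$value,
    function(d) goddard_comparator(d, 0.05)$value,
    function(d) single_variance_first_order(d, 0.05)$value
  )
  for (m in methods) {
    vN <- vapply(seq(1000, 10000, 1000),
                 function(N) m(design_spec(N, 500, 0.3)), numeric(1))
    expect_true(all(diff(vN) >= -1e-12))
    vh <- vapply(seq(0.1, 0.7, 0.1),
                 function(h2) m(design_spec(5000, 500, h2)), numeric(1))
    expect_true(all(diff(vh) >= -1e-12))
    vM <- vapply(c(500, 1000), function(M) m(design_spec(5000, M, 0.3)),
                 numeric(1))
    expect_lte(vM[2], vM[1])
  }
})
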