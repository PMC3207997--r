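fams <- default_repeat_families()

test_that("size factors match the median-of-ratios definition", {
  set.seed(60)
  m <- matrix(rpois(120, 200), nrow = 12,
              dimnames = list(fams, paste0("s", 1:10)))
  s <- estimate_size_factors(m)
  # identical columns give unit factors
  mc <- matrix(rep(m[, 1], 4), ncol = 4,
               dimnames = list(fams, paste0("c", 1:4)))
  expect_equal(unname(estimate_size_factors(mc)), rep(1, 4))
  # exact doubling doubles the factor
  m2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  s2 <- estimate_size_factors(m2)
  expect_equal(unname(s2[2] / s2[1]), 2)
  # direct formula evaluation
  loggeo <- rowMeans(log(m))
  direct <- apply(m, 2, function(cnts)
    exp(median((log(cnts) - loggeo)[is.finite(loggeo) & cnts > 0])))
  expect_equal(s, direct)
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(61)
  m <- matrix(rnbinom(240, mu = 150, size = 5), nrow = 12,
              dimnames = list(fams, paste0("s", 1:20)))
  expect_equal(unname(estimate_size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)))
})

test_that("size factors are scale-equivariant and guarded", {
  set.seed(62)
  m <- matrix(rpois(60, 100), nrow = 12, ncol = 5,
              dimnames = list(fams, paste0("s", 1:5)))
  s <- estimate_size_factors(m)
  m3 <- m; m3[, 3] <- m3[, 3] * 5L
  s3 <- estimate_size_factors(m3)
  # factors are defined relative to the geometric-mean reference, so the
  # equivariance holds for ratios between samples
  expect_equal(unname((s3[3] / s3[1]) / (s[3] / s[1])), 5)
  zeros <- matrix(0L, nrow = 2, ncol = 2,
                  dimnames = list(c("a", "b"), c("x", "y")))
  zeros[1, 1] <- 5L; zeros[2, 2] <- 5L
  expect_error(estimate_size_factors(zeros), "pseudocount|nonzero")
})

test_that("dispersion fit recovers Poisson and NB regimes", {
  set.seed(63)
  mus <- c(10, 20, 40, 80, 160, 320, 640, 30, 60, 120, 240, 480)
  # Poisson data: raw variance should be near zero relative to shot noise
  mp <- matrix(rpois(12 * 100, rep(mus, 100)), nrow = 12,
               dimnames = list(fams, paste0("s", 1:100)))
  fit <- fit_dispersion(mp, rep(1, 100))
  expect_true(all(abs(fit$table$w_fit - fit$table$base_mean) /
                    fit$table$base_mean < 0.35))
  expect_lt(median(fit$table$raw_scv), 0.01)
  # NB data with alpha = 0.1: recovered scv within 50% at the top means
  mn <- matrix(rnbinom(12 * 100, mu = rep(mus, 100), size = 10), nrow = 12,
               dimnames = list(fams, paste0("s", 1:100)))
  fitn <- fit_dispersion(mn, rep(1, 100))
  big <- fitn$table$base_mean > 100
  expect_true(all(abs(fitn$table$raw_scv[big] - 0.1) < 0.05))
})

test_that("constant counts floor at shot noise, single sample errors", {
  m <- matrix(7L, nrow = 12, ncol = 5,
              dimnames = list(fams, paste0("s", 1:5)))
  fit <- fit_dispersion(m, rep(1, 5), sharing = "fit-only")
  expect_equal(fit$table$raw_var, rep(0, 12))  # variance 0 -> Poisson floor
  expect_error(fit_dispersion(m[, 1, drop = FALSE], 1), "2 samples")
})

test_that("exact test gives p = 1 for a symmetric observed split", {
  res <- nb_exact_test(50, 50, 50, 50, 60, 60)
  expect_equal(res$p, 1)
  expect_equal(nb_exact_test(0, 0, 5, 5)$p, 1)  # zero total, flagged
  expect_equal(nb_exact_test(0, 0, 5, 5)$flag, "zero_total")
})

test_that("Poisson-limit p-values equal exhaustive enumeration", {
  cases <- list(c(3, 17, 5, 15), c(10, 10, 10, 10), c(0, 20, 8, 12),
                c(40, 60, 55, 45), c(100, 100, 80, 120))
  for (cs in cases) {
    mine <- nb_exact_test(cs[1], cs[2], cs[3], cs[4],
                          var_a = cs[3], var_b = cs[4])
    orc <- poisson_exact_oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(mine$p, orc, tolerance = 1e-9)
  }
})

test_that("p decreases monotonically with the planted mean shift", {
  shifts <- c(1, 1.5, 2, 3, 5)
  ps <- vapply(shifts, function(f) {
    k_b <- 1000; k_a <- round(100 * f)
    nb_exact_test(k_a, k_b, mu_a = 110, mu_b = 1100,
                  var_a = 130, var_b = 1400)$log10_p
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("log-space p survives astronomically small tails", {
  res <- nb_exact_test(20000, 2000, 11000, 11000, 12000, 12000)
  expect_lt(res$log10_p, -300)
  expect_true(is.finite(res$log10_p))
})

test_that("BH step-up equals its definition and p.adjust", {
  set.seed(64)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  expect_equal(bh_adjust(0.02), 0.02)            # single p unchanged
  expect_equal(bh_adjust(rep(0.3, 6)), rep(0.3, 6))  # uniform tie
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # permutation invariance and idempotence on monotone capped vectors
  p <- c(0.001, 0.02, 0.5, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  adj <- bh_adjust(p)
  expect_true(all(bh_adjust(adj) >= adj - 1e-12))
})

test_that("identical observed and simulated matrices give null results", {
  set.seed(65)
  m <- matrix(rpois(120, 300), nrow = 12,
              dimnames = list(fams, paste0("s", 1:10)))
  obs <- family_count_matrix(m, "observed")
  sim <- family_count_matrix(`colnames<-`(m, paste0("d", 1:10)),
                             "simulated_repeats")
  res <- run_family_test(obs, sim)
  expect_equal(res$fold_change, rep(1, 12))
  expect_equal(res$p_raw, rep(1, 12))
  expect_equal(res$p_adj, rep(1, 12))
})

test_that("adjusted p-values never fall below raw ones", {
  set.seed(66)
  obs <- family_count_matrix(
    matrix(rpois(36, 100), nrow = 12,
           dimnames = list(fams, paste0("s", 1:3))), "observed")
  sim <- family_count_matrix(
    matrix(rpois(60, 120), nrow = 12,
           dimnames = list(fams, paste0("d", 1:5))), "simulated_repeats")
  res <- run_family_test(obs, sim)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(res$log10_p_adj >= res$log10_p_raw - 1e-9))
  expect_error(run_family_test(obs, family_count_matrix(
    matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
    "simulated_repeats")), "family ordering")
})
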