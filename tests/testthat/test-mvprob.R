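test_that("correlation validation repairs tiny negative eigenvalues only", {
  R <- diag(3)
  expect_false(as_correlation(R)$repaired)
  # rank-deficient but PSD: perfect correlation passes unrepaired
  P <- matrix(1, 2, 2)
  expect_false(as_correlation(P)$repaired)
  bad <- matrix(c(1, 0.9, 0.9, 1), 2)
  bad[1, 2] <- 2                       # asymmetric
  expect_error(as_correlation(bad), "not symmetric")
  expect_error(as_correlation(diag(2) * 1.5), "diagonal")
  # beyond repair: eigenvalue well below -1e-8
  M <- matrix(c(1, 1.01, 1.01, 1), 2)
  expect_error(as_correlation(M), "positive semi-definite")
})

test_that("univariate and identity cases match closed forms", {
  p1 <- equicoordinate_probability(1.959964, diag(1), df = Inf, seed = 1)
  expect_equal(p1$value, 0.95, tolerance = 1e-6)
  expect_equal(p1$est_error, 0)

  p3 <- equicoordinate_probability(1.959964, diag(3), df = Inf, seed = 1,
                                   accuracy = 1e-4)
  expect_equal(p3$value, 0.95^3, tolerance = 3e-4)
  expect_lte(p3$est_error, 2e-4)

  # product form for the normal at several dimensions and thresholds
  for (k in c(2, 5, 15, 20)) {
    for (t in c(1.5, 2.5)) {
      p <- equicoordinate_probability(t, diag(k), df = Inf, seed = k,
                                      accuracy = 1e-4)
      expect_equal(p$value, (2 * pnorm(t) - 1)^k, tolerance = 3e-4,
                   label = sprintf("k=%d t=%.1f", k, t))
    }
  }
})

test_that("finite-df identity case matches the chi-scale mixture oracle", {
  # the standard multivariate t shares one chi-square scale, so the
  # unconditional product form applies only at df = Inf; the oracle mixes
  # the conditional product over the scale
  for (k in c(2, 5, 15)) {
    for (df in c(5, 30)) {
      p <- equicoordinate_probability(1.9, diag(k), df = df, seed = k + df,
                                      accuracy = 1e-4)
      expect_equal(p$value, ident_mvt_oracle(1.9, k, df), tolerance = 3e-4,
                   label = sprintf("k=%d df=%d", k, df))
    }
  }
})

test_that("probability is monotone in t with boundary values 0 and 1", {
  R <- random_correlation(4, seed = 5)
  expect_equal(equicoordinate_probability(0, R, df = Inf, seed = 1)$value, 0)
  ts <- c(0.5, 1, 1.5, 2, 3, 6)
  ps <- vapply(ts, function(t) {
    equicoordinate_probability(t, R, df = 10, seed = 7,
                               accuracy = 1e-4)$value
  }, numeric(1))
  expect_true(all(diff(ps) > -3e-4))
  expect_gt(ps[length(ps)], 0.999)
})

test_that("perfect correlation collapses to the univariate probability", {
  R <- matrix(1 - 1e-10, 4, 4); diag(R) <- 1
  p <- equicoordinate_probability(1.959964, R, df = Inf, seed = 2,
                                  accuracy = 1e-4)
  expect_equal(p$value, 0.95, tolerance = 1e-3)
})

test_that("multivariate t converges to the normal as df grows", {
  R <- random_correlation(5, seed = 8)
  pt_ <- equicoordinate_probability(2.2, R, df = 1e6, seed = 3,
                                    accuracy = 1e-4)$value
  pn <- equicoordinate_probability(2.2, R, df = Inf, seed = 3,
                                   accuracy = 1e-4)$value
  expect_equal(pt_, pn, tolerance = 5e-4)
})

test_that("low-dimensional probabilities match dense quadrature oracles", {
  # k = 2, normal and t
  for (rho in c(-0.4, 0.3, 0.8)) {
    R <- matrix(c(1, rho, rho, 1), 2)
    p <- equicoordinate_probability(1.7, R, df = Inf, seed = 4,
                                    accuracy = 1e-4)
    expect_equal(p$value, mvn2_oracle(1.7, rho), tolerance = 1e-3,
                 label = paste("normal rho", rho))
    pt2 <- equicoordinate_probability(1.7, R, df = 12, seed = 4,
                                      accuracy = 1e-4)
    expect_equal(pt2$value, mvt_oracle(1.7, R, 12), tolerance = 1e-3,
                 label = paste("t rho", rho))
  }
  # k = 3 with an unstructured correlation
  R3 <- random_correlation(3, seed = 21)
  p3 <- equicoordinate_probability(2.1, R3, df = Inf, seed = 6,
                                   accuracy = 1e-4)
  expect_equal(p3$value, mvn3_oracle(2.1, R3), tolerance = 1e-3)
  p3t <- equicoordinate_probability(2.1, R3, df = 9, seed = 6,
                                    accuracy = 1e-4)
  expect_equal(p3t$value, mvt_oracle(2.1, R3, 9), tolerance = 1e-3)
})

test_that("probabilities agree with the reference QMC implementation", {
  skip_if_not_installed("mvtnorm")
  R <- random_correlation(6, seed = 33)
  for (df in c(20, Inf)) {
    mine <- equicoordinate_probability(2.4, R, df = df, seed = 9,
                                       accuracy = 1e-4)$value
    ref <- if (is.finite(df)) {
      mvtnorm::pmvt(lower = rep(-2.4, 6), upper = rep(2.4, 6), df = df,
                    corr = R, algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                             maxpts = 1e6))
    } else {
      mvtnorm::pmvnorm(lower = rep(-2.4, 6), upper = rep(2.4, 6), corr = R,
                       algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                      maxpts = 1e6))
    }
    expect_equal(mine, as.numeric(ref), tolerance = 5e-4)
  }
})

test_that("quantiles match the Sidak closed form under independence", {
  q1 <- equicoordinate_quantile(0.05, diag(1), df = Inf, seed = 1)
  expect_equal(as.numeric(q1), 1.959964, tolerance = 1e-3)
  q1t <- equicoordinate_quantile(0.05, diag(1), df = 7, seed = 1)
  expect_equal(as.numeric(q1t), qt(0.975, 7), tolerance = 1e-6)

  # independence: exact Sidak value for the normal
  sidak <- qnorm(1 - (1 - 0.95^(1 / 15)) / 2)
  q15 <- equicoordinate_quantile(0.05, diag(15), df = Inf, seed = 2,
                                 accuracy = 1e-4)
  expect_equal(as.numeric(q15), sidak, tolerance = 5e-3)
})

test_that("quantile and probability round-trip at QMC precision", {
  for (spec in list(list(k = 4, df = Inf), list(k = 6, df = 30),
                    list(k = 3, df = 5))) {
    R <- random_correlation(spec$k, seed = spec$k * 7)
    q <- equicoordinate_quantile(0.05, R, df = spec$df, seed = 11,
                                 accuracy = 1e-4)
    p <- equicoordinate_probability(as.numeric(q), R, df = spec$df,
                                    seed = 11, accuracy = 1e-4)
    expect_equal(p$value, 0.95, tolerance = 3e-4,
                 label = sprintf("k=%d df=%s", spec$k, spec$df))
  }
})

test_that("invalid inputs are rejected", {
  expect_error(equicoordinate_probability(-1, diag(2)), "non-negative")
  expect_error(equicoordinate_quantile(1.2, diag(2)), "alpha")
})
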