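# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: sandwich matrices by element-wise
# accumulation, rectangle probabilities by quadrature, the studentized
# range by its defining double integral.

# n x p indicator (cell-means) design from a group factor
indicator_design <- function(group_index) {
  stats::model.matrix(~ 0 + group_index)
}

# (X'X)^-1 X' diag(w) X (X'X)^-1 accumulated observation by observation
brute_sandwich <- function(X, w) {
  p <- ncol(X)
  bread <- solve(t(X) %*% X)
  meat <- matrix(0, p, p)
  for (i in seq_len(nrow(X))) {
    meat <- meat + w[i] * tcrossprod(X[i, ])
  }
  bread %*% meat %*% bread
}

hc_weights <- function(e, h, n, p, type) {
  switch(type,
         HC0 = e^2,
         HC1 = e^2 * n / (n - p),
         HC2 = e^2 / (1 - h),
         HC3 = e^2 / (1 - h)^2)
}

# P(|X1|<=t, |X2|<=t) for bivariate normal, correlation rho: 1-D quadrature
mvn2_oracle <- function(t, rho) {
  s <- sqrt(1 - rho^2)
  stats::integrate(function(x) {
    stats::dnorm(x) * (stats::pnorm((t - rho * x) / s) -
                       stats::pnorm((-t - rho * x) / s))
  }, -t, t, rel.tol = 1e-10)$value
}

# trivariate normal rectangle probability: 2-D quadrature over (x1, x2)
# with the conditional distribution of x3
mvn3_oracle <- function(t, R) {
  b <- solve(R[1:2, 1:2], R[1:2, 3])
  s3 <- sqrt(1 - sum(b * R[1:2, 3]))
  r <- R[1, 2]
  f <- function(x, y) {
    dens <- exp(-(x^2 - 2 * r * x * y + y^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
    mu <- b[1] * x + b[2] * y
    dens * (stats::pnorm((t - mu) / s3) - stats::pnorm((-t - mu) / s3))
  }
  pracma::integral2(f, -t, t, -t, t, reltol = 1e-8)$Q
}

# finite-df equicoordinate probability by mixing the normal oracle over the
# shared chi-square scale (k <= 3)
mvt_oracle <- function(t, R, df) {
  k <- nrow(R)
  inner <- function(tt) {
    if (k == 1) stats::pnorm(tt) - stats::pnorm(-tt)
    else if (k == 2) mvn2_oracle(tt, R[1, 2])
    else mvn3_oracle(tt, R)
  }
  stats::integrate(Vectorize(function(u) {
    inner(t * sqrt(stats::qchisq(u, df) / df))
  }), 0, 1, rel.tol = 1e-7)$value
}

# identity-correlation finite-df probability: conditional product over the
# shared chi-square scale (any k)
ident_mvt_oracle <- function(t, k, df) {
  if (!is.finite(df)) return((stats::pnorm(t) - stats::pnorm(-t))^k)
  stats::integrate(function(u) {
    (2 * stats::pnorm(t * sqrt(stats::qchisq(u, df) / df)) - 1)^k
  }, 0, 1, rel.tol = 1e-10)$value
}

# studentized range CDF P(Q_{k, df} <= q) from its defining double
# integral: outer over the chi scale s, inner over the location z
srange_cdf_oracle <- function(q, k, df) {
  chi_dens <- function(s) {
    exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(s) -
          df * s^2 / 2 + log(2))
  }
  inner <- function(s) {
    stats::integrate(function(z) {
      k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }, -8, 8 + q * s, rel.tol = 1e-9)$value
  }
  stats::integrate(Vectorize(function(s) chi_dens(s) * inner(s)),
                   0, 10, rel.tol = 1e-7)$value
}

# random correlation matrix via random orthogonal mixing
random_correlation <- function(k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  S <- crossprod(A) + diag(k) * 0.5
  stats::cov2cor(S)
}
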