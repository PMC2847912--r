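#' Validate (and if needed repair) a correlation matrix
#'
#' Checks symmetry and unit diagonal, then the spectrum: a smallest
#' eigenvalue below `-1e-8` is an error; one in `(-1e-8, 0)` — which can
#' happen for correlations assembled from sandwich covariances — is
#' repaired by clipping negative eigenvalues at zero and renormalizing the
#' diagonal back to 1.
#'
#' @param mat A square numeric matrix.
#' @return An object of class `correlation_matrix` with elements `matrix`
#'   and `repaired` (logical).
#' @export
as_correlation <- function(mat) {
  if (inherits(mat, "correlation_matrix")) return(mat)
  mat <- as.matrix(mat)
  k <- nrow(mat)
  stopifnot(k == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-8) stop("correlation matrix not symmetric")
  if (max(abs(diag(mat) - 1)) > 1e-8) stop("correlation matrix diagonal != 1")
  mat <- (mat + t(mat)) / 2
  repaired <- FALSE
  if (k > 1L) {
    ev <- eigen(mat, symmetric = TRUE)
    lmin <- min(ev$values)
    if (lmin < -1e-8) stop("correlation matrix is not positive semi-definite")
    if (lmin < 0) {
      vals <- pmax(ev$values, 0)
      mat <- ev$vectors %*% (vals * t(ev$vectors))
      d <- sqrt(diag(mat))
      mat <- mat / tcrossprod(d)
      diag(mat) <- 1
      repaired <- TRUE
    }
  }
  structure(list(matrix = mat, repaired = repaired),
            class = "correlation_matrix")
}

# run expr with a private RNG stream; caller's .Random.seed is untouched
with_private_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# uniform random shifts for randomized QMC: n_shifts rows, dim columns
qmc_shifts <- function(seed, dim, n_shifts = 12L) {
  with_private_seed(seed, matrix(stats::runif(n_shifts * dim),
                                 nrow = n_shifts, ncol = dim))
}

# square roots of the first `dim` primes, generators of the Richtmyer
# (Kronecker) low-discrepancy sequence
kronecker_generators <- function(dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47,
              53, 59, 61, 67, 71, 73, 79, 83, 89, 97, 101, 103, 107,
              109, 113, 127, 131, 137, 139, 149, 151, 157, 163, 167, 173)
  if (dim > length(primes)) stop("dimension too large for QMC generator table")
  sqrt(primes[seq_len(dim)])
}

# Cholesky factor with greedy variable reordering (smallest conditional
# probability first), for the rectangle [-t, t]^k. The permutation does not
# change the equicoordinate probability; it reduces QMC variance.
genz_chol <- function(R, t) {
  k <- nrow(R)
  C <- R
  L <- matrix(0, k, k)
  y <- numeric(k)
  perm <- seq_len(k)
  for (i in seq_len(k)) {
    im1 <- seq_len(i - 1L)
    best <- i; bestp <- Inf
    for (j in i:k) {
      s2 <- C[j, j] - sum(L[j, im1]^2)
      s <- sqrt(max(s2, 0))
      mu <- sum(L[j, im1] * y[im1])
      pj <- if (s > 0) {
        stats::pnorm((t - mu) / s) - stats::pnorm((-t - mu) / s)
      } else 1
      if (pj < bestp) { bestp <- pj; best <- j }
    }
    if (best != i) {
      C[c(i, best), ] <- C[c(best, i), ]
      C[, c(i, best)] <- C[, c(best, i)]
      L[c(i, best), ] <- L[c(best, i), ]
      perm[c(i, best)] <- perm[c(best, i)]
    }
    s2 <- C[i, i] - sum(L[i, im1]^2)
    L[i, i] <- sqrt(max(s2, 0))
    if (i < k) {
      for (j in (i + 1L):k) {
        L[j, i] <- if (L[i, i] > 0) {
          (C[j, i] - sum(L[i, im1] * L[j, im1])) / L[i, i]
        } else 0
      }
    }
    mu <- sum(L[i, im1] * y[im1])
    if (L[i, i] > 0) {
      al <- (-t - mu) / L[i, i]
      be <- (t - mu) / L[i, i]
      pab <- stats::pnorm(be) - stats::pnorm(al)
      y[i] <- if (pab > 1e-12) {
        (stats::dnorm(al) - stats::dnorm(be)) / pab
      } else (al + be) / 2
    }
  }
  list(L = L, perm = perm)
}

# QMC point set for k-dimensional max-|T| integration: per random shift, a
# matrix W of k-1 conditioning uniforms and (finite df only) the chi scale
# factors sc = sqrt(chi2_df / df) mapped from one extra coordinate. Points
# j = lo..hi of the Kronecker sequence with a baker's (tent) transform, so
# the set can be extended incrementally. Caching sc here is what lets a
# quantile search or a family of p-values reuse one lattice cheaply.
qmc_pointset <- function(df, k, shifts, lo, hi) {
  dim_u <- (k - 1L) + is.finite(df)
  gen <- kronecker_generators(dim_u)
  j <- lo:hi
  eps <- 1e-15
  lapply(seq_len(nrow(shifts)), function(s) {
    U <- (outer(j, gen) + matrix(shifts[s, ], length(j), dim_u,
                                 byrow = TRUE)) %% 1
    U <- abs(2 * U - 1)
    sc <- if (is.finite(df)) {
      sqrt(stats::qchisq(pmin(pmax(U[, dim_u], eps), 1 - eps), df) / df)
    } else NULL
    list(W = U[, seq_len(k - 1L), drop = FALSE], sc = sc)
  })
}

join_pointsets <- function(a, b) {
  Map(function(x, y) list(W = rbind(x$W, y$W), sc = c(x$sc, y$sc)), a, b)
}

# per-shift estimates of P(max_j |T_j| <= t) on a cached point set
prob_on_pointset <- function(t, L, pts) {
  k <- nrow(L)
  eps <- 1e-15
  diagL <- pmax(diag(L), 1e-100)
  vapply(pts, function(p) {
    npts <- nrow(p$W)
    tt <- if (!is.null(p$sc)) t * p$sc else rep.int(t, npts)
    e <- stats::pnorm(tt / diagL[1L])
    d <- stats::pnorm(-tt / diagL[1L])
    f <- e - d
    if (k > 1L) {
      Y <- matrix(0, npts, k - 1L)
      for (i in 2:k) {
        z <- pmin(pmax(d + p$W[, i - 1L] * (e - d), eps), 1 - eps)
        Y[, i - 1L] <- stats::qnorm(z)
        mu <- Y[, seq_len(i - 1L), drop = FALSE] %*% L[i, seq_len(i - 1L)]
        e <- stats::pnorm((tt - mu) / diagL[i])
        d <- stats::pnorm((-tt - mu) / diagL[i])
        f <- f * (e - d)
      }
    }
    sum(f) / npts
  }, numeric(1))
}

# build a point set adaptively: double until the 3-sigma error of the
# per-shift means at threshold t meets `accuracy` or the cap is reached
adaptive_pointset <- function(t, L, df, shifts, accuracy, max_points,
                              n0 = 512L) {
  k <- nrow(L)
  n <- n0
  pts <- qmc_pointset(df, k, shifts, 1L, n)
  est <- prob_on_pointset(t, L, pts)
  n_shifts <- length(pts)
  repeat {
    err <- 3 * stats::sd(est) / sqrt(n_shifts)
    if (err <= accuracy || n >= max_points) break
    pts <- join_pointsets(pts, qmc_pointset(df, k, shifts, n + 1L, 2L * n))
    est <- prob_on_pointset(t, L, pts)
    n <- 2L * n
  }
  list(pts = pts, est = est, n = n,
       err = 3 * stats::sd(est) / sqrt(n_shifts))
}

#' Equicoordinate probability for the maximum absolute component
#'
#' Estimates `P(max_j |T_j| <= t)` for a central multivariate t
#' (`df < Inf`) or multivariate normal (`df = Inf`) vector with the given
#' correlation matrix, by randomized quasi-Monte Carlo over the separated
#' (Genz) transform of the rectangle probability: Cholesky with greedy
#' variable reordering, a Kronecker lattice with `n_shifts` random shifts,
#' and point doubling until the estimated error meets `accuracy`. The
#' multivariate t is the standard one: all components share a single
#' chi-square scale, so even under an identity correlation they are
#' dependent unless `df = Inf`.
#'
#' @param t Non-negative threshold.
#' @param corr Correlation matrix (or `correlation_matrix` object).
#' @param df Degrees of freedom; `Inf` for the multivariate normal.
#' @param seed Integer seed for the random shifts.
#' @param accuracy Target Monte-Carlo error bound (default `1e-4`).
#' @param n_shifts Number of independent lattice randomizations.
#' @param max_points Cap on lattice points per shift.
#' @return A list of class `mv_prob`: `value`, `est_error` (about a 3-sigma
#'   bound), `n_points` (total integrand evaluations), `seed`.
#' @examples
#' equicoordinate_probability(1.96, diag(3), df = Inf, seed = 1)
#' @export
equicoordinate_probability <- function(t, corr, df = Inf, seed = 1L,
                                       accuracy = 1e-4, n_shifts = 12L,
                                       max_points = 2^15) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold t must be a single non-negative number")
  }
  stopifnot(length(df) == 1L, df > 0)
  corr <- as_correlation(corr)
  k <- nrow(corr$matrix)
  if (k == 1L) {
    v <- univariate_prob(t, df)
    return(structure(list(value = v, est_error = 0, n_points = 0L,
                          seed = seed), class = "mv_prob"))
  }
  ch <- genz_chol(corr$matrix, t)
  dim_u <- (k - 1L) + is.finite(df)
  shifts <- qmc_shifts(seed, dim_u, n_shifts)
  ad <- adaptive_pointset(t, ch$L, df, shifts, accuracy, max_points)
  structure(list(value = min(max(mean(ad$est), 0), 1),
                 est_error = ad$err,
                 n_points = ad$n * n_shifts, seed = seed),
            class = "mv_prob")
}

univariate_prob <- function(t, df) {
  if (is.finite(df)) {
    stats::pt(t, df) - stats::pt(-t, df)
  } else {
    stats::pnorm(t) - stats::pnorm(-t)
  }
}

#' @export
print.mv_prob <- function(x, ...) {
  cat(sprintf("P = %.6f (est. error %.2g, %d QMC points, seed %s)\n",
              x$value, x$est_error, x$n_points, format(x$seed)))
  invisible(x)
}

sidak_start <- function(alpha, k, df) {
  p_each <- (1 - alpha)^(1 / k)
  if (is.finite(df)) stats::qt((1 + p_each) / 2, df) else
    stats::qnorm((1 + p_each) / 2)
}

# root search for P(q) = 1 - alpha on a fixed point set (common random
# numbers across iterations keep the objective monotone in q)
quantile_on_pointset <- function(alpha, L, pts, q0) {
  f <- function(q) mean(prob_on_pointset(q, L, pts)) - (1 - alpha)
  lo <- max(q0 - 1.5, 0); hi <- q0 + 1.5
  flo <- if (lo == 0) -(1 - alpha) else f(lo)
  fhi <- f(hi)
  while (fhi < 0 && hi < 20) { hi <- min(hi + 2, 20); fhi <- f(hi) }
  while (flo > 0 && lo > 0) { lo <- max(lo - 2, 0)
                              flo <- if (lo == 0) -(1 - alpha) else f(lo) }
  if (fhi < 0) {
    stop("pathological correlation: quantile not bracketed in [0, 20]")
  }
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-4)$root
}

#' Equicoordinate quantile of the maximum absolute component
#'
#' Finds `q` with `P(max_j |T_j| <= q) = 1 - alpha`, the critical value of
#' the max-t test and the half-width multiplier of simultaneous confidence
#' intervals. The root search re-evaluates the probability on one cached
#' lattice (common random numbers), so the objective is monotone in `q` and
#' the root is well-defined at QMC precision.
#'
#' @param alpha Family error level in (0, 1).
#' @inheritParams equicoordinate_probability
#' @return The quantile (numeric scalar) with attributes `n_points` and
#'   `est_error` from the pilot probability evaluation.
#' @examples
#' equicoordinate_quantile(0.05, diag(2), df = Inf, seed = 1)
#' @export
equicoordinate_quantile <- function(alpha, corr, df = Inf, seed = 1L,
                                    accuracy = 1e-4, n_shifts = 12L,
                                    max_points = 2^15) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  corr <- as_correlation(corr)
  k <- nrow(corr$matrix)
  if (k == 1L) {
    q <- if (is.finite(df)) {
      stats::qt(1 - alpha / 2, df)
    } else stats::qnorm(1 - alpha / 2)
    return(structure(q, n_points = 0L, est_error = 0))
  }
  q0 <- sidak_start(alpha, k, df)
  ch <- genz_chol(corr$matrix, q0)
  dim_u <- (k - 1L) + is.finite(df)
  shifts <- qmc_shifts(seed, dim_u, n_shifts)
  ad <- adaptive_pointset(q0, ch$L, df, shifts, accuracy, max_points)
  q <- quantile_on_pointset(alpha, ch$L, ad$pts, q0)
  structure(q, n_points = ad$n * n_shifts, est_error = ad$err)
}
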