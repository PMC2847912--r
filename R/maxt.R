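resolve_df <- function(df, fit) {
  if (is.numeric(df)) {
    stopifnot(length(df) == 1L, df > 0)
    return(df)
  }
  switch(match.arg(df, c("residual", "normal")),
         residual = fit$df_residual,
         normal = Inf)
}

# correlation of the standardized contrast statistics: D^{-1/2} K S K' D^{-1/2}
contrast_correlation <- function(K, Sigma) {
  V <- K %*% Sigma %*% t(K)
  d <- diag(V)
  if (any(d <= 0)) stop("degenerate contrast variance (zero standard error)")
  R <- V / tcrossprod(sqrt(d))
  diag(R) <- 1
  as_correlation(R)
}

# shared QMC machinery for a family of thresholds plus the quantile, all on
# one lattice + shift set so p-values and intervals are mutually coherent
maxt_engine <- function(tstats, corr, df, alpha, seed, accuracy = 1e-4,
                        n_shifts = 12L, max_points = 2^15) {
  k <- nrow(corr$matrix)
  if (k == 1L) {
    p <- 1 - univariate_prob(abs(tstats), df)
    q <- if (is.finite(df)) stats::qt(1 - alpha / 2, df) else
      stats::qnorm(1 - alpha / 2)
    return(list(adj_p = p, quantile = q, n_points = 0L, est_error = 0))
  }
  q0 <- sidak_start(alpha, k, df)
  ch <- genz_chol(corr$matrix, q0)
  dim_u <- (k - 1L) + is.finite(df)
  shifts <- qmc_shifts(seed, dim_u, n_shifts)
  ad <- adaptive_pointset(q0, ch$L, df, shifts, accuracy, max_points)

  prob <- function(t) mean(prob_on_pointset(t, ch$L, ad$pts))
  adj_p <- vapply(abs(tstats), function(t) min(max(1 - prob(t), 0), 1),
                  numeric(1))
  q <- quantile_on_pointset(alpha, ch$L, ad$pts, q0)
  list(adj_p = adj_p, quantile = q, n_points = ad$n * n_shifts,
       est_error = ad$err)
}

# per-pair rejection decisions without computing every adjusted p-value:
# statistics are visited in decreasing order and evaluation stops at the
# first non-rejection (P is nondecreasing in t on a common lattice)
maxt_decisions <- function(tstats, corr, df, alpha, seed, accuracy = 2e-3,
                           n_shifts = 8L, max_points = 4096L) {
  k <- length(tstats)
  at <- abs(tstats)
  if (nrow(corr$matrix) == 1L) {
    return(1 - univariate_prob(at, df) < alpha)
  }
  ch <- genz_chol(corr$matrix, sidak_start(alpha, nrow(corr$matrix), df))
  dim_u <- (nrow(corr$matrix) - 1L) + is.finite(df)
  shifts <- qmc_shifts(seed, dim_u, n_shifts)
  ord <- order(at, decreasing = TRUE)
  reject <- logical(k)
  pts <- NULL
  for (j in ord) {
    if (is.null(pts)) {
      ad <- adaptive_pointset(at[j], ch$L, df, shifts, accuracy, max_points)
      pts <- ad$pts
      p <- mean(ad$est)
    } else {
      p <- mean(prob_on_pointset(at[j], ch$L, pts))
    }
    if (p > 1 - alpha) reject[j] <- TRUE else break
  }
  reject
}

#' Max-t simultaneous test of a set of linear contrasts
#'
#' Standardizes each contrast by its estimated standard error and refers
#' the statistics jointly to the multivariate t (or normal) distribution of
#' the maximum absolute component, yielding single-step adjusted p-values
#' that control the familywise error rate.
#'
#' @param fit A [fit_one_way()] object.
#' @param contrasts A `contrast_set` (or specification accepted by
#'   [resolve_contrasts()]).
#' @param covariance A `covariance_estimate` for the same fit; defaults to
#'   [hc_covariance()] with HC3.
#' @param df `"residual"` (default, multivariate t with `N - p` degrees of
#'   freedom), `"normal"` (asymptotic multivariate normal), or a number.
#' @param seed Seed for the QMC randomization; one seed governs every
#'   probability and quantile evaluation of the analysis.
#' @param accuracy QMC error target for adjusted p-values (default `1e-3`,
#'   decision-level precision; tighten for reporting more digits).
#' @param alpha Family error level (used for the companion quantile).
#' @return A list of class `maxt_result`: tibble `results` (contrast,
#'   estimate, std_error, statistic, adj_p), `correlation`, `df`,
#'   `estimator_tag`, `quantile`, `alpha`, `seed`, `accuracy`.
#' @export
simultaneous_test <- function(fit, contrasts, covariance = hc_covariance(fit),
                              df = "residual", alpha = 0.05, seed = 1L,
                              accuracy = 1e-3) {
  stopifnot(inherits(fit, "one_way_fit"),
            inherits(covariance, "covariance_estimate"))
  cs <- resolve_contrasts(contrasts, fit$group_labels)
  K <- cs$matrix
  Sigma <- covariance$matrix
  est <- as.numeric(K %*% fit$coefficients) - cs$rhs
  se <- unname(sqrt(diag(K %*% Sigma %*% t(K))))
  if (any(se <= 0)) stop("degenerate contrast variance (zero standard error)")
  tstat <- est / se
  corr <- contrast_correlation(K, Sigma)
  nu <- resolve_df(df, fit)
  eng <- maxt_engine(tstat, corr, nu, alpha, seed, accuracy)
  structure(
    list(
      results = tibble::tibble(
        contrast = cs$row_labels,
        estimate = est,
        std_error = se,
        statistic = tstat,
        adj_p = eng$adj_p
      ),
      contrasts = cs,
      correlation = corr,
      df = nu,
      estimator_tag = covariance$estimator_tag,
      quantile = eng$quantile,
      alpha = alpha,
      seed = seed,
      accuracy = accuracy,
      n_points = eng$n_points
    ),
    class = "maxt_result"
  )
}

#' Simultaneous confidence intervals for a set of linear contrasts
#'
#' Intervals `estimate +/- q * std_error` where `q` is the equicoordinate
#' quantile of the joint reference distribution at family level
#' `1 - alpha`, so all intervals cover their targets simultaneously with
#' that probability.
#'
#' @inheritParams simultaneous_test
#' @return A list of class `maxt_ci`: tibble `results` (contrast, estimate,
#'   conf_low, conf_high), `quantile`, `alpha`, `df`, `estimator_tag`.
#' @export
simultaneous_ci <- function(fit, contrasts, covariance = hc_covariance(fit),
                            alpha = 0.05, df = "residual", seed = 1L,
                            accuracy = 1e-3) {
  st <- simultaneous_test(fit, contrasts, covariance, df = df, alpha = alpha,
                          seed = seed, accuracy = accuracy)
  structure(
    list(
      results = dplyr::mutate(
        st$results[, c("contrast", "estimate", "std_error")],
        conf_low = .data$estimate - st$quantile * .data$std_error,
        conf_high = .data$estimate + st$quantile * .data$std_error
      ),
      quantile = st$quantile,
      alpha = alpha,
      df = st$df,
      estimator_tag = st$estimator_tag,
      seed = seed
    ),
    class = "maxt_ci"
  )
}

#' Max-t multiple comparisons of group means
#'
#' One-stop pipeline: fits the one-way cell-means model, builds the
#' requested contrasts, estimates the coefficient covariance (HC3 sandwich
#' by default, robust to unequal group variances), and runs the max-t
#' simultaneous test with matching simultaneous confidence intervals.
#'
#' @param data Data frame with one row per observation.
#' @param group,value Grouping and response columns (tidy-eval; defaults
#'   `group`, `value`).
#' @param contrasts `"tukey"` (all pairwise, default), `"dunnett"`,
#'   `"dunnett:<ref>"`, a character vector of symbolic expressions such as
#'   `"B - A = 0"`, or a `contrast_set`.
#' @param vcov Covariance estimator: `"HC3"` (default), `"HC2"`, `"HC1"`,
#'   `"HC0"` or `"OLS"`.
#' @param alpha Family error level for intervals and the significance
#'   count.
#' @param df Reference distribution: `"residual"` (multivariate t,
#'   `N - p` df), `"normal"`, or a number.
#' @param seed Seed for the QMC randomization.
#' @param accuracy QMC error target.
#' @param na_action Passed to [fit_one_way()].
#' @return An object of class `maxt_test` whose `tidy()` method returns
#'   one row per contrast with estimate, std_error, statistic, adj_p,
#'   conf_low and conf_high, and whose `glance()` method returns the
#'   family-level summary (quantile, df, number significant, ...).
#' @examples
#' d <- simulate_one_way(sizes = c(8, 12, 16), means = c(0, 0, 1),
#'                       sds = c(1, 2, 3), seed = 7)
#' fit <- max_t_test(d, contrasts = "tukey", vcov = "HC3", seed = 1)
#' tidy(fit)
#' glance(fit)
#' @export
max_t_test <- function(data, group = group, value = value,
                       contrasts = "tukey",
                       vcov = c("HC3", "HC2", "HC1", "HC0", "OLS"),
                       alpha = 0.05, df = "residual", seed = 1L,
                       accuracy = 1e-3, na_action = "drop") {
  vcov <- match.arg(toupper(vcov[1L]), c("HC3", "HC2", "HC1", "HC0", "OLS"))
  fit <- fit_one_way(data, {{ group }}, {{ value }}, na_action = na_action)
  covariance <- if (vcov == "OLS") ols_covariance(fit) else
    hc_covariance(fit, type = vcov)
  st <- simultaneous_test(fit, contrasts, covariance, df = df, alpha = alpha,
                          seed = seed, accuracy = accuracy)
  res <- dplyr::mutate(
    st$results,
    conf_low = .data$estimate - st$quantile * .data$std_error,
    conf_high = .data$estimate + st$quantile * .data$std_error
  )
  structure(
    list(
      results = res,
      fit = fit,
      contrasts = st$contrasts,
      correlation = st$correlation,
      df = st$df,
      estimator_tag = st$estimator_tag,
      quantile = st$quantile,
      alpha = alpha,
      seed = seed,
      accuracy = accuracy,
      n_points = st$n_points,
      n_significant = sum(st$results$adj_p < alpha)
    ),
    class = "maxt_test"
  )
}

#' @method tidy maxt_test
#' @export
tidy.maxt_test <- function(x, ...) x$results

#' @method tidy maxt_result
#' @export
tidy.maxt_result <- function(x, ...) x$results

#' @method tidy maxt_ci
#' @export
tidy.maxt_ci <- function(x, ...) x$results

#' @method glance maxt_test
#' @export
glance.maxt_test <- function(x, ...) {
  tibble::tibble(
    n_obs = x$fit$n_obs,
    n_groups = x$fit$n_groups,
    n_contrasts = nrow(x$results),
    df = x$df,
    estimator = x$estimator_tag,
    alpha = x$alpha,
    quantile = x$quantile,
    n_significant = x$n_significant,
    seed = x$seed
  )
}

signif_marks <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", ".", " "))
}

#' Plain-text report of a max-t analysis
#'
#' Formats the per-contrast table (estimate, standard error, t statistic,
#' adjusted p-value with significance marks, simultaneous confidence
#' bounds) plus the family-level summary, in the style of standard
#' simultaneous-inference output. Adjusted p-values below 0.001 are shown
#' as `<0.001`; the stored values stay numeric.
#'
#' @param x A `maxt_test` object.
#' @param digits Number of decimals for estimates and bounds.
#' @return The report as a character vector (invisibly); printed to the
#'   console as a side effect.
#' @export
maxt_report <- function(x, digits = 6) {
  stopifnot(inherits(x, "maxt_test"))
  r <- x$results
  pshow <- ifelse(r$adj_p < 1e-3, "<0.001", sprintf("%.5f", r$adj_p))
  tab <- data.frame(
    Contrast = paste(r$contrast, "== 0"),
    Estimate = sprintf(paste0("%.", digits, "f"), r$estimate),
    `Std.Error` = sprintf(paste0("%.", digits, "f"), r$std_error),
    `t.value` = sprintf("%.3f", r$statistic),
    `adj.p` = pshow,
    ` ` = as.character(signif_marks(r$adj_p)),
    lwr = sprintf(paste0("%.", digits, "f"), r$conf_low),
    upr = sprintf(paste0("%.", digits, "f"), r$conf_high),
    check.names = FALSE
  )
  lines <- c(
    "Simultaneous max-t tests for linear contrasts of group means",
    sprintf("Covariance estimator: %s; df = %s; seed = %s",
            x$estimator_tag, format(x$df), format(x$seed)),
    sprintf("%d%% family-wise confidence level; estimated quantile = %.4f",
            round(100 * (1 - x$alpha)), x$quantile),
    "",
    utils::capture.output(print(tab, row.names = FALSE)),
    "",
    "Signif. codes: 0 '***' 0.001 '**' 0.01 '*' 0.05 '.' 0.1 ' ' 1",
    sprintf("%d of %d comparisons significant at alpha = %s",
            x$n_significant, nrow(r), format(x$alpha))
  )
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.maxt_test <- function(x, ...) {
  maxt_report(x)
  invisible(x)
}

#' Confidence-interval plot for a max-t analysis
#'
#' Horizontal simultaneous confidence intervals, one row per contrast, with
#' a dashed reference line at zero.
#'
#' @param object A `maxt_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @method autoplot maxt_test
#' @export
autoplot.maxt_test <- function(object, ...) {
  r <- dplyr::mutate(object$results,
                     contrast = factor(.data$contrast,
                                       levels = rev(.data$contrast)))
  ggplot2::ggplot(r, ggplot2::aes(y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf_low,
                                         xmax = .data$conf_high),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate)) +
    ggplot2::labs(
      x = "Difference of group means",
      y = NULL,
      title = sprintf("%d%% simultaneous confidence intervals (%s)",
                      round(100 * (1 - object$alpha)), object$estimator_tag)
    ) +
    ggplot2::theme_minimal()
}
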