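#' Tukey-Kramer all-pairwise comparisons
#'
#' The classical procedure assuming equal variances in all groups: each
#' pairwise statistic `q_ij = |m_i - m_j| / sqrt(s2_pooled (1/n_i + 1/n_j) / 2)`
#' is referred to the studentized range distribution with `p` groups and
#' `N - p` degrees of freedom (the Kramer adjustment handles unequal
#' `n_i`). Included as the comparison standard for the max-t procedure; it
#' is not robust to heteroscedasticity.
#'
#' @inheritParams max_t_test
#' @return A list of class `tk_test`: tibble `results` (contrast, estimate,
#'   std_error, statistic on the studentized-range scale, adj_p, conf_low,
#'   conf_high), `crit` (critical value on the q scale), `df`, `alpha`.
#' @examples
#' d <- simulate_one_way(sizes = c(10, 10, 10), means = c(0, 0, 2),
#'                       sds = c(1, 1, 1), seed = 2)
#' tidy(tukey_kramer_test(d))
#' @export
tukey_kramer_test <- function(data, group = group, value = value,
                              alpha = 0.05, na_action = "drop") {
  fit <- fit_one_way(data, {{ group }}, {{ value }}, na_action = na_action)
  cs <- contrast_tukey(fit$group_labels)
  p <- fit$n_groups
  s2p <- fit$sigma2_hat
  if (s2p <= 0) stop("pooled variance is zero")
  est <- as.numeric(cs$matrix %*% fit$coefficients)
  nn <- fit$group_sizes
  # per-row 1/n_i + 1/n_j from the +-1 coding
  inv <- as.numeric(abs(cs$matrix) %*% (1 / nn))
  se_q <- sqrt(s2p * inv / 2)
  qstat <- abs(est) / se_q
  adj_p <- stats::ptukey(qstat, nmeans = p, df = fit$df_residual,
                         lower.tail = FALSE)
  crit <- stats::qtukey(1 - alpha, nmeans = p, df = fit$df_residual)
  structure(
    list(
      results = tibble::tibble(
        contrast = cs$row_labels,
        estimate = est,
        std_error = se_q,
        statistic = qstat,
        adj_p = adj_p,
        conf_low = est - crit * se_q,
        conf_high = est + crit * se_q
      ),
      crit = crit,
      df = fit$df_residual,
      alpha = alpha,
      n_significant = sum(adj_p < alpha)
    ),
    class = "tk_test"
  )
}

#' @method tidy tk_test
#' @export
tidy.tk_test <- function(x, ...) x$results

#' @method glance tk_test
#' @export
glance.tk_test <- function(x, ...) {
  tibble::tibble(n_contrasts = nrow(x$results), df = x$df,
                 crit = x$crit, alpha = x$alpha,
                 n_significant = x$n_significant)
}

#' @export
print.tk_test <- function(x, ...) {
  cat("Tukey-Kramer all-pairwise comparisons (pooled variance, df ",
      x$df, ")\n", sep = "")
  print(x$results)
  cat(x$n_significant, "of", nrow(x$results),
      "comparisons significant at alpha =", format(x$alpha), "\n")
  invisible(x)
}
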