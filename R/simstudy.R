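#' Simulate one unbalanced heteroscedastic one-way dataset
#'
#' Draws `sizes[i]` observations for group `i` with mean `means[i]` and
#' standard deviation `sds[i]`. Errors are either normal or right-skewed,
#' the latter a standardized shifted exponential `sd * (Exp(1) - 1)` with
#' exact mean 0 and standard deviation `sd`.
#'
#' @param sizes Integer vector of group sizes.
#' @param means Numeric vector of group means (recycled scalar allowed).
#' @param sds Positive numeric vector of group standard deviations
#'   (recycled scalar allowed).
#' @param error_law `"normal"` or `"right_skewed"`.
#' @param seed Integer seed; same seed, same dataset.
#' @param labels Group labels; default `G1, G2, ...`.
#' @return A tibble with columns `group` (character) and `value`.
#' @examples
#' simulate_one_way(c(4, 8), means = c(0, 1), sds = c(1, 2), seed = 1)
#' @export
simulate_one_way <- function(sizes, means = 0, sds = 1,
                             error_law = c("normal", "right_skewed"),
                             seed = NULL,
                             labels = paste0("G", seq_along(sizes))) {
  error_law <- match.arg(error_law)
  k <- length(sizes)
  stopifnot(k >= 1L, all(sizes >= 1L), length(labels) == k)
  means <- rep_len(means, k)
  sds <- rep_len(sds, k)
  stopifnot(all(sds > 0))
  gen <- function() {
    g <- rep(labels, times = sizes)
    s <- rep(sds, times = sizes)
    m <- rep(means, times = sizes)
    e <- switch(error_law,
      normal = stats::rnorm(length(g), mean = 0, sd = 1),
      right_skewed = stats::rexp(length(g)) - 1
    )
    tibble::tibble(group = g, value = m + s * e)
  }
  if (is.null(seed)) gen() else with_private_seed(seed, gen())
}

#' Describe a simulation scenario
#'
#' A full generative description of one setting of the familywise error
#' rate / power study: group sizes, true effects, group-specific standard
#' deviations, error law, nominal level, replicate count and the grid of
#' effect offsets applied to group 1.
#'
#' @param group_sizes Integer vector `n_i`.
#' @param effects True group means (default all 0, the complete null).
#' @param sds Group standard deviations.
#' @param error_law `"normal"` or `"right_skewed"`.
#' @param alpha Nominal familywise level.
#' @param n_datasets Number of simulated datasets per setting.
#' @param delta_grid Offsets added to the group-1 effect; default 41
#'   equally spaced values on `[0, 2 max(sds)]`.
#' @return A list of class `scenario`.
#' @export
scenario <- function(group_sizes, effects = 0, sds = 1,
                     error_law = c("normal", "right_skewed"),
                     alpha = 0.05, n_datasets = 1000,
                     delta_grid = seq(0, 2 * max(sds), length.out = 41)) {
  error_law <- match.arg(error_law)
  k <- length(group_sizes)
  stopifnot(k >= 2L, all(group_sizes >= 2L))
  effects <- rep_len(effects, k)
  sds <- rep_len(sds, k)
  stopifnot(all(sds > 0), n_datasets >= 1L, alpha > 0, alpha <= 1,
            all(delta_grid >= 0))
  structure(
    list(group_sizes = as.integer(group_sizes), effects = effects,
         sds = sds, error_law = error_law, alpha = alpha,
         n_datasets = as.integer(n_datasets), delta_grid = delta_grid,
         labels = paste0("G", seq_len(k))),
    class = "scenario"
  )
}

#' Preset heteroscedasticity patterns A-E
#'
#' Four-group unbalanced scenarios following the standard positive/negative
#' pairing patterns: allocation `N * (0.1, 0.2, 0.3, 0.4)`;
#' standard deviations all 1 under homoscedasticity (A), `(0.5, 1, 1.5, 2)`
#' aligned with the sizes so the smaller groups have the smaller variances
#' (B, D), and reversed so the smaller groups have the larger variances
#' (C, E); normal errors for A-C, right-skewed for D and E. These constants
#' are package defaults, overridable through [scenario()].
#'
#' @param model One of `"A"` to `"E"`.
#' @param N Total sample size (default 80); sizes are `N * (0.1, 0.2, 0.3, 0.4)`.
#' @inheritParams scenario
#' @return A `scenario`.
#' @examples
#' model_scenario("C", N = 80, n_datasets = 100)
#' @export
model_scenario <- function(model = c("A", "B", "C", "D", "E"), N = 80,
                           alpha = 0.05, n_datasets = 1000,
                           delta_grid = NULL) {
  model <- match.arg(model)
  sizes <- round(N * c(0.1, 0.2, 0.3, 0.4))
  sds <- switch(model,
    A = c(1, 1, 1, 1),
    B = c(0.5, 1, 1.5, 2),
    C = c(2, 1.5, 1, 0.5),
    D = c(0.5, 1, 1.5, 2),
    E = c(2, 1.5, 1, 0.5)
  )
  law <- if (model %in% c("D", "E")) "right_skewed" else "normal"
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, 2 * max(sds), length.out = 41)
  }
  scenario(group_sizes = sizes, effects = 0, sds = sds, error_law = law,
           alpha = alpha, n_datasets = n_datasets, delta_grid = delta_grid)
}

#' Draw one dataset from a scenario
#'
#' @param scn A [scenario()].
#' @param delta Offset added to the group-1 effect.
#' @param seed Integer seed.
#' @return A tibble with columns `group`, `value`.
#' @export
generate_dataset <- function(scn, delta = 0, seed = NULL) {
  stopifnot(inherits(scn, "scenario"), delta >= 0)
  means <- scn$effects
  means[1L] <- means[1L] + delta
  simulate_one_way(scn$group_sizes, means = means, sds = scn$sds,
                   error_law = scn$error_law, seed = seed,
                   labels = scn$labels)
}

# substream seeds: one per (replicate, delta); deterministic given the
# master seed so any replicate is reproducible in isolation
substream_seeds <- function(seed, n_rep, n_delta) {
  with_private_seed(seed, matrix(sample.int(2147483646L, n_rep * n_delta),
                                 nrow = n_rep, ncol = n_delta))
}

# per-pair rejection decisions for one dataset under one method
method_decisions <- function(data, method, alpha, seed, accuracy, n_shifts,
                             max_points) {
  if (method == "tukey_kramer") {
    tk <- tukey_kramer_test(data, alpha = alpha)
    return(tk$results$adj_p < alpha)
  }
  fit <- fit_one_way(data)
  covariance <- if (method == "maxt_ols") ols_covariance(fit) else
    hc_covariance(fit, "HC3")
  cs <- contrast_tukey(fit$group_labels)
  K <- cs$matrix
  Sigma <- covariance$matrix
  est <- as.numeric(K %*% fit$coefficients)
  se <- sqrt(diag(K %*% Sigma %*% t(K)))
  tstat <- abs(est / se)
  if (alpha >= 1) return(tstat > 0)
  corr <- contrast_correlation(K, Sigma)
  maxt_decisions(tstat, corr, df = fit$df_residual, alpha = alpha,
                 seed = seed, accuracy = accuracy, n_shifts = n_shifts,
                 max_points = max_points)
}

#' Run the familywise error rate / power study
#'
#' For every replicate, delta and method, simulates a dataset and records
#' the per-pair rejection decisions of Tukey all-pairwise comparisons. All
#' methods see the same datasets at a given (replicate, delta), and the
#' same replicates serve both the error-rate and the power summaries.
#' Pairs not involving group 1 are true nulls for every delta; pairs
#' involving group 1 are true nulls only at `delta = 0`.
#'
#' @param scn A [scenario()].
#' @param methods Subset of `c("maxt_hc3", "maxt_ols", "tukey_kramer")`.
#' @param deltas Offsets to evaluate; defaults to `scn$delta_grid`.
#' @param seed Master seed; per-replicate substreams are derived from it.
#' @param accuracy QMC error target for the max-t quantiles
#'   (decision-level precision; default `2e-3`).
#' @return A tibble with one row per method x delta x metric: columns
#'   `method`, `delta`, `metric` (`"fwer"` or `"power"`), `pair` (`NA` for
#'   fwer rows), `estimate`, `mc_se`, `n_datasets`.
#' @examples
#' scn <- model_scenario("A", N = 40, n_datasets = 20)
#' run_study(scn, methods = "tukey_kramer", deltas = 0, seed = 1)
#' @export
run_study <- function(scn, methods = c("maxt_hc3", "tukey_kramer"),
                      deltas = NULL, seed = 1L, accuracy = 2e-3) {
  stopifnot(inherits(scn, "scenario"))
  methods <- match.arg(methods, c("maxt_hc3", "maxt_ols", "tukey_kramer"),
                       several.ok = TRUE)
  if (is.null(deltas)) deltas <- scn$delta_grid
  stopifnot(length(deltas) >= 1L)
  R <- scn$n_datasets
  seeds <- substream_seeds(seed, R, length(deltas))
  cs <- contrast_tukey(scn$labels)
  k <- nrow(cs$matrix)
  involves_g1 <- cs$matrix[, 1L] != 0

  out <- vector("list", length(deltas) * length(methods))
  slot <- 0L
  for (d in seq_along(deltas)) {
    delta <- deltas[d]
    # decisions[r, pair, method]
    dec <- array(NA, dim = c(R, k, length(methods)))
    for (r in seq_len(R)) {
      rs <- seeds[r, d]
      dat <- generate_dataset(scn, delta = delta, seed = rs)
      for (m in seq_along(methods)) {
        dec[r, , m] <- method_decisions(dat, methods[m], scn$alpha,
                                        seed = rs, accuracy = accuracy,
                                        n_shifts = 8L, max_points = 4096L)
      }
    }
    null_pairs <- if (delta == 0) rep(TRUE, k) else !involves_g1
    # group-1 pairs are tracked at every delta; at delta = 0 their
    # "power" is the per-pair type-I error rate
    false_pairs <- involves_g1
    for (m in seq_along(methods)) {
      dm <- matrix(dec[, , m], nrow = R, ncol = k)
      any_false_pos <- apply(dm[, null_pairs, drop = FALSE], 1L, any)
      fwer <- mean(any_false_pos)
      rows <- tibble::tibble(
        method = methods[m], delta = delta, metric = "fwer",
        pair = NA_character_, estimate = fwer,
        mc_se = sqrt(fwer * (1 - fwer) / R), n_datasets = R
      )
      if (any(false_pairs)) {
        pw <- colMeans(dm[, false_pairs, drop = FALSE])
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          method = methods[m], delta = delta, metric = "power",
          pair = cs$row_labels[false_pairs], estimate = pw,
          mc_se = sqrt(pw * (1 - pw) / R), n_datasets = R
        ))
      }
      slot <- slot + 1L
      out[[slot]] <- rows
    }
  }
  dplyr::bind_rows(out[seq_len(slot)])
}

#' Estimate the familywise error rate of a method under a scenario
#'
#' Proportion of replicates with at least one falsely rejected true
#' pairwise null. With `delta = 0` every pair is a true null; with
#' `delta > 0` only the pairs not involving group 1 count.
#'
#' @inheritParams run_study
#' @param method One of `"maxt_hc3"`, `"maxt_ols"`, `"tukey_kramer"`.
#' @param delta Offset of the group-1 effect (default 0, the complete
#'   null).
#' @return One-row tibble: `method`, `delta`, `fwer`, `mc_se`,
#'   `n_datasets`.
#' @export
estimate_fwer <- function(scn, method = "maxt_hc3", delta = 0, seed = 1L,
                          accuracy = 2e-3) {
  res <- run_study(scn, methods = method, deltas = delta, seed = seed,
                   accuracy = accuracy)
  res <- res[res$metric == "fwer", ]
  tibble::tibble(method = res$method, delta = res$delta,
                 fwer = res$estimate, mc_se = res$mc_se,
                 n_datasets = res$n_datasets)
}

#' Estimate per-comparison power along the delta grid
#'
#' For each delta and each false pair (group 1 versus the others), the
#' proportion of replicates in which that pair is rejected.
#'
#' @inheritParams estimate_fwer
#' @param deltas Offsets to evaluate; defaults to the scenario's grid.
#' @return Tibble with columns `method`, `delta`, `pair`, `power`,
#'   `mc_se`, `n_datasets`.
#' @export
estimate_power <- function(scn, method = "maxt_hc3", deltas = NULL,
                           seed = 1L, accuracy = 2e-3) {
  if (is.null(deltas)) deltas <- scn$delta_grid
  res <- run_study(scn, methods = method, deltas = deltas, seed = seed,
                   accuracy = accuracy)
  res <- res[res$metric == "power", ]
  tibble::tibble(method = res$method, delta = res$delta, pair = res$pair,
                 power = res$estimate, mc_se = res$mc_se,
                 n_datasets = res$n_datasets)
}

#' Power curves from a study result
#'
#' @param power_tbl Output of [estimate_power()] (possibly several methods
#'   bound together).
#' @return A ggplot object: power against delta, one line per method,
#'   facetted by pair.
#' @export
plot_power_curves <- function(power_tbl) {
  ggplot2::ggplot(power_tbl,
                  ggplot2::aes(x = .data$delta, y = .data$power,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "Distance of group-1 effect", y = "Estimated power") +
    ggplot2::theme_minimal()
}

#' Familywise error rate summary plot
#'
#' @param fwer_tbl Rows of [run_study()] output with `metric == "fwer"`
#'   (several methods/deltas).
#' @param alpha Nominal level drawn as a reference line.
#' @return A ggplot object (boxplot of FWER estimates per method).
#' @export
plot_fwer <- function(fwer_tbl, alpha = 0.05) {
  ggplot2::ggplot(fwer_tbl,
                  ggplot2::aes(x = .data$method, y = .data$estimate)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = alpha, colour = "red") +
    ggplot2::labs(x = NULL, y = "Estimated familywise error rate") +
    ggplot2::theme_minimal()
}
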