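#' Fit a one-way cell-means linear model by ordinary least squares
#'
#' Fits the one-way layout `y_ij = beta_i + e_ij` where `beta_i` is the mean
#' of group `i`. The cell-means coding (one indicator column per group, no
#' intercept) makes every pairwise contrast a simple +1/-1 pattern on the
#' coefficient vector, so no reference-level bookkeeping is needed
#' downstream. Group labels are ordered lexicographically at ingest and all
#' downstream contrast labelling derives from that order.
#'
#' @param data A data frame with one row per observation.
#' @param group,value Columns of `data` holding the group label and the
#'   numeric response (tidy-eval; defaults `group` and `value`).
#' @param na_action `"drop"` (default) removes rows with missing responses
#'   and records the count; `"error"` fails on any missing response.
#'
#' @return An object of class `one_way_fit`: a list with elements
#'   `coefficients` (named vector of group means), `group_labels`,
#'   `n_groups`, `group_sizes`, `residuals`, `leverage`, `fitted`,
#'   `group_index` (factor, one entry per retained observation),
#'   `df_residual` (`N - p`), `sigma2_hat` (pooled residual variance),
#'   `n_obs`, and `n_dropped`.
#'
#' @examples
#' d <- data.frame(group = c("A", "A", "A", "B", "B"),
#'                 value = c(1, 2, 3, 10, 20))
#' fit <- fit_one_way(d)
#' coef(fit)
#' @export
fit_one_way <- function(data, group = group, value = value,
                        na_action = c("drop", "error")) {
  na_action <- match.arg(na_action)
  stopifnot(is.data.frame(data))
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  y <- rlang::eval_tidy(rlang::enquo(value), data)
  if (length(g) != length(y)) {
    stop("group and value columns must have equal length")
  }
  g <- as.character(g)
  if (!is.numeric(y)) stop("response must be numeric")

  bad <- is.na(y) | is.na(g) | !is.finite(y)
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    if (na_action == "error") {
      stop(n_dropped, " missing/non-finite responses (na_action = \"error\")")
    }
    message("fit_one_way: dropped ", n_dropped,
            " observation(s) with missing or non-finite response")
    g <- g[!bad]
    y <- y[!bad]
  }

  labels <- sort(unique(g))
  if (length(labels) < 2L) stop("need >= 2 groups")
  idx <- factor(g, levels = labels)
  n_i <- as.integer(table(idx))
  if (any(n_i == 0L)) stop("degenerate group: empty after cleaning")

  means <- tapply(y, idx, mean)
  fitted <- as.numeric(means[idx])
  res <- y - fitted
  p <- length(labels)
  n <- length(y)
  df_res <- n - p
  if (df_res < 1L) stop("saturated model: no residual degrees of freedom")

  structure(
    list(
      coefficients = stats::setNames(as.numeric(means), labels),
      group_labels = labels,
      n_groups = p,
      group_sizes = stats::setNames(n_i, labels),
      residuals = res,
      leverage = 1 / n_i[as.integer(idx)],
      fitted = fitted,
      group_index = idx,
      df_residual = df_res,
      sigma2_hat = sum(res^2) / df_res,
      n_obs = n,
      n_dropped = n_dropped
    ),
    class = "one_way_fit"
  )
}

#' @export
coef.one_way_fit <- function(object, ...) object$coefficients

#' @export
print.one_way_fit <- function(x, ...) {
  cat("One-way cell-means fit:", x$n_groups, "groups,",
      x$n_obs, "observations, residual df", x$df_residual, "\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy one_way_fit
#' @export
tidy.one_way_fit <- function(x, ...) {
  tibble::tibble(
    group = x$group_labels,
    n = as.integer(x$group_sizes),
    estimate = unname(x$coefficients),
    std_error = sqrt(x$sigma2_hat / x$group_sizes)
  )
}

#' @method glance one_way_fit
#' @export
glance.one_way_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    n_groups = x$n_groups,
    df_residual = x$df_residual,
    sigma2_hat = x$sigma2_hat,
    n_dropped = x$n_dropped
  )
}

new_covariance <- function(matrix, tag, labels) {
  dimnames(matrix) <- list(labels, labels)
  structure(list(matrix = matrix, estimator_tag = tag),
            class = "covariance_estimate")
}

#' @export
print.covariance_estimate <- function(x, ...) {
  cat("Coefficient covariance estimate (", x$estimator_tag, ")\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' Ordinary least squares covariance of the group-mean estimates
#'
#' Returns `sigma2_hat * (X'X)^{-1}`, which for the cell-means one-way
#' design is `diag(sigma2_hat / n_i)`. Consistent only under
#' homoscedasticity; see [hc_covariance()] for the robust alternatives.
#'
#' @param fit A [fit_one_way()] object.
#' @return A `covariance_estimate` (p x p matrix plus estimator tag).
#' @export
ols_covariance <- function(fit) {
  stopifnot(inherits(fit, "one_way_fit"))
  if (fit$df_residual < 1L) stop("saturated model")
  new_covariance(diag(fit$sigma2_hat / fit$group_sizes,
                      nrow = fit$n_groups),
                 "OLS", fit$group_labels)
}

#' Heteroscedasticity-consistent (sandwich) covariance of the group means
#'
#' Computes `(X'X)^{-1} X' diag(w_i) X (X'X)^{-1}` with observation weights
#' `w_i = e_i^2` (HC0), `e_i^2 * N/(N-p)` (HC1), `e_i^2/(1-h_ii)` (HC2) or
#' `e_i^2/(1-h_ii)^2` (HC3, the default and the small-sample
#' recommendation). In the cell-means one-way design the leverage is
#' `h_ii = 1/n_i`, the sandwich collapses to a diagonal matrix, and HC3
#' gives `Var(beta_i) = sum_j e_ij^2 / (n_i - 1)^2`.
#'
#' @param fit A [fit_one_way()] object.
#' @param type One of `"HC3"` (default), `"HC2"`, `"HC1"`, `"HC0"`.
#' @return A `covariance_estimate`.
#' @export
hc_covariance <- function(fit, type = c("HC3", "HC2", "HC1", "HC0")) {
  stopifnot(inherits(fit, "one_way_fit"))
  type <- match.arg(type)
  h <- fit$leverage
  if (type %in% c("HC2", "HC3") && max(h) >= 1 - 1e-12) {
    stop("leverage one: HC2/HC3 undefined (singleton group present)")
  }
  e2 <- fit$residuals^2
  w <- switch(type,
    HC0 = e2,
    HC1 = e2 * fit$n_obs / fit$df_residual,
    HC2 = e2 / (1 - h),
    HC3 = e2 / (1 - h)^2
  )
  # diagonal sandwich: sum of weights within group i divided by n_i^2
  s <- tapply(w, fit$group_index, sum)
  v <- as.numeric(s) / fit$group_sizes^2
  new_covariance(diag(v, nrow = fit$n_groups), type, fit$group_labels)
}
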