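hetero_data <- function(seed = 5) {
  simulate_one_way(sizes = c(8, 15, 10, 20), means = c(0, 0.8, 0.2, 1),
                   sds = c(0.4, 1.5, 0.8, 2), seed = seed)
}

test_that("a single contrast reduces to the ordinary two-sided t test", {
  d <- simulate_one_way(sizes = c(9, 14), means = c(0, 1), sds = c(1, 1),
                        seed = 3)
  fit <- fit_one_way(d)
  res <- simultaneous_test(fit, "tukey", ols_covariance(fit), seed = 1)
  expect_equal(nrow(res$results), 1L)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  # the contrast is G2 - G1 while t.test reports G1 - G2
  expect_equal(res$results$statistic, -unname(tt$statistic),
               tolerance = 1e-10)
  expect_equal(res$results$adj_p, tt$p.value, tolerance = 1e-10)
  # interval equals the ordinary t interval
  ci <- simultaneous_ci(fit, "tukey", ols_covariance(fit), alpha = 0.05,
                        seed = 1)
  expect_equal(c(ci$results$conf_low, ci$results$conf_high),
               unname(-tt$conf.int[2:1]), tolerance = 1e-9)
})

test_that("orthogonal contrasts under normal reference match Sidak", {
  # disjoint pairs with OLS covariance give an identity correlation
  d <- simulate_one_way(sizes = rep(12, 4), means = c(0, 0.5, 0, 1.2),
                        sds = 1, seed = 8, labels = c("A", "B", "C", "D"))
  fit <- fit_one_way(d)
  V <- ols_covariance(fit)
  res <- simultaneous_test(fit, c("B - A = 0", "D - C = 0"), V,
                           df = "normal", seed = 2, accuracy = 1e-4)
  expect_equal(unname(res$correlation$matrix), diag(2), tolerance = 1e-12)
  praw <- 2 * pnorm(-abs(res$results$statistic))
  expect_equal(res$results$adj_p, 1 - (1 - praw)^2, tolerance = 5e-4)
})

test_that("published worked-example row is reproduced", {
  data(fattyacid, package = "multcomp", envir = environment())
  res <- suppressMessages(
    max_t_test(fattyacid, group = PE, value = FA, contrasts = "tukey",
               vcov = "HC3", seed = 1)
  )
  row <- res$results[res$results$contrast == "PE5 - PE4", ]
  expect_equal(round(row$estimate, 6), -0.071579)
  expect_equal(round(row$std_error, 6), 0.019764)
  expect_equal(round(row$statistic, 3), -3.622)
  expect_lt(abs(row$adj_p - 0.00600), 0.002)
})

test_that("t statistics and adjusted p-values are scale equivariant", {
  d <- hetero_data()
  r1 <- max_t_test(d, seed = 4)
  d2 <- dplyr::mutate(d, value = value * 7)
  r2 <- max_t_test(d2, seed = 4)
  expect_equal(r2$results$statistic, r1$results$statistic,
               tolerance = 1e-10)
  expect_equal(r2$results$adj_p, r1$results$adj_p, tolerance = 1e-8)
  expect_equal(r2$results$conf_low, 7 * r1$results$conf_low,
               tolerance = 1e-8)
  expect_equal(r2$quantile, r1$quantile, tolerance = 1e-8)
})

test_that("relabelling groups permutes rows but not pair-level p-values", {
  d <- hetero_data(seed = 12)
  r1 <- max_t_test(d, seed = 6)
  # reverse the lexicographic order via new labels
  map <- c(G1 = "Z4", G2 = "Z3", G3 = "Z2", G4 = "Z1")
  d2 <- dplyr::mutate(d, group = unname(map[group]))
  r2 <- max_t_test(d2, seed = 6)
  key1 <- vapply(strsplit(r1$results$contrast, " - "), function(x) {
    paste(sort(unname(map[x])), collapse = "|")
  }, character(1))
  key2 <- vapply(strsplit(r2$results$contrast, " - "),
                 function(x) paste(sort(x), collapse = "|"), character(1))
  m <- match(key1, key2)
  expect_false(any(is.na(m)))
  expect_equal(r2$results$adj_p[m], r1$results$adj_p, tolerance = 3e-3)
  expect_equal(abs(r2$results$statistic[m]), abs(r1$results$statistic),
               tolerance = 1e-10)
})

test_that("adjusted p-values are monotone in |t| and bounded by raw p", {
  d <- hetero_data(seed = 20)
  r <- max_t_test(d, seed = 2)
  ord <- order(abs(r$results$statistic), decreasing = TRUE)
  expect_true(all(diff(r$results$adj_p[ord]) > -1e-9))
  praw <- 2 * pt(-abs(r$results$statistic), df = r$df)
  expect_true(all(r$results$adj_p >= praw - 1e-9))
  expect_true(all(r$results$adj_p >= 0 & r$results$adj_p <= 1))
})

test_that("interval decisions cohere with adjusted p-values", {
  for (s in c(2, 9, 31)) {
    r <- max_t_test(hetero_data(seed = s), alpha = 0.05, seed = 1)
    excludes <- r$results$conf_low > 0 | r$results$conf_high < 0
    expect_equal(excludes, r$results$adj_p < 0.05, label = paste("seed", s))
  }
})

test_that("balanced homoscedastic OLS ordering agrees with Tukey-Kramer", {
  d <- simulate_one_way(sizes = rep(10, 4), means = c(0, 0.3, 0.9, 1.4),
                        sds = 1, seed = 17)
  mt <- max_t_test(d, vcov = "OLS", seed = 1)
  tk <- tukey_kramer_test(d)
  expect_equal(order(mt$results$adj_p), order(tk$results$adj_p))
})

test_that("null configurations and degenerate inputs behave", {
  # exactly equal group means: all t = 0, all adjusted p = 1
  d0 <- data.frame(group = rep(c("A", "B"), each = 2),
                   value = c(-1, 1, -2, 2))
  r0 <- max_t_test(d0, seed = 1)
  expect_equal(r0$results$statistic, 0)
  expect_equal(r0$results$adj_p, 1)
  expect_equal(r0$n_significant, 0L)
  # zero residual variance: degenerate contrast variance
  dc <- data.frame(group = rep(c("A", "B"), each = 3),
                   value = rep(c(1, 2), each = 3))
  expect_error(max_t_test(dc, seed = 1), "degenerate contrast variance")
})

test_that("the report formats significance levels and counts", {
  d <- hetero_data(seed = 5)
  r <- max_t_test(d, seed = 1)
  lines <- capture.output(out <- maxt_report(r))
  expect_true(any(grepl("family-wise confidence level", lines)))
  expect_true(any(grepl("comparisons significant at alpha", lines)))
  # tiny p-values shown with a floor, stored numerically
  if (any(r$results$adj_p < 1e-3)) {
    expect_true(any(grepl("<0.001", lines, fixed = TRUE)))
    expect_true(all(r$results$adj_p >= 0))
  }
  expect_s3_class(autoplot(r), "ggplot")
})

test_that("HC3 and OLS intervals differ under heteroscedasticity", {
  d <- hetero_data(seed = 40)
  r_hc <- max_t_test(d, vcov = "HC3", seed = 1)
  r_ols <- max_t_test(d, vcov = "OLS", seed = 1)
  w_hc <- r_hc$results$conf_high - r_hc$results$conf_low
  w_ols <- r_ols$results$conf_high - r_ols$results$conf_low
  # some intervals narrower, some wider
  expect_true(any(w_hc < w_ols) && any(w_hc > w_ols))
})
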