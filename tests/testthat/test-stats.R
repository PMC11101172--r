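long_df <- function(...) {
  gs <- list(...)
  tibble::tibble(value = unlist(gs),
                 group = rep(names(gs), lengths(gs)))
}

test_that("Kruskal-Wallis matches the hand rank-sum formula", {
  same <- long_df(a = c(1, 2, 3), b = c(1, 2, 3))
  r0 <- kruskal_wallis(same, value, group)
  expect_lt(r0$statistic, 1e-10)
  expect_gt(r0$p_value, 0.99)

  d <- long_df(a = c(1.1, 2.3, 3.8, 4.1), b = c(2.9, 5.5, 6.2, 0.7),
               c = c(7.4, 8.8, 9.1, 3.3))
  r <- kruskal_wallis(d, value, group)
  # hand computation: H = 12/(N(N+1)) * sum(n_i * Rbar_i^2) - 3(N+1), no ties
  rk <- rank(d$value)
  rbar <- tapply(rk, d$group, mean)
  H <- 12 / (12 * 13) * sum(4 * rbar^2) - 3 * 13
  expect_equal(unname(r$statistic), unname(H))
  expect_equal(r$df, 2)

  sep <- long_df(a = 1:10, b = 11:20, c = 21:30)
  expect_lt(kruskal_wallis(sep, value, group)$p_value, 0.001)
  expect_error(kruskal_wallis(long_df(a = 1:3), value, group), "2 groups")
})

test_that("test statistics are invariant to group relabeling", {
  d <- long_df(a = c(1.1, 2.3, 3.8, 4.1), b = c(2.9, 5.5, 6.2, 0.7),
               c = c(7.4, 8.8, 9.1, 3.3))
  d2 <- d[rev(seq_len(nrow(d))), ]
  expect_equal(kruskal_wallis(d, value, group)$statistic,
               kruskal_wallis(d2, value, group)$statistic)
  ph <- dunn_posthoc(d, value, group)
  ph2 <- dunn_posthoc(d2, value, group)
  key <- function(t) paste(pmin(t$group1, t$group2), pmax(t$group1, t$group2))
  expect_equal(abs(ph$z[order(key(ph))]), abs(ph2$z[order(key(ph2))]))
})

test_that("Dunn post hoc reproduces brute-force mean-rank z statistics", {
  d <- long_df(a = c(1, 5, 8), b = c(2, 6, 9), c = c(15, 17, 20))
  ph <- dunn_posthoc(d, value, group)
  # independent computation from first principles
  rk <- rank(d$value)  # no ties
  N <- 9
  rbar <- tapply(rk, d$group, mean)
  se <- sqrt((N * (N + 1) / 12) * (2 / 3))
  z_ab <- (rbar[["a"]] - rbar[["b"]]) / se
  z_ac <- (rbar[["a"]] - rbar[["c"]]) / se
  row_ab <- ph[ph$group1 == "a" & ph$group2 == "b", ]
  row_ac <- ph[ph$group1 == "a" & ph$group2 == "c", ]
  expect_equal(row_ab$z, z_ab)
  expect_equal(row_ac$z, z_ac)
  expect_equal(row_ab$p_value, 2 * pnorm(-abs(z_ab)))
  expect_true(all(ph$p_adjusted >= ph$p_value))   # BH can only increase

  ident <- long_df(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  ph0 <- dunn_posthoc(ident, value, group)
  expect_true(all(ph0$p_adjusted > 0.99))

  # tie correction: duplicated values shrink the standard error term
  tied <- long_df(a = c(1, 1, 2), b = c(2, 3, 3), c = c(4, 4, 5))
  expect_silent(dunn_posthoc(tied, value, group))
})

test_that("Mann-Whitney uses exact enumeration for small tie-free samples", {
  d <- long_df(a = c(1, 2, 3), b = c(4, 5, 6))
  r <- mann_whitney(d, value, group)
  expect_equal(r$p_value, 2 / choose(6, 3))  # = 0.1, fully separated
  same <- long_df(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_gt(mann_whitney(same, value, group)$p_value, 0.99)

  # rank-test property: invariant under strictly monotone transforms
  set.seed(14)
  d2 <- long_df(a = rnorm(15), b = rnorm(15, 0.8))
  p1 <- mann_whitney(d2, value, group)$p_value
  d3 <- dplyr::mutate(d2, value = exp(value))
  expect_equal(mann_whitney(d3, value, group)$p_value, p1)
  expect_error(mann_whitney(long_df(a = 1:3, b = 1:3, c = 1:3), value, group),
               "2 groups")
})

test_that("Pearson chi-square matches the 2x2 closed form", {
  flat <- matrix(c(10, 10, 10, 10), 2)
  r <- chi2_contingency(flat)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$df, 1)

  set.seed(8)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    N <- sum(tab)
    closed <- (a * d - b * c)^2 * N /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(unname(chi2_contingency(tab)$statistic), closed)
  }

  # permutation of rows/columns leaves the statistic unchanged
  tab <- matrix(c(19, 7, 11, 23, 9, 30), 2)
  expect_equal(chi2_contingency(tab)$statistic,
               chi2_contingency(tab[2:1, c(2, 3, 1)])$statistic)
  expect_equal(chi2_contingency(tab)$df, 2)
})

test_that("Fisher's exact test: 2x2 enumeration and Monte-Carlo agreement", {
  r <- fisher_exact(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$p_value, 2 / choose(10, 5))  # 2/252

  # independence exactly at the margin expectation
  expect_equal(fisher_exact(matrix(c(10, 10, 10, 10), 2))$p_value, 1)

  rmc <- fisher_exact(matrix(c(5, 0, 0, 5), 2), mode = "montecarlo",
                      B = 1e5, seed = 42)
  expect_lt(abs(rmc$p_value - r$p_value), 3 * rmc$mc_se + 1 / rmc$B)
  expect_error(fisher_exact(matrix(1:4, 2), mode = "montecarlo", B = 10),
               "1e5")
  # RxC Monte-Carlo is reproducible for a fixed seed
  tab <- matrix(c(12, 3, 5, 9, 2, 7, 4, 8), 2)
  p1 <- fisher_exact(tab, seed = 7)$p_value
  p2 <- fisher_exact(tab, seed = 7)$p_value
  expect_identical(p1, p2)
})

test_that("Benjamini-Hochberg step-up adjustment", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(6)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving
})

test_that("group summaries are median and type-7 IQR", {
  d <- long_df(a = c(1, 2, 3, 4, 5), b = rep(7, 4))
  s <- summarize_groups(d, value, group)
  expect_equal(s$median, c(3, 7))
  expect_equal(s$iqr, c(2, 0))
  d2 <- dplyr::mutate(d, value = -2.5 * value)
  s2 <- summarize_groups(d2, value, group)
  expect_equal(s2$median, -2.5 * s$median)
  expect_equal(s2$iqr, 2.5 * s$iqr)
})

test_that("comparison objects expose tidy and glance views", {
  d <- long_df(a = rnorm(10), b = rnorm(10, 2), c = rnorm(10, 4))
  r <- kruskal_wallis(d, value, group, posthoc = TRUE)
  g <- glance(r)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_groups, 3)
  t <- tidy(r)
  expect_equal(nrow(t), 3)  # three pairs
  expect_true(all(c("group1", "group2", "p_adjusted") %in% names(t)))
  expect_output(print(r), "Kruskal-Wallis")
})
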