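new_comparison <- function(test_name, statistic = NA_real_, df = NA_real_,
                           p_value, posthoc = NULL, summaries = NULL,
                           extra = list()) {
  out <- c(list(test_name = test_name, statistic = unname(statistic),
                df = unname(df), p_value = unname(p_value),
                posthoc = posthoc, summaries = summaries), extra)
  class(out) <- "saltmig_comparison"
  out
}

#' @export
print.saltmig_comparison <- function(x, ...) {
  cat(x$test_name, "\n")
  if (!is.na(x$statistic)) {
    cat("  statistic =", format(x$statistic, digits = 5))
    if (!is.na(x$df)) cat(", df =", x$df)
    cat("\n")
  }
  cat("  p-value =", format.pval(x$p_value, digits = 4), "\n")
  if (!is.null(x$summaries)) {
    cat("  group summaries (median, IQR):\n")
    print(as.data.frame(x$summaries), row.names = FALSE)
  }
  if (!is.null(x$posthoc)) {
    cat("  post hoc (adjusted):\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Tidy a saltmig comparison
#'
#' Returns the post hoc pair table when present, otherwise a one-row tibble
#' of the omnibus test.
#'
#' @param x A `saltmig_comparison`.
#' @param ... Unused.
#' @method tidy saltmig_comparison
#' @export
tidy.saltmig_comparison <- function(x, ...) {
  if (!is.null(x$posthoc)) return(tibble::as_tibble(x$posthoc))
  tibble::tibble(test = x$test_name, statistic = x$statistic, df = x$df,
                 p.value = x$p_value)
}

#' One-row summary of a saltmig comparison
#'
#' @param x A `saltmig_comparison`.
#' @param ... Unused.
#' @method glance saltmig_comparison
#' @export
glance.saltmig_comparison <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic, df = x$df,
                 p.value = x$p_value,
                 n_groups = if (!is.null(x$summaries)) nrow(x$summaries) else NA_integer_)
}

resolve_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  keep <- !is.na(v) & !is.na(g)
  split(v[keep], factor(g[keep], levels = unique(g[keep])))
}

#' Median and IQR group summaries
#'
#' Results are conventionally reported as median (interquartile range);
#' quantiles use linear interpolation (R type 7).
#'
#' @param data Data frame.
#' @param value,group Unquoted column names of the measurement and group
#'   label.
#' @return Tibble with `group`, `n`, `median`, `q1`, `q3`, `iqr`.
#' @export
summarize_groups <- function(data, value, group) {
  gs <- resolve_groups(data, {{ value }}, {{ group }})
  purrr::imap(gs, function(v, nm) {
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(group = nm, n = length(v), median = q[2],
                   q1 = q[1], q3 = q[3], iqr = q[3] - q[1])
  }) |> dplyr::bind_rows()
}

#' Kruskal-Wallis rank-based comparison
#'
#' One-way Kruskal-Wallis analysis of variance on ranks (tie-corrected H,
#' chi-square reference with k-1 degrees of freedom), the default multi-group
#' test for the migration metrics, optionally followed by Dunn's post hoc
#' test ([dunn_posthoc()]).
#'
#' @inheritParams summarize_groups
#' @param posthoc Also run Dunn's test with Benjamini-Hochberg adjustment.
#' @return A `saltmig_comparison` object (statistic, df, p, per-group
#'   median/IQR summaries, optional post hoc table). Use [tidy()] /
#'   [glance()] for tibble views.
#' @export
kruskal_wallis <- function(data, value, group, posthoc = FALSE) {
  gs <- resolve_groups(data, {{ value }}, {{ group }})
  if (length(gs) < 2) abort("need at least 2 groups")
  kt <- kruskal.test(unname(gs))
  ph <- if (posthoc) dunn_posthoc(data, {{ value }}, {{ group }}) else NULL
  new_comparison("Kruskal-Wallis rank sum test",
                 statistic = kt$statistic, df = kt$parameter,
                 p_value = kt$p.value, posthoc = ph,
                 summaries = summarize_groups(data, {{ value }}, {{ group }}))
}

#' Dunn's post hoc test
#'
#' Pairwise z statistics from group mean ranks with tie correction,
#' following a Kruskal-Wallis test. For groups i, j on the pooled ranking of
#' N values, \deqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i +
#' 1/n_j)}} with tie term \eqn{T = \sum (t^3 - t) / (12 (N - 1))}. Two-sided
#' p-values are adjusted with the Benjamini-Hochberg step-up rule.
#'
#' @inheritParams summarize_groups
#' @param adjust Multiple-testing adjustment; only `"benjamini_hochberg"`.
#' @return Tibble with one row per unordered pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(data, value, group, adjust = "benjamini_hochberg") {
  if (!identical(adjust, "benjamini_hochberg")) {
    abort("only benjamini_hochberg adjustment is supported")
  }
  gs <- resolve_groups(data, {{ value }}, {{ group }})
  k <- length(gs)
  if (k < 2) abort("need at least 2 groups")
  pooled <- unlist(gs, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(gs)
  idx_end <- cumsum(sizes)
  idx_start <- idx_end - sizes + 1
  mean_ranks <- purrr::map2_dbl(idx_start, idx_end, ~ mean(r[.x:.y]))
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  z <- p <- numeric(ncol(pairs))
  for (c_i in seq_len(ncol(pairs))) {
    i <- pairs[1, c_i]; j <- pairs[2, c_i]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[i] + 1 / sizes[j]))
    z[c_i] <- (mean_ranks[i] - mean_ranks[j]) / se
    p[c_i] <- 2 * pnorm(-abs(z[c_i]))
  }
  tibble::tibble(
    group1 = names(gs)[pairs[1, ]],
    group2 = names(gs)[pairs[2, ]],
    z = z, p_value = p, p_adjusted = bh_adjust(p)
  )
}

#' Mann-Whitney rank sum test
#'
#' Two-sided Wilcoxon/Mann-Whitney U test for pairwise comparisons: exact
#' enumeration for small tie-free samples (both n <= 20), normal
#' approximation with tie correction otherwise.
#'
#' @inheritParams summarize_groups
#' @return A `saltmig_comparison` (U statistic, p, per-group summaries).
#' @export
mann_whitney <- function(data, value, group) {
  gs <- resolve_groups(data, {{ value }}, {{ group }})
  if (length(gs) != 2) abort("mann_whitney requires exactly 2 groups")
  a <- gs[[1]]; b <- gs[[2]]
  exact <- length(a) <= 20 && length(b) <= 20 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = FALSE))
  new_comparison("Mann-Whitney rank sum test",
                 statistic = wt$statistic, df = NA_real_,
                 p_value = wt$p.value,
                 summaries = summarize_groups(data, {{ value }}, {{ group }}))
}

#' Pearson chi-square test on an RxC contingency table
#'
#' Pearson statistic with df = (R-1)(C-1) and no continuity correction
#' (2-sample proportion comparisons are analysed as 2x2 tables).
#'
#' @param table Matrix of counts.
#' @return A `saltmig_comparison`.
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  new_comparison("Pearson's Chi-squared test",
                 statistic = ct$statistic, df = ct$parameter,
                 p_value = ct$p.value,
                 extra = list(observed = table, expected = ct$expected))
}

#' Fisher's exact test (2x2 exact, RxC Monte-Carlo)
#'
#' For 2x2 tables, the exact two-sided hypergeometric test (sum of the
#' probabilities of tables at least as extreme as the observed one). For
#' larger tables, a Monte-Carlo p-value over tables sampled with fixed
#' margins (at least 1e5 samples, fixed seed) reported with its Monte-Carlo
#' standard error.
#'
#' @param table Matrix of counts.
#' @param mode `"auto"` picks exact for 2x2 and Monte-Carlo otherwise;
#'   `"exact_2x2"` and `"montecarlo"` force a mode.
#' @param B Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo draw (recorded in the result).
#' @return A `saltmig_comparison`; Monte-Carlo results carry `mc_se`, `B`
#'   and `seed` fields.
#' @export
fisher_exact <- function(table, mode = c("auto", "exact_2x2", "montecarlo"),
                         B = 1e5, seed = 1) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (mode == "auto") {
    mode <- if (all(dim(table) == c(2, 2))) "exact_2x2" else "montecarlo"
  }
  if (mode == "exact_2x2") {
    if (!all(dim(table) == c(2, 2))) abort("exact_2x2 mode needs a 2x2 table")
    ft <- fisher.test(table)
    return(new_comparison("Fisher's exact test", p_value = ft$p.value))
  }
  B <- as.integer(B)
  if (B < 1e5) abort("Monte-Carlo mode requires B >= 1e5")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ft <- fisher.test(table, simulate.p.value = TRUE, B = B)
  p <- ft$p.value
  new_comparison("Fisher's exact test (Monte-Carlo)", p_value = p,
                 extra = list(mc_se = sqrt(p * (1 - p) / B), B = B,
                              seed = seed))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with enforced monotonicity,
#' capped at 1.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p.adjust(p, method = "BH")
}

#' Compare cohorts on one metric
#'
#' Convenience wrapper used by the pipeline/CLI: two groups get a
#' Mann-Whitney test, three or more a Kruskal-Wallis test with Dunn's post
#' hoc; median/IQR summaries are always attached.
#'
#' @param metrics Per-cell metrics tibble ([compute_cell_metrics()]) with a
#'   `group` column; QC-excluded rows should be filtered beforehand.
#' @param metric Unquoted metric column, e.g. `speed`.
#' @return A `saltmig_comparison`.
#' @export
compare_cohorts <- function(metrics, metric) {
  k <- length(unique(metrics$group))
  if (k < 2) abort("need at least 2 groups")
  if (k == 2) {
    mann_whitney(metrics, {{ metric }}, group)
  } else {
    kruskal_wallis(metrics, {{ metric }}, group, posthoc = TRUE)
  }
}
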