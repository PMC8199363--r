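#' ROUT-style robust outlier detection for a univariate sample
#'
#' Single-sample form of the robust-fit + false-discovery-rate outlier
#' procedure: the robust centre is the sample median, the robust scale
#' (RSDR) is the 68.27th percentile of the absolute residuals scaled by
#' n/(n - 1), each point gets a t-like statistic |residual| / RSDR with
#' n - 1 degrees of freedom, and points are tested from the most extreme
#' inward with the sequential FDR threshold Q (n - i + 1) / n on the
#' two-sided p-value of the i-th most extreme point; testing stops at the
#' first failure. On clean null data this flags approximately a fraction Q
#' of points. The mask is deterministic. A sample with zero robust spread
#' flags nothing.
#'
#' @param values Numeric sample, n >= 3.
#' @param q FDR rate in percent, in (0, 10\]. Default 1.
#' @return Logical inlier mask (`TRUE` = keep), same length as `values`.
#' @examples
#' x <- c(rnorm(20), 50)
#' which(!rout_outliers(x))
#' @export
rout_outliers <- function(values, q = 1) {
  if (!is.numeric(values) || length(values) < 3) {
    abort("`values` must be numeric with n >= 3.")
  }
  if (!is.numeric(q) || q <= 0 || q > 10) abort("`q` must be in (0, 10] percent.")
  n <- length(values)
  res <- values - median(values)
  rsdr <- unname(quantile(abs(res), 0.6827, type = 7)) * n / (n - 1)
  if (rsdr == 0) return(rep(TRUE, n))
  tval <- abs(res) / rsdr
  p <- 2 * pt(tval, df = n - 1, lower.tail = FALSE)
  ord <- order(p)
  keep <- rep(TRUE, n)
  qfrac <- q / 100
  for (i in seq_len(n)) {
    if (p[ord[i]] < qfrac * (n - i + 1) / n) {
      keep[ord[i]] <- FALSE
    } else {
      break
    }
  }
  keep
}

#' Normality screen (one-sample KS with Lilliefors correction)
#'
#' Tests a sample against a normal distribution with estimated mean and SD.
#' Because the parameters are estimated from the same data, the Lilliefors
#' correction of the one-sample Kolmogorov--Smirnov test is required (and is
#' what standard statistics packages apply for this screen); the decision is
#' recorded at the chosen significance level.
#'
#' @param values Numeric sample, n >= 5.
#' @param alpha Significance level (default 0.05).
#' @return A list with `statistic`, `p_value` and `normal` (logical decision
#'   at `alpha`; `FALSE` means normality rejected). A degenerate
#'   (constant) sample rejects with `p_value = 0`.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (!is.numeric(values) || length(values) < 5) {
    abort("`values` must be numeric with n >= 5.")
  }
  if (sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = 0, normal = FALSE))
  }
  kt <- nortest::lillie.test(values)
  list(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    normal = kt$p.value > alpha
  )
}

#' Kruskal--Wallis omnibus test with Dunn post-hoc comparisons
#'
#' Rank-based comparison of k groups: the tie-corrected Kruskal--Wallis H
#' statistic (via [stats::kruskal.test()]) for the omnibus hypothesis, then
#' Dunn's pairwise z-tests on mean ranks,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_g (t_g^3 - t_g)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with two-sided p-values adjusted for the C(k, 2) comparisons (Holm by
#' default). Identical groups give H close to 0 and omnibus p close to 1.
#'
#' @param data A data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping variable.
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return A `p31_group_comparison` list: `metric`, `groups` (per-group n,
#'   mean, sd, mean rank), `H`, `df`, `p_value`, and `pairwise` (tibble with
#'   `group1`, `group2`, `z`, `p_raw`, `p_adj`, `significant` at 0.05).
#' @export
kruskal_dunn <- function(data, value, group, p_adjust = "holm") {
  stopifnot(is.data.frame(data), value %in% names(data), group %in% names(data))
  x <- data[[value]]
  g <- as.factor(data[[group]])
  ok <- complete.cases(x, g)
  x <- x[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2) abort("Need at least 2 non-empty groups.")
  if (any(table(g) < 2)) abort("Every group needs n >= 2.")

  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_corr
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)

  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  pw <- purrr::map(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    se <- sqrt(var_term * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    tibble(group1 = g1, group2 = g2, z = z,
           p_raw = 2 * pnorm(abs(z), lower.tail = FALSE))
  }) %>% bind_rows()
  pw$p_adj <- p.adjust(pw$p_raw, method = p_adjust)
  pw$significant <- pw$p_adj < 0.05

  groups_tbl <- tibble(
    group = lev,
    n = as.integer(ns[lev]),
    mean = as.numeric(tapply(x, g, mean)[lev]),
    sd = as.numeric(tapply(x, g, sd)[lev]),
    mean_rank = as.numeric(mean_ranks[lev])
  )
  structure(
    list(
      metric = value,
      groups = groups_tbl,
      H = unname(kw$statistic),
      df = unname(kw$parameter),
      p_value = kw$p.value,
      pairwise = pw,
      p_adjust = p_adjust
    ),
    class = "p31_group_comparison"
  )
}

#' @export
print.p31_group_comparison <- function(x, ...) {
  cat(sprintf("<p31_group_comparison> %s: H = %.3f (df %d), p = %.3g\n",
              x$metric, x$H, x$df, x$p_value))
  print(x$pairwise, n = nrow(x$pairwise))
  invisible(x)
}

#' @rdname kruskal_dunn
#' @param x A `p31_group_comparison`.
#' @param ... Ignored.
#' @method tidy p31_group_comparison
#' @export
tidy.p31_group_comparison <- function(x, ...) {
  mutate(x$pairwise, metric = x$metric, .before = 1)
}

#' @rdname kruskal_dunn
#' @method glance p31_group_comparison
#' @export
glance.p31_group_comparison <- function(x, ...) {
  tibble(metric = x$metric, H = x$H, df = x$df, p_value = x$p_value,
         n = sum(x$groups$n))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of tie-averaged ranks; the p-value uses the
#' t approximation \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of
#' freedom. Invariant under strictly monotone transforms of either
#' variable.
#'
#' @param x,y Paired numeric samples, n >= 4; pairs with missing values are
#'   dropped.
#' @param variable_pair Optional label pair recorded in the output.
#' @param region Optional region label recorded in the output.
#' @return A one-row tibble: `var1`, `var2`, `region`, `rho`, `p_value`,
#'   `n`.
#' @export
spearman_cor <- function(x, y, variable_pair = c("x", "y"), region = NA_character_) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) abort("Need at least 4 complete pairs.")
  r <- cor(rank(x), rank(y))
  p <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  tibble(var1 = variable_pair[1], var2 = variable_pair[2],
         region = region, rho = r, p_value = p, n = n)
}

#' Regional descriptive table of the twelve metrics
#'
#' Mean +/- SD of every metric (ten ratios, pH, Mg2+) per region, in the
#' layout of a regional summary table: one row per metric, one column pair
#' per region. Regions with a single voxel report `NA` SD; requested
#' regions with no voxels are flagged missing.
#'
#' @param cohort A cohort tibble (e.g. from [run_pipeline()]) with a
#'   `region` column and the metric columns; normally already
#'   quality-controlled and outlier-screened.
#' @param metrics Metric column names (default the twelve reported ones).
#' @param regions Regions to tabulate (default [region_levels()] present in
#'   the data).
#' @return A tibble in long form: `metric`, `region`, `n`, `mean`, `sd`.
#'   Use [regional_table_wide()] for the one-row-per-metric layout.
#' @export
regional_table <- function(cohort, metrics = .metric_names,
                           regions = NULL) {
  stopifnot(is.data.frame(cohort), "region" %in% names(cohort))
  metrics <- intersect(metrics, names(cohort))
  if (!length(metrics)) abort("None of the requested metric columns are present.")
  regions <- regions %||% intersect(region_levels(), unique(cohort$region))
  missing_regions <- setdiff(regions, unique(cohort$region))
  long <- cohort %>%
    filter(.data$region %in% regions) %>%
    tidyr::pivot_longer(all_of(metrics), names_to = "metric",
                        values_to = "value") %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$metric, .data$region) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      metric = factor(.data$metric, levels = metrics),
      region = factor(.data$region, levels = regions)
    ) %>%
    arrange(.data$metric, .data$region) %>%
    mutate(metric = as.character(.data$metric),
           region = as.character(.data$region))
  if (length(missing_regions)) {
    attr(long, "missing_regions") <- missing_regions
  }
  long
}

#' @rdname regional_table
#' @param table A long table from [regional_table()].
#' @param digits Rounding for the formatted `mean +/- sd` strings.
#' @export
regional_table_wide <- function(table, digits = 2) {
  table %>%
    mutate(cell = sprintf(paste0("%.", digits, "f ± %.", digits, "f"),
                          .data$mean, .data$sd)) %>%
    select("metric", "region", "cell") %>%
    tidyr::pivot_wider(names_from = "region", values_from = "cell")
}

#' Mean-and-SD plot of the regional metrics
#'
#' @param table A long table from [regional_table()].
#' @return A ggplot faceted by metric, one point-range per region.
#' @export
plot_regional <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$region, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    )) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = "mean ± SD")
}
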