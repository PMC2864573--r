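# Occupancy-expression statistics: sliding-window correlation, expression
# quantile tables, bootstrap KS and rank-sum tests, TFIIB/NC2 ratio curves,
# dominated-set selection and TSS shape classification.

drop_absent <- function(data) {
  if ("present" %in% names(data)) filter(data, .data$present) else data
}

#' Sliding-window occupancy-expression curve
#'
#' Sorts genes by occupancy, partitions the occupancy axis into consecutive
#' non-overlapping intervals of width `step` (log2 units), and computes the
#' mean expression per window. Windows holding fewer than `min_genes` genes
#' are merged with the following window. Records flagged absent (a `present`
#' column, if any) are excluded.
#'
#' @param data Tibble with one row per gene.
#' @param occupancy,expression Names of the occupancy and expression columns.
#' @param step Window width on the occupancy scale (default 0.1).
#' @param min_genes Minimum genes per window before merging (default 10).
#' @return Object of class `sliding_window_fit`: window tibble
#'   (`occupancy`, `mean_expression`, `n_genes`) plus the Pearson correlation
#'   `pearson_r` of the window curve.
#' @export
sliding_window_expression <- function(data, occupancy = "occupancy",
                                      expression = "expression",
                                      step = 0.1, min_genes = 10) {
  stopifnot(step > 0, all(c(occupancy, expression) %in% names(data)))
  df <- drop_absent(data)
  df <- df[order(df[[occupancy]]), , drop = FALSE]
  occ <- df[[occupancy]]
  expr <- df[[expression]]
  raw_win <- floor((occ - min(occ)) / step)
  # merge small windows forward
  group <- integer(length(occ))
  g <- 1L
  count_in_g <- 0L
  uw <- unique(raw_win)
  for (w in uw) {
    members <- raw_win == w
    group[members] <- g
    count_in_g <- count_in_g + sum(members)
    if (count_in_g >= min_genes) {
      g <- g + 1L
      count_in_g <- 0L
    }
  }
  if (count_in_g > 0 && g > 1L) group[group == g] <- g - 1L
  windows <- tibble(group = group, occ = occ, expr = expr) %>%
    group_by(.data$group) %>%
    summarise(occupancy = mean(.data$occ),
              mean_expression = mean(.data$expr),
              n_genes = n(), .groups = "drop") %>%
    select(-all_of("group"))
  if (nrow(windows) < 2) abort("fewer than 2 populated windows")
  structure(list(
    windows = windows,
    pearson_r = cor(windows$occupancy, windows$mean_expression),
    step = step, min_genes = min_genes, n_genes = nrow(df)
  ), class = "sliding_window_fit")
}

#' @export
print.sliding_window_fit <- function(x, ...) {
  cat("Sliding-window occupancy-expression curve:", nrow(x$windows),
      "windows over", x$n_genes, "genes\n")
  cat(sprintf("  Pearson r of window curve: %.4f\n", x$pearson_r))
  invisible(x)
}

#' Expression-quantile distribution across occupancy deciles
#'
#' Ranks genes into occupancy deciles and expression quantiles and
#' tabulates, per occupancy decile, the fraction of genes in each expression
#' quantile (rows sum to 1). Also reports, per occupancy decile, the fraction
#' of genes expressed above the overall expression median.
#'
#' @param data Tibble with one row per gene.
#' @param occupancy,expression Column names.
#' @param n_quantiles Number of expression quantiles (default 10).
#' @return List of class `quantile_distribution` with tibbles `table`
#'   (`occupancy_decile`, `expression_quantile`, `fraction`) and
#'   `above_median` (`occupancy_decile`, `fraction_above_median`).
#' @export
quantile_distribution <- function(data, occupancy = "occupancy",
                                  expression = "expression",
                                  n_quantiles = 10) {
  stopifnot(all(c(occupancy, expression) %in% names(data)))
  df <- drop_absent(data)
  stopifnot(nrow(df) >= n_quantiles)
  med <- median(df[[expression]])
  df <- df %>%
    mutate(occupancy_decile = dplyr::ntile(.data[[occupancy]], 10),
           expression_quantile = dplyr::ntile(.data[[expression]], n_quantiles))
  tab <- df %>%
    count(.data$occupancy_decile, .data$expression_quantile) %>%
    group_by(.data$occupancy_decile) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup() %>%
    select(-all_of("n"))
  above <- df %>%
    group_by(.data$occupancy_decile) %>%
    summarise(fraction_above_median = mean(.data[[expression]] > med),
              .groups = "drop")
  structure(list(table = tab, above_median = above,
                 n_quantiles = n_quantiles, n = nrow(df)),
            class = "quantile_distribution")
}

# Two-sample KS statistic, sup |ECDF_a - ECDF_b|.
ks_statistic <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  w <- c(a, b)
  z <- cumsum(ifelse(order(w) <= na, 1 / na, -1 / nb))
  ws <- sort(w)
  max(abs(z[c(diff(ws) != 0, TRUE)]))
}

#' Bootstrap two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup |ECDF_a - ECDF_b|` and a bootstrap p-value: the pooled
#' sample is resampled with replacement into the original group sizes
#' `n_boot` times, and `p = (1 + #\{D* >= D\}) / (n_boot + 1)`. The
#' resampling null keeps the test valid in the presence of ties, where the
#' classical KS null distribution does not hold.
#'
#' @param a,b Numeric samples (non-empty).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Optional seed for the resampling.
#' @return Object of class `ks_boot_test` with `statistic` (D), `p_value`,
#'   `n_a`, `n_b`, `n_boot`.
#' @export
ks_boot <- function(a, b, n_boot = 1000, seed = NULL) {
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  stopifnot(n_boot >= 100)
  if (!is.null(seed)) set.seed(seed)
  na <- length(a)
  nb <- length(b)
  D <- ks_statistic(a, b)
  pooled <- c(a, b)
  n <- na + nb
  hits <- 0L
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Dstar <- ks_statistic(pooled[idx[seq_len(na)]], pooled[idx[-seq_len(na)]])
    if (Dstar >= D) hits <- hits + 1L
  }
  structure(list(statistic = D, p_value = (1 + hits) / (n_boot + 1),
                 n_a = na, n_b = nb, n_boot = n_boot,
                 method = "bootstrap two-sample Kolmogorov-Smirnov"),
            class = "ks_boot_test")
}

#' @export
print.ks_boot_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  D = %.4f, p = %.4g (n_a = %d, n_b = %d, %d bootstrap replicates)\n",
              x$statistic, x$p_value, x$n_a, x$n_b, x$n_boot))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney test on positions
#'
#' Two-sided rank-sum test with normal approximation, tie correction and
#' continuity correction, used to compare the genomic positions of
#' high-score probes between two factors.
#'
#' @param positions_a,positions_b Integer/numeric position vectors.
#' @return Object of class `ranksum_test` with `statistic` (W), `p_value`,
#'   group sizes.
#' @export
ranksum_positions <- function(positions_a, positions_b) {
  if (length(positions_a) == 0 || length(positions_b) == 0) {
    abort("both position vectors must be non-empty")
  }
  wt <- wilcox.test(positions_a, positions_b, alternative = "two.sided",
                    exact = FALSE, correct = TRUE)
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(positions_a), n_b = length(positions_b),
                 method = "Wilcoxon-Mann-Whitney (normal approximation)"),
            class = "ranksum_test")
}

#' @export
print.ranksum_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  W = %.1f, p = %.4g (n_a = %d, n_b = %d)\n",
              x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' TFIIB/NC2 ratio across expression percentile bins
#'
#' Ranks genes by expression into bins of `bin_pct` percent, converts the
#' per-gene log2 enrichments to the linear scale (2^x), and reports per bin
#' the mean linear TFIIB and NC2 enrichment and their ratio. Averaging on the
#' linear scale keeps the ratio positive and interpretable as relative PIC
#' dominance.
#'
#' @param data Tibble with one row per gene.
#' @param tfiib,nc2,expression Column names; `tfiib`/`nc2` hold log2
#'   enrichments.
#' @param bin_pct Bin width in expression percentiles; must divide 100.
#' @return Tibble of class `ratio_curve`: `bin`, `pct_lo`, `pct_hi`,
#'   `mean_tfiib`, `mean_nc2` (linear scale), `ratio`, `n_genes`.
#' @export
ratio_curve <- function(data, tfiib = "tfiib", nc2 = "nc2",
                        expression = "expression", bin_pct = 5) {
  stopifnot(all(c(tfiib, nc2, expression) %in% names(data)))
  if (100 %% bin_pct != 0) abort("bin_pct must divide 100")
  df <- drop_absent(data)
  n_bins <- as.integer(100 / bin_pct)
  stopifnot(nrow(df) >= n_bins)
  out <- df %>%
    mutate(bin = dplyr::ntile(.data[[expression]], n_bins)) %>%
    group_by(.data$bin) %>%
    summarise(mean_tfiib = mean(2^.data[[tfiib]]),
              mean_nc2 = mean(2^.data[[nc2]]),
              n_genes = n(), .groups = "drop") %>%
    mutate(pct_lo = (.data$bin - 1) * bin_pct,
           pct_hi = .data$bin * bin_pct,
           ratio = .data$mean_tfiib / .data$mean_nc2) %>%
    select(all_of(c("bin", "pct_lo", "pct_hi", "mean_tfiib", "mean_nc2",
                    "ratio", "n_genes")))
  class(out) <- c("ratio_curve", class(out))
  out
}

#' Select TFIIB- and NC2-dominated gene sets
#'
#' Restricts to active genes (at or above the `cutoff_pct` percentile in
#' TFIIB occupancy, NC2 occupancy and expression simultaneously), computes
#' the per-gene linear TFIIB/NC2 ratio, and returns the `top_n` genes with
#' the highest ratios (TFIIB-dominated) and lowest ratios (NC2-dominated).
#' Ties at the selection boundary break deterministically by promoter id.
#'
#' @param data Tibble with `promoter_id` and the three tracks.
#' @param tfiib,nc2,expression Column names (log2 scale for the factors).
#' @param cutoff_pct Eligibility percentile (default 60).
#' @param top_n Set size (default 100).
#' @return List of class `dominated_sets`: `tfiib_dominated` and
#'   `nc2_dominated` (promoter id vectors), `ratios` (eligible-gene tibble),
#'   `eligible_n`.
#' @export
select_dominated <- function(data, tfiib = "tfiib", nc2 = "nc2",
                             expression = "expression",
                             cutoff_pct = 60, top_n = 100) {
  stopifnot(all(c("promoter_id", tfiib, nc2, expression) %in% names(data)))
  df <- drop_absent(data)
  thr <- vapply(c(tfiib, nc2, expression),
                function(cl) quantile(df[[cl]], cutoff_pct / 100, names = FALSE),
                numeric(1))
  eligible <- df[df[[tfiib]] >= thr[1] & df[[nc2]] >= thr[2] &
                   df[[expression]] >= thr[3], , drop = FALSE]
  if (nrow(eligible) < top_n) {
    abort(paste0("only ", nrow(eligible), " eligible genes for top_n = ",
                 top_n))
  }
  ratios <- eligible %>%
    mutate(ratio = 2^(.data[[tfiib]] - .data[[nc2]])) %>%
    select(all_of(c("promoter_id", "ratio")))
  hi <- ratios %>%
    arrange(desc(.data$ratio), .data$promoter_id) %>%
    head(top_n)
  lo <- ratios %>%
    arrange(.data$ratio, .data$promoter_id) %>%
    head(top_n)
  structure(list(tfiib_dominated = hi$promoter_id,
                 nc2_dominated = lo$promoter_id,
                 ratios = ratios, eligible_n = nrow(eligible),
                 cutoff_pct = cutoff_pct, top_n = top_n),
            class = "dominated_sets")
}

#' @export
print.dominated_sets <- function(x, ...) {
  cat("Dominated-set selection:", x$eligible_n, "eligible genes (cutoff",
      paste0(x$cutoff_pct, "th"), "percentile)\n")
  cat(sprintf("  per-gene TFIIB/NC2 ratio range: %.3g .. %.3g\n",
              max(x$ratios$ratio), min(x$ratios$ratio)))
  cat("  TFIIB-dominated:", length(x$tfiib_dominated), "genes;",
      "NC2-dominated:", length(x$nc2_dominated), "genes\n")
  invisible(x)
}

classify_shape_one <- function(offset, count) {
  keep <- count > 0
  offset <- offset[keep]
  count <- count[keep]
  total <- sum(count)
  if (length(offset) == 0 || total < 1) abort("empty tag map")
  class4 <- if (max(offset) - min(offset) <= 4L) {
    "single"
  } else if (max(count) / total > 0.5) {
    # strict majority: two equal half-share peaks are not 'dominant'
    "dominant"
  } else {
    # greedy peak picking: strongest positions first, enforcing >= 25 bp
    # separation and >= 20% of tags per retained peak
    ord <- order(-count, offset)
    peaks <- integer(0)
    for (i in ord) {
      if (count[i] < 0.2 * total) break
      if (all(abs(offset[i] - peaks) >= 25L)) peaks <- c(peaks, offset[i])
    }
    if (length(peaks) >= 2) "multimodal" else "broad"
  }
  tibble(class4 = class4,
         class2 = if (class4 %in% c("single", "dominant")) "focused"
                  else "dispersed",
         tag_total = total)
}

#' Classify TSS shape from tag-count vectors
#'
#' Four-way classification of per-promoter tag distributions: `single` (all
#' tags within a 4-bp span), `dominant` (one position holds at least half the
#' tags), `multimodal` (two or more peaks at least 25 bp apart, each holding
#' at least 20% of tags), else `broad`. `single`/`dominant` promoters are
#' `focused`; `broad`/`multimodal` are `dispersed`. The thresholds are
#' exposed in code and the classification is invariant under common position
#' shifts.
#'
#' @param cage_tags Tibble with `promoter_id`, `offset`, `count`.
#' @return Tibble with `promoter_id`, `class4`, `class2`, `tag_total`.
#' @export
classify_tss_shape <- function(cage_tags) {
  stopifnot(all(c("promoter_id", "offset", "count") %in% names(cage_tags)))
  cage_tags %>%
    group_by(.data$promoter_id) %>%
    group_modify(~ classify_shape_one(.x$offset, .x$count)) %>%
    ungroup()
}

#' Mean tag total per promoter
#'
#' @param cage_tags Tibble with `promoter_id`, `offset`, `count`.
#' @param ids Optional promoter ids to average over (default all).
#' @return Arithmetic mean of per-promoter tag totals.
#' @export
mean_tags <- function(cage_tags, ids = NULL) {
  totals <- cage_tags %>%
    group_by(.data$promoter_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (!is.null(ids)) {
    if (length(ids) == 0) abort("`ids` must be non-empty")
    totals <- filter(totals, .data$promoter_id %in% ids)
  }
  mean(totals$total)
}
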