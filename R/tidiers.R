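# broom-style tidiers for corepic result objects.

#' @export
tidy.ks_boot_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, n_boot = x$n_boot, method = x$method)
}

#' @export
glance.ks_boot_test <- function(x, ...) tidy(x)

#' @export
tidy.ranksum_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value,
         n_a = x$n_a, n_b = x$n_b, method = x$method)
}

#' @export
glance.ranksum_test <- function(x, ...) tidy(x)

#' @export
tidy.sliding_window_fit <- function(x, ...) x$windows

#' @export
glance.sliding_window_fit <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, n_windows = nrow(x$windows),
         n_genes = x$n_genes, step = x$step)
}

#' @export
tidy.concordance_report <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, overlap_fraction = x$overlap_fraction,
         top_a_size = x$top_a_size, top_b_size = x$top_b_size, n = x$n)
}

#' @export
glance.concordance_report <- function(x, ...) tidy(x)

#' @export
tidy.combination_report <- function(x, ...) x$size_counts

#' @export
glance.combination_report <- function(x, ...) {
  tibble(n = x$n, classes = paste(x$classes, collapse = ","),
         at_least_one = sum(x$size_counts$count[x$size_counts$size != "0"]))
}

#' @export
tidy.quantile_distribution <- function(x, ...) x$table

#' @export
glance.quantile_distribution <- function(x, ...) {
  tibble(n = x$n, n_quantiles = x$n_quantiles)
}

#' @export
tidy.dominated_sets <- function(x, ...) {
  x$ratios %>%
    mutate(set = dplyr::case_when(
      .data$promoter_id %in% x$tfiib_dominated ~ "tfiib_dominated",
      .data$promoter_id %in% x$nc2_dominated ~ "nc2_dominated",
      TRUE ~ "eligible"
    ))
}

#' @export
glance.dominated_sets <- function(x, ...) {
  tibble(eligible_n = x$eligible_n, top_n = x$top_n,
         cutoff_pct = x$cutoff_pct,
         max_ratio = max(x$ratios$ratio), min_ratio = min(x$ratios$ratio))
}
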