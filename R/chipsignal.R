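# Probe scaling, promoter scoring, peak calling and TSS-aligned profiles for
# tiling-array ChIP/input log2 ratios.

#' One-step Tukey biweight mean
#'
#' Robust location estimate used to center tiling-array log2 ratios: with
#' `M = median(x)` and `S = median(|x - M|)`, weights are
#' `w_i = (1 - u_i^2)^2` for `|u_i| < 1` (else 0) where
#' `u_i = (x_i - M) / (c * S + eps)`, and the estimate is the weighted mean.
#' Falls back to the median when every weight is zero.
#'
#' @param x Numeric vector with at least one finite value.
#' @param c Tuning constant (default 5, the array-analysis convention).
#' @param eps Small stabilizer added to `c * S` (default 1e-4).
#' @return The biweight location (scalar).
#' @examples
#' biweight_mean(c(1, 2, 3, 4, 100))
#' @export
biweight_mean <- function(x, c = 5, eps = 1e-4) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("biweight_mean: no finite values")
  M <- median(x)
  S <- median(abs(x - M))
  u <- (x - M) / (c * S + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(M)
  sum(w * x) / sum(w)
}

#' Center probe signals with the biweight mean
#'
#' Subtracts the Tukey biweight mean of all probe values on each array
#' (each `factor` x `replicate` combination) from every probe value, centering
#' the log2 ratios around zero by robust statistics. Idempotent up to the
#' near-zero biweight mean of already-scaled data.
#'
#' @param signals Probe-signal tibble with columns `factor`, `replicate` and
#'   `log2_ratio` (as produced by [generate_cohort()]).
#' @param value Name of the column to scale (default `"log2_ratio"`).
#' @return The input tibble with an added `scaled` column.
#' @export
scale_signals <- function(signals, value = "log2_ratio") {
  stopifnot(value %in% names(signals))
  grouping <- intersect(c("factor", "replicate"), names(signals))
  signals %>%
    group_by(across(all_of(grouping))) %>%
    mutate(scaled = .data[[value]] - biweight_mean(.data[[value]])) %>%
    ungroup()
}

#' Promoter occupancy scores
#'
#' The median of the scaled log2 ChIP/input ratio of each 15-probe probeset
#' measures promoter occupancy.
#'
#' @param signals Scaled probe-signal tibble (from [scale_signals()]).
#' @param value Column to summarise (default `"scaled"`).
#' @return Tibble with `promoter_id`, `factor`, `replicate`, `score`.
#' @export
promoter_scores <- function(signals, value = "scaled") {
  stopifnot(value %in% names(signals))
  grouping <- intersect(c("promoter_id", "factor", "replicate"),
                        names(signals))
  scores <- signals %>%
    group_by(across(all_of(grouping))) %>%
    summarise(score = median(.data[[value]]), n_probes = n(),
              .groups = "drop")
  bad <- scores$promoter_id[scores$n_probes != 15L]
  if (length(bad) > 0) {
    abort(paste0("promoter '", bad[1], "' has ",
                 scores$n_probes[scores$n_probes != 15L][1],
                 " probes; 15 are required"))
  }
  select(scores, -all_of("n_probes"))
}

#' Threshold-run peak calling
#'
#' Calls peaks on a per-position score series at a cut-off of
#' `mean + k * sd` (population sd, n denominator). A peak is a maximal run of
#' at least `min_run` consecutive positions strictly above the threshold; the
#' apex is the position of the run maximum (leftmost on ties). A zero-variance
#' series yields zero peaks.
#'
#' @param scores Numeric score series.
#' @param k Stringency multiplier in standard deviations (> 0).
#' @param min_run Minimum run length (>= 1).
#' @param positions Positions of the scores (default `seq_along(scores)`).
#' @param threshold Optional explicit threshold overriding `mean + k * sd`
#'   (used when calling within regions against an array-wide cut-off).
#' @return Tibble with `start`, `end`, `apex`, `height`, one row per peak.
#' @examples
#' call_peaks(c(0, 0, 0, 9, 9, 0, 0, 0, 0, 0), k = 1, min_run = 2)
#' @export
call_peaks <- function(scores, k = 1, min_run = 2,
                       positions = seq_along(scores), threshold = NULL) {
  stopifnot(k > 0, min_run >= 1, length(scores) >= min_run,
            length(positions) == length(scores))
  if (is.null(threshold)) {
    mu <- mean(scores)
    sd_pop <- sqrt(mean((scores - mu)^2))
    threshold <- mu + k * sd_pop
  }
  above <- scores > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) {
    return(tibble(start = numeric(), end = numeric(),
                  apex = numeric(), height = numeric()))
  }
  out <- lapply(which(keep), function(j) {
    idx <- starts[j]:ends[j]
    apex_i <- idx[which.max(scores[idx])]  # which.max is leftmost on ties
    tibble(start = positions[starts[j]], end = positions[ends[j]],
           apex = positions[apex_i], height = scores[apex_i])
  })
  bind_rows(out)
}

#' Call peaks per promoter region against an array-wide cut-off
#'
#' Applies [call_peaks()] within each promoter's ordered probe series, with
#' the threshold `mean + k * sd` computed over all probes of the array
#' (each `factor` x `replicate`).
#'
#' @param signals Scaled probe-signal tibble.
#' @param k Stringency multiplier.
#' @param min_run Minimum consecutive probes above threshold.
#' @param value Score column (default `"scaled"`).
#' @return Tibble of peaks with `factor`, `replicate`, `promoter_id`,
#'   `start`, `end`, `apex` (probe offsets, bp), `height`, `k`.
#' @export
call_promoter_peaks <- function(signals, k = 1, min_run = 2,
                                value = "scaled") {
  stopifnot(value %in% names(signals))
  signals %>%
    group_by(across(all_of(intersect(c("factor", "replicate"),
                                     names(signals))))) %>%
    group_modify(function(df, key) {
      x <- df[[value]]
      mu <- mean(x)
      thr <- mu + k * sqrt(mean((x - mu)^2))
      df %>%
        arrange(.data$promoter_id, .data$offset) %>%
        group_by(.data$promoter_id) %>%
        group_modify(~ call_peaks(.x[[value]], k = k, min_run = min_run,
                                  positions = .x$offset, threshold = thr)) %>%
        ungroup()
    }) %>%
    ungroup() %>%
    mutate(k = k)
}

#' Probes in the top percentile of scaled signal
#'
#' @param signals Scaled probe-signal tibble.
#' @param pct Percentile width, in (0, 100): `pct = 5` keeps probes at or
#'   above the 95th percentile; ties at the boundary are included.
#' @param value Score column (default `"scaled"`).
#' @return The qualifying rows of `signals`.
#' @export
top_percentile_probes <- function(signals, pct = 5, value = "scaled") {
  stopifnot(pct > 0, pct < 100, value %in% names(signals))
  if (nrow(signals) == 0) abort("empty signal table")
  thr <- quantile(signals[[value]], 1 - pct / 100, names = FALSE)
  filter(signals, .data[[value]] >= thr)
}

#' Replicate concordance of promoter scores
#'
#' Pearson correlation of paired promoter scores plus the fraction of one
#' replicate's top-percentile promoters recovered in the other replicate's
#' (wider) top-percentile set. Percentile boundaries include tied values.
#'
#' @param data Tibble with `promoter_id` and two score columns.
#' @param score_a,score_b Names of the two score columns.
#' @param top_pct_a Percentile width defining the first replicate's top set
#'   (default 5: upper 5th percentile).
#' @param top_pct_b Percentile width for the second replicate's reference set
#'   (default 10).
#' @return Object of class `concordance_report` with `pearson_r`,
#'   `overlap_fraction`, set sizes and `n`.
#' @export
replicate_concordance <- function(data, score_a, score_b,
                                  top_pct_a = 5, top_pct_b = 10) {
  stopifnot(all(c("promoter_id", score_a, score_b) %in% names(data)))
  if (nrow(data) < 3) abort("at least 3 paired promoters are required")
  a <- data[[score_a]]
  b <- data[[score_b]]
  thr_a <- quantile(a, 1 - top_pct_a / 100, names = FALSE)
  thr_b <- quantile(b, 1 - top_pct_b / 100, names = FALSE)
  top_a <- data$promoter_id[a >= thr_a]
  top_b <- data$promoter_id[b >= thr_b]
  structure(list(
    pearson_r = cor(a, b),
    overlap_fraction = length(intersect(top_a, top_b)) / length(top_a),
    top_a_size = length(top_a),
    top_b_size = length(top_b),
    top_pct_a = top_pct_a,
    top_pct_b = top_pct_b,
    n = nrow(data)
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Replicate concordance over", x$n, "promoters\n")
  cat(sprintf("  Pearson r: %.4f\n", x$pearson_r))
  cat(sprintf("  overlap: %.1f%% of the top %g%% set (n=%d) found in the top %g%% set (n=%d)\n",
              100 * x$overlap_fraction, x$top_pct_a, x$top_a_size,
              x$top_pct_b, x$top_b_size))
  invisible(x)
}

# Nearest multiple of `width` with .5 ties rounded toward 0.
bin_center <- function(offset, width = 10L) {
  q <- offset %/% width
  rem <- offset %% width
  half <- width / 2
  ifelse(rem < half, q * width,
         ifelse(rem > half, (q + 1) * width,
                ifelse(offset < 0, (q + 1) * width, q * width)))
}

#' TSS-aligned average binding profile
#'
#' Bins strand-oriented probe offsets into 10-bp bins around the aligned TSS
#' and reports, per bin, the fraction of high-score probes relative to all
#' available probes at that position (availability correction). Bins with no
#' available probes are omitted.
#'
#' @param high_probes Tibble with `promoter_id`, `offset` for high-score
#'   probes; must be a sub-multiset of `all_probes`.
#' @param all_probes Tibble with `promoter_id`, `offset` for all available
#'   probes.
#' @param mode `"fraction"` (raw high/available) or `"max1"` (fractions
#'   rescaled so the maximum equals 1).
#' @param bin_width Bin width in bp (default 10).
#' @return Tibble of class `binding_profile` with `bin_center`, `available`,
#'   `high`, `fraction`.
#' @export
build_profile <- function(high_probes, all_probes,
                          mode = c("fraction", "max1"), bin_width = 10L) {
  mode <- arg_match(mode)
  need <- c("promoter_id", "offset")
  stopifnot(all(need %in% names(high_probes)), all(need %in% names(all_probes)))
  hc <- count(high_probes, .data$promoter_id, .data$offset, name = "n_high")
  ac <- count(all_probes, .data$promoter_id, .data$offset, name = "n_all")
  chk <- left_join(hc, ac, by = need)
  if (any(is.na(chk$n_all)) || any(chk$n_high > chk$n_all)) {
    abort("high_probes must be a subset of all_probes")
  }
  avail <- all_probes %>%
    mutate(bin_center = bin_center(.data$offset, bin_width)) %>%
    count(.data$bin_center, name = "available")
  high <- high_probes %>%
    mutate(bin_center = bin_center(.data$offset, bin_width)) %>%
    count(.data$bin_center, name = "high")
  prof <- avail %>%
    left_join(high, by = "bin_center") %>%
    mutate(high = dplyr::coalesce(.data$high, 0L),
           fraction = .data$high / .data$available) %>%
    arrange(.data$bin_center)
  if (mode == "max1") prof$fraction <- prof$fraction / max(prof$fraction)
  attr(prof, "mode") <- mode
  class(prof) <- c("binding_profile", class(prof))
  prof
}

#' Modal bin of a binding profile
#'
#' @param profile A `binding_profile` from [build_profile()].
#' @return The `bin_center` with the highest fraction (leftmost on ties).
#' @export
profile_mode <- function(profile) {
  profile$bin_center[which.max(profile$fraction)]
}
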