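gene_table <- function(n, coupling = 1, noise = 0, seed = 1, rho = 0.8) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(
    promoter_id = sprintf("g%04d", 1:n),
    tfiib = 1 + z1,
    nc2 = 1 + z2,
    occupancy = 1 + z1,
    expression = coupling * (1 + z1) + rnorm(n, 0, noise)
  )
}

test_that("sliding window recovers a perfect monotone coupling", {
  d <- gene_table(500, coupling = 1, noise = 0, seed = 601)
  fit <- sliding_window_expression(d)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
  expect_true(all(fit$windows$n_genes >= 10 |
                    dplyr::row_number(fit$windows$occupancy) == nrow(fit$windows)))
  expect_equal(sum(fit$windows$n_genes), 500)
})

test_that("sliding window r is small under independence, large under coupling", {
  rs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    d <- tibble::tibble(promoter_id = sprintf("g%04d", 1:2000),
                        occupancy = rnorm(2000),
                        expression = rnorm(2000))
    sliding_window_expression(d)$pearson_r
  }, numeric(1))
  expect_true(all(abs(rs) < 0.6))
  expect_lt(mean(abs(rs)), 0.3)
  d <- gene_table(2000, coupling = 1, noise = 0.2, seed = 602)
  expect_gt(sliding_window_expression(d)$pearson_r, 0.9)
})

test_that("degenerate occupancy collapses to a single window and errors", {
  d <- tibble::tibble(promoter_id = c("a", "b", "c"),
                      occupancy = c(1, 1, 1), expression = c(1, 2, 3))
  expect_error(sliding_window_expression(d, min_genes = 1), "windows")
})

test_that("quantile distribution rows sum to one and track coupling", {
  d <- gene_table(1000, coupling = 1, noise = 0, seed = 603)
  qd <- quantile_distribution(d)
  sums <- qd$table %>%
    dplyr::group_by(occupancy_decile) %>%
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # perfect coupling: top occupancy decile sits in the top expression decile
  top <- qd$table %>%
    dplyr::filter(occupancy_decile == 10, expression_quantile == 10)
  expect_equal(top$fraction, 1)
  expect_equal(qd$above_median$fraction_above_median[10], 1)
  # independence: cells hover near 1/n_quantiles
  set.seed(604)
  ind <- tibble::tibble(promoter_id = sprintf("g%04d", 1:5000),
                        occupancy = rnorm(5000), expression = rnorm(5000))
  qi <- quantile_distribution(ind)
  expect_lt(max(abs(qi$table$fraction - 0.1)), 0.08)
})

test_that("ks_boot statistic matches the classical D and handles edge cases", {
  x <- c(1, 2, 3, 4, 5)
  same <- ks_boot(x, x, n_boot = 100, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disj <- ks_boot(0:9, 100:109, n_boot = 100, seed = 1)
  expect_equal(disj$statistic, 1)
  expect_lt(disj$p_value, 0.05)
  expect_error(ks_boot(numeric(0), x), "non-empty")
  # D agrees with the reference implementation on random continuous samples
  set.seed(605)
  for (i in 1:25) {
    a <- rnorm(40)
    b <- rnorm(35, mean = runif(1, -1, 1))
    D_ref <- unname(suppressWarnings(stats::ks.test(a, b)$statistic))
    expect_equal(ks_boot(a, b, n_boot = 100, seed = i)$statistic, D_ref)
  }
})

test_that("ks_boot p-values are approximately uniform under the null", {
  # D lives on a lattice of width ~1/n, so near-uniformity of the bootstrap
  # p-value needs samples large enough for the lattice to be fine; n = 100
  # per group keeps the discretization below the resolution of a 200-draw
  # uniformity check
  set.seed(606)
  pvals <- vapply(1:200, function(i) {
    a <- rnorm(100)
    b <- rnorm(100)
    ks_boot(a, b, n_boot = 500)$p_value
  }, numeric(1))
  unif <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(unif$p.value, 0.01)
})

test_that("rank-sum test on positions detects separation and ignores shifts", {
  set.seed(607)
  a <- sample(-300:300, 50, replace = TRUE)
  near_id <- ranksum_positions(a, a)
  expect_gt(near_id$p_value, 0.9)
  sep <- ranksum_positions(a, a + 1000L)
  expect_lt(sep$p_value, 1e-10)
  shifted <- ranksum_positions(a + 137L, a + 1000L + 137L)
  expect_equal(sep$p_value, shifted$p_value)
  expect_equal(sep$statistic, shifted$statistic)
})

test_that("ratio curve equals one for identical tracks and is shift-invariant", {
  d <- gene_table(400, seed = 608)
  d$nc2 <- d$tfiib
  rc <- ratio_curve(d)
  expect_true(all(abs(rc$ratio - 1) < 1e-12))
  d2 <- gene_table(400, noise = 0.3, seed = 609)
  rc_a <- ratio_curve(d2)
  d3 <- dplyr::mutate(d2, tfiib = tfiib + 2.5, nc2 = nc2 + 2.5)
  rc_b <- ratio_curve(d3)
  expect_equal(rc_a$ratio, rc_b$ratio, tolerance = 1e-12)
  expect_error(ratio_curve(d2, bin_pct = 7), "divide")
})

test_that("ratio curve rises toward the most highly expressed genes", {
  d <- gene_table(2000, coupling = 1, noise = 0.3, seed = 610, rho = 0.8)
  rc <- ratio_curve(d, bin_pct = 5)
  mid <- mean(rc$ratio[rc$pct_hi >= 45 & rc$pct_hi <= 55])
  expect_gt(rc$ratio[rc$pct_hi == 100], mid)
  expect_gt(rc$ratio[rc$pct_hi == 95], mid)
})

test_that("dominated-set selection ranks per-gene linear ratios", {
  d <- tibble::tibble(
    promoter_id = c("g1", "g2", "g3", "g4", "g5"),
    tfiib = c(3, 2, 1, 0, 2),
    nc2 = c(0, 1, 2, 3, 2),
    expression = c(1, 2, 3, 4, 5))
  sel <- select_dominated(d, cutoff_pct = 0, top_n = 2)
  # ratios: g1=8, g2=2, g3=0.5, g4=0.125, g5=1
  expect_equal(sel$tfiib_dominated, c("g1", "g2"))
  expect_equal(sel$nc2_dominated, c("g4", "g3"))
  expect_equal(sel$eligible_n, 5)
  # equal ratios break ties by promoter id
  tied <- dplyr::mutate(d, tfiib = 1, nc2 = 1)
  sel_t <- select_dominated(tied, cutoff_pct = 0, top_n = 2)
  expect_equal(sel_t$tfiib_dominated, c("g1", "g2"))
  expect_equal(sel_t$nc2_dominated, c("g1", "g2"))
  expect_error(select_dominated(d, cutoff_pct = 0, top_n = 10), "eligible")
})

test_that("dominated sets are disjoint when top_n <= eligible / 2", {
  set.seed(611)
  d <- gene_table(300, noise = 0.4, seed = 611)
  sel <- select_dominated(d, cutoff_pct = 60, top_n = 10)
  expect_length(intersect(sel$tfiib_dominated, sel$nc2_dominated), 0)
  expect_length(sel$tfiib_dominated, 10)
})

test_that("TSS shape classification follows the four-way rules", {
  one <- tibble::tibble(promoter_id = "p", offset = 0L, count = 50L)
  expect_equal(classify_tss_shape(one)$class4, "single")
  expect_equal(classify_tss_shape(one)$class2, "focused")
  two_far <- tibble::tibble(promoter_id = "p", offset = c(0L, 100L),
                            count = c(25L, 25L))
  cls <- classify_tss_shape(two_far)
  expect_equal(cls$class4, "multimodal")
  expect_equal(cls$class2, "dispersed")
  dom <- tibble::tibble(promoter_id = "p", offset = c(0L, 40L, 80L),
                        count = c(60L, 20L, 20L))
  expect_equal(classify_tss_shape(dom)$class4, "dominant")
  broad <- tibble::tibble(promoter_id = "p", offset = seq(0L, 90L, 10L),
                          count = rep(3L, 10))
  expect_equal(classify_tss_shape(broad)$class4, "broad")
  # invariance under uniform translation
  for (shift in c(-500L, 137L)) {
    shifted <- dplyr::mutate(two_far, offset = offset + shift)
    expect_equal(classify_tss_shape(shifted)$class4, "multimodal")
  }
  expect_error(classify_shape_one(integer(0), integer(0)), "empty")
})

test_that("mean_tags averages per-promoter totals over selected ids", {
  tags <- tibble::tibble(promoter_id = rep(c("a", "b", "c"), each = 2),
                         offset = rep(c(0L, 5L), 3),
                         count = c(50L, 50L, 100L, 100L, 150L, 150L))
  expect_equal(mean_tags(tags), 200)
  expect_equal(mean_tags(tags, ids = c("a", "c")), 200)
  expect_equal(mean_tags(tags, ids = "b"), 200)
  expect_equal(mean_tags(tags, ids = "a"), 100)
  expect_error(mean_tags(tags, ids = character(0)), "non-empty")
})
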