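# Random valid blueprint: subsets of promoters per class with the planting
# implications (tata => tata_like, breu => breu_like) made explicit.
random_blueprint <- function(n = 40, seed = 1) {
  set.seed(seed)
  pick <- function(k) sort(sample.int(n, k))
  tata <- pick(sample(0:8, 1))
  tata_like <- sort(union(tata, pick(sample(0:10, 1))))
  breu <- pick(sample(0:4, 1))
  breu_like <- sort(union(breu, pick(sample(0:6, 1))))
  inr <- pick(sample(0:8, 1))
  dpe <- pick(sample(0:6, 1))
  mt <- dplyr::bind_rows(
    if (length(tata)) tibble::tibble(promoter = tata, class = "tata"),
    if (length(tata_like)) tibble::tibble(promoter = tata_like, class = "tata_like"),
    if (length(breu)) tibble::tibble(promoter = breu, class = "breu"),
    if (length(breu_like)) tibble::tibble(promoter = breu_like, class = "breu_like"),
    if (length(inr)) tibble::tibble(promoter = inr, class = "inr"),
    if (length(dpe)) tibble::tibble(promoter = dpe, class = "dpe")
  )
  cohort_blueprint(n_promoters = n, background_gc = runif(1, 0.4, 0.65),
                   motif_table = mt, seed = seed + 1000L)
}

test_that("identical blueprint and seed give byte-identical cohorts", {
  bp <- load_preset("top100", seed = 99)
  c1 <- generate_cohort(bp)
  c2 <- generate_cohort(bp)
  expect_identical(c1, c2)
  c3 <- generate_cohort(load_preset("top100", seed = 100))
  expect_false(identical(c1$promoters$core_seq, c3$promoters$core_seq))
})

test_that("zero-planting fixture cohorts scan clean for all seven classes", {
  bp <- cohort_blueprint(n_promoters = 50, background_gc = 0.45, seed = 17)
  cohort <- generate_cohort(bp, mode = "fixture")
  freq <- motif_frequency(scan_promoters(cohort$promoters))
  expect_true(all(freq$count == 0))
})

test_that("fixture round-trip: scanner counts equal planted counts", {
  for (s in c(11, 22, 33, 44, 55)) {
    bp <- random_blueprint(n = 40, seed = s)
    cohort <- generate_cohort(bp, mode = "fixture")
    wide <- annotation_wide(scan_promoters(cohort$promoters))
    planted <- table(factor(bp$motif_table$class, levels = MOTIF_CLASSES))
    for (cl in MOTIF_CLASSES) {
      expect_equal(sum(wide[[cl]]), unname(planted[cl]),
                   label = paste("class", cl, "seed", s),
                   ignore_attr = TRUE)
    }
  }
})

test_that("implication closure holds in generated cohorts", {
  for (s in c(7, 8)) {
    cohort <- generate_cohort(random_blueprint(n = 30, seed = s))
    wide <- annotation_wide(scan_promoters(cohort$promoters))
    expect_true(all(!wide$tata | wide$tata_like))
    expect_true(all(!wide$breu | wide$breu_like))
  }
})

test_that("blueprint validation names the violated implication", {
  expect_error(
    cohort_blueprint(n_promoters = 10,
                     motif_table = tibble::tibble(promoter = 1, class = "tata")),
    "TATA => TATA-like")
  expect_error(
    cohort_blueprint(n_promoters = 10,
                     motif_table = tibble::tibble(promoter = 2, class = "breu")),
    "BREu => BREu-like")
  expect_error(
    cohort_blueprint(n_promoters = 10,
                     motif_table = tibble::tibble(promoter = 3, class = "bred")),
    "BREd requires TATA")
  expect_error(
    cohort_blueprint(n_promoters = 10,
                     motif_table = tibble::tibble(promoter = 1,
                                                  class = c("tata", "tata_like"),
                                                  anchor = c(-45L, NA))),
    "legal scan window")
  expect_error(
    cohort_blueprint(n_promoters = 5,
                     motif_table = tibble::tibble(promoter = 9, class = "inr")),
    "outside 1..n_promoters")
})

test_that("unknown presets are rejected with the list of valid names", {
  expect_error(load_preset("nope"), "top100")
  expect_error(load_preset("nope"), "profile_minus50")
})

test_that("shipped presets reproduce their documented compositions", {
  want <- list(
    top100 = c(tata = 24, tata_like = 66, breu = 3, breu_like = 17,
               bred = 0, inr = 17, dpe = 0),
    high_tfiib = c(tata = 5, tata_like = 29, breu = 3, breu_like = 19,
                   bred = 0, inr = 12, dpe = 0),
    low_tfiib = c(tata = 1, tata_like = 20, breu = 3, breu_like = 21,
                  bred = 0, inr = 10, dpe = 0),
    nc2_dominated = c(tata = 1, tata_like = 16, breu = 1, breu_like = 12,
                      bred = 0, inr = 13, dpe = 1)
  )
  for (nm in names(want)) {
    cohort <- generate_cohort(load_preset(nm, seed = 5))
    freq <- motif_frequency(scan_promoters(cohort$promoters))
    got <- setNames(freq$count[match(MOTIF_CLASSES, freq$class)], MOTIF_CLASSES)
    expect_equal(got, want[[nm]], label = nm, ignore_attr = TRUE)
  }
})

test_that("lower replicate noise strictly increases replicate correlation", {
  mean_r <- function(noise) {
    rs <- vapply(1:4, function(s) {
      bp <- cohort_blueprint(n_promoters = 80, replicate_noise = noise,
                             seed = 600 + s)
      scores <- promoter_scores(scale_signals(generate_cohort(bp)$signals))
      w <- tidyr::pivot_wider(
        dplyr::filter(scores, factor == "tfiib"),
        names_from = "replicate", values_from = "score", names_prefix = "r")
      cor(w$r1, w$r2)
    }, numeric(1))
    mean(rs)
  }
  r_hi <- mean_r(1.5)
  r_mid <- mean_r(0.5)
  r_lo <- mean_r(0.1)
  expect_lt(r_hi, r_mid)
  expect_lt(r_mid, r_lo)
})

test_that("background GC calibration recovers the target cohort GC", {
  bp <- load_preset("high_tfiib", seed = 31)
  big <- cohort_blueprint(
    n_promoters = 300, background_gc = bp$background_gc,
    motif_table = dplyr::bind_rows(lapply(0:2, function(k) {
      dplyr::mutate(bp$motif_table, promoter = promoter + 100L * k)
    })),
    seed = 31)
  cohort <- generate_cohort(big, mode = "sampling")
  expect_lt(abs(gc_content(cohort$promoters) - 0.61), 0.02)
})

test_that("tag vectors realize the blueprint's TSS shape labels", {
  n <- 60
  shapes <- tibble::tibble(promoter = 1:n,
                           shape = rep(c("focused", "dispersed"), n / 2))
  bp <- cohort_blueprint(n_promoters = n, tss_shape_table = shapes,
                         tag_mean = 500, seed = 77)
  cohort <- generate_cohort(bp)
  cls <- classify_tss_shape(cohort$cage_tags) %>%
    dplyr::inner_join(cohort$tss_shapes, by = "promoter_id")
  focused_ok <- mean(cls$class2[cls$shape == "focused"] == "focused")
  dispersed_ok <- mean(cls$class2[cls$shape == "dispersed"] == "dispersed")
  expect_gte(focused_ok, 0.95)
  expect_gte(dispersed_ok, 0.95)
  # tag depth is recovered within sampling error
  expect_lt(abs(mean_tags(cohort$cage_tags) - 500) / 500, 0.05)
})

test_that("signals carry 15 probes per promoter per factor and replicate", {
  cohort <- generate_cohort(cohort_blueprint(n_promoters = 12, seed = 3))
  cnt <- dplyr::count(cohort$signals, promoter_id, factor, replicate)
  expect_true(all(cnt$n == 15))
  expect_equal(nrow(cnt), 12 * 2 * 2)
  expect_true(all(sort(unique(cohort$signals$offset)) == probe_offsets()))
})

test_that("promoter scores increase with planted occupancy", {
  # wide footprint so most of the 15 probes carry occupancy signal, making
  # the probeset median a low-noise readout of the planted enrichment
  bp <- cohort_blueprint(n_promoters = 200, seed = 91,
                         footprint = list(center = -50, spread = 400,
                                          baseline = 0, probe_noise = 0.1),
                         replicate_noise = 0.1)
  cohort <- generate_cohort(bp)
  scores <- promoter_scores(scale_signals(cohort$signals)) %>%
    dplyr::filter(factor == "tfiib") %>%
    dplyr::group_by(promoter_id) %>%
    dplyr::summarise(score = mean(score), .groups = "drop") %>%
    dplyr::inner_join(
      dplyr::filter(cohort$occupancy, factor == "tfiib"), by = "promoter_id")
  expect_gt(cor(scores$score, scores$log2_enrichment), 0.9)
})

test_that("blueprints survive a YAML round trip", {
  bp <- load_preset("tfiib_dominated", seed = 13)
  path <- tempfile(fileext = ".yaml")
  write_blueprint(bp, path)
  bp2 <- read_blueprint(path)
  expect_equal(bp2$n_promoters, bp$n_promoters)
  expect_equal(bp2$background_gc, bp$background_gc)
  expect_equal(dplyr::arrange(bp2$motif_table, promoter, class),
               dplyr::arrange(bp$motif_table, promoter, class))
  expect_identical(generate_cohort(bp2)$promoters,
                   generate_cohort(bp)$promoters)
})

test_that("cohort export produces well-formed plain-text files", {
  cohort <- generate_cohort(cohort_blueprint(n_promoters = 8, seed = 21))
  dir <- tempfile()
  write_cohort(cohort, dir)
  expect_setequal(list.files(dir),
                  c("promoters.fasta", "tss.bed", "probe_signals.tsv",
                    "expression.tsv", "cage_tags.tsv"))
  prom <- read_promoters(file.path(dir, "promoters.fasta"))
  expect_equal(prom$promoter_id, cohort$promoters$promoter_id)
  expect_equal(prom$core_seq, cohort$promoters$core_seq)
  sig <- read_probe_signals(file.path(dir, "probe_signals.tsv"))
  expect_equal(nrow(sig), nrow(cohort$signals))
})
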