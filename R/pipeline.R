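# End-to-end pipeline: generation -> scaling -> scoring -> scanning ->
# statistics -> text reports.

CONFIG_FIELDS <- c("preset", "blueprint", "out_dir", "seed", "mode",
                   "top_pct", "top_pct_wide", "cutoff_pct", "bin_pct",
                   "peak_k", "min_run", "n_boot", "step", "top_n")

#' Build and validate a pipeline configuration
#'
#' @param preset Preset name (see [load_preset()]); alternatively `blueprint`.
#' @param blueprint Path to a YAML blueprint (used when `preset` is `NULL`).
#' @param out_dir Output directory for reports.
#' @param seed Integer seed driving all pipeline randomness.
#' @param mode Cohort generation mode, `"fixture"` or `"sampling"`.
#' @param top_pct Top-percentile width for high-score probes/promoters.
#' @param top_pct_wide Wider percentile for the concordance reference set.
#' @param cutoff_pct Eligibility percentile for dominated-set selection.
#' @param bin_pct Expression bin width for the ratio curve; must divide 100.
#' @param peak_k Stringency multipliers for peak calling.
#' @param min_run Minimum probes per peak run.
#' @param n_boot Bootstrap replicates for the KS test.
#' @param step Sliding-window step on the occupancy scale.
#' @param top_n Dominated-set size.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "top100", blueprint = NULL,
                            out_dir = tempfile("corepic_"), seed = 1L,
                            mode = "fixture", top_pct = 5, top_pct_wide = 10,
                            cutoff_pct = 60, bin_pct = 5,
                            peak_k = c(1, 2, 2.5), min_run = 2,
                            n_boot = 200, step = 0.1, top_n = 10) {
  cfg <- list(preset = preset, blueprint = blueprint, out_dir = out_dir,
              seed = as.integer(seed), mode = mode, top_pct = top_pct,
              top_pct_wide = top_pct_wide, cutoff_pct = cutoff_pct,
              bin_pct = bin_pct, peak_k = peak_k, min_run = min_run,
              n_boot = n_boot, step = step, top_n = top_n)
  validate_config(cfg)
}

#' Validate a pipeline configuration list
#'
#' @param cfg Named list (e.g. from [yaml::read_yaml()]); unknown keys are
#'   rejected and numeric fields are range-checked.
#' @return The validated config with class `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), CONFIG_FIELDS)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$preset) && is.null(cfg$blueprint)) {
    abort("config must name a `preset` or a `blueprint` path")
  }
  if (!is.null(cfg$preset) && !(cfg$preset %in% PRESET_NAMES)) {
    abort(paste0("unknown preset '", cfg$preset, "'; valid presets: ",
                 paste(PRESET_NAMES, collapse = ", ")))
  }
  if (!cfg$mode %in% c("fixture", "sampling")) {
    abort("mode must be 'fixture' or 'sampling'")
  }
  if (100 %% cfg$bin_pct != 0) abort("bin_pct must divide 100")
  stopifnot(cfg$top_pct > 0, cfg$top_pct < 100,
            cfg$top_pct_wide >= cfg$top_pct, cfg$top_pct_wide < 100,
            cfg$cutoff_pct >= 0, cfg$cutoff_pct < 100,
            all(cfg$peak_k > 0), cfg$min_run >= 1, cfg$n_boot >= 100,
            cfg$step > 0, cfg$top_n >= 1)
  structure(cfg, class = "pipeline_config")
}

#' Build the per-gene occupancy/expression table of a cohort
#'
#' Joins replicate-averaged promoter scores of both factors with the
#' expression table.
#'
#' @param cohort A `synthetic_cohort`.
#' @param scores Promoter scores from [promoter_scores()]; computed from the
#'   cohort's scaled signals when omitted.
#' @return Tibble with `promoter_id`, `tfiib`, `nc2`, `expression`, `present`.
#' @export
cohort_gene_table <- function(cohort, scores = NULL) {
  if (is.null(scores)) {
    scores <- promoter_scores(scale_signals(cohort$signals))
  }
  wide <- scores %>%
    group_by(.data$promoter_id, .data$factor) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "factor", values_from = "score")
  wide %>%
    inner_join(rename(cohort$expression, expression = "signal"),
               by = "promoter_id")
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, exports it, scales and scores the probe
#' signals, calls peaks at every configured stringency, builds the TSS
#' binding profile, scans motifs, and computes frequency, combination,
#' co-occurrence, concordance, ratio-curve, dominated-set, KS and TSS-shape
#' reports. All outputs are plain-text tables under `cfg$out_dir`; the run is
#' deterministic given the config seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with all intermediate results.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  bp <- stage("blueprint", {
    if (!is.null(cfg$preset)) load_preset(cfg$preset, seed = cfg$seed)
    else read_blueprint(cfg$blueprint)
  })
  cohort <- stage("generate", generate_cohort(bp, mode = cfg$mode))
  stage("export", write_cohort(cohort, file.path(cfg$out_dir, "cohort")))

  scaled <- stage("scale", scale_signals(cohort$signals))
  scores <- stage("score", promoter_scores(scaled))
  readr::write_tsv(scores, file.path(cfg$out_dir, "promoter_scores.tsv"))

  peaks <- stage("peaks", bind_rows(lapply(cfg$peak_k, function(k) {
    call_promoter_peaks(scaled, k = k, min_run = cfg$min_run)
  })))
  readr::write_tsv(peaks, file.path(cfg$out_dir, "peaks.tsv"))

  tfiib1 <- filter(scaled, .data$factor == "tfiib", .data$replicate == 1)
  profile <- stage("profile", build_profile(
    top_percentile_probes(tfiib1, pct = cfg$top_pct),
    tfiib1))
  readr::write_tsv(profile, file.path(cfg$out_dir, "binding_profile.tsv"))

  annotations <- stage("scan", scan_promoters(cohort$promoters))
  readr::write_tsv(annotations, file.path(cfg$out_dir, "annotations.tsv"))
  freq <- motif_frequency(annotations)
  readr::write_tsv(freq, file.path(cfg$out_dir, "motif_frequency.tsv"))

  combos <- stage("cooccur", combination_counts(annotations))
  readr::write_tsv(combos$size_counts,
                   file.path(cfg$out_dir, "combination_sizes.tsv"))
  readr::write_tsv(combos$pair_counts,
                   file.path(cfg$out_dir, "pair_counts.tsv"))

  conc <- stage("concordance", {
    rep_scores <- scores %>%
      filter(.data$factor == "tfiib") %>%
      tidyr::pivot_wider(names_from = "replicate", values_from = "score",
                         names_prefix = "rep")
    replicate_concordance(rep_scores, "rep1", "rep2",
                          top_pct_a = cfg$top_pct,
                          top_pct_b = cfg$top_pct_wide)
  })

  genes <- stage("gene_table", cohort_gene_table(cohort, scores))
  rc <- stage("ratio", ratio_curve(genes, bin_pct = cfg$bin_pct))
  readr::write_tsv(rc, file.path(cfg$out_dir, "ratio_curve.tsv"))

  dom <- stage("dominate", select_dominated(
    genes, cutoff_pct = cfg$cutoff_pct, top_n = cfg$top_n))
  readr::write_tsv(tibble(promoter_id = dom$tfiib_dominated),
                   file.path(cfg$out_dir, "tfiib_dominated.tsv"))
  readr::write_tsv(tibble(promoter_id = dom$nc2_dominated),
                   file.path(cfg$out_dir, "nc2_dominated.tsv"))

  ks <- stage("ks", {
    gene_tab <- drop_absent(genes)
    thr <- quantile(gene_tab$tfiib, 0.9, names = FALSE)
    top <- gene_tab[gene_tab$tfiib >= thr, , drop = FALSE]
    ks_boot(top$expression, gene_tab$expression, n_boot = cfg$n_boot,
            seed = cfg$seed + 1L)
  })

  shapes <- stage("shapes", classify_tss_shape(cohort$cage_tags))
  readr::write_tsv(shapes, file.path(cfg$out_dir, "tss_shapes.tsv"))

  stage("summary", {
    lines <- c(
      "corepic pipeline summary",
      paste0("package version: ",
             as.character(utils::packageVersion("corepic"))),
      paste0("preset: ", cfg$preset %||% cfg$blueprint),
      paste0("seed: ", cfg$seed, "  mode: ", cfg$mode),
      paste0("promoters: ", nrow(cohort$promoters)),
      "",
      "motif counts:",
      paste0("  ", freq$class, ": ", freq$count,
             " (", round(freq$percent, 1), "%)"),
      "",
      "combination sizes (collapsed classes):",
      paste0("  ", combos$size_counts$size, ": ", combos$size_counts$count),
      "",
      sprintf("replicate concordance: r = %.4f, overlap = %.4f",
              conc$pearson_r, conc$overlap_fraction),
      sprintf("KS (top-decile TFIIB expression vs all): D = %.4f, p = %.4g",
              ks$statistic, ks$p_value),
      sprintf("ratio curve, top bin (%d-%d): %.4f",
              max(rc$pct_lo), max(rc$pct_hi), rc$ratio[which.max(rc$bin)]),
      sprintf("focused TSS fraction: %.3f",
              mean(shapes$class2 == "focused")),
      sprintf("mean tags per promoter: %.1f", mean_tags(cohort$cage_tags))
    )
    writeLines(lines, file.path(cfg$out_dir, "summary.txt"))
  })

  invisible(list(blueprint = bp, cohort = cohort, scaled = scaled,
                 scores = scores, peaks = peaks, profile = profile,
                 annotations = annotations, frequency = freq,
                 combinations = combos, concordance = conc, genes = genes,
                 ratio_curve = rc, dominated = dom, ks = ks,
                 shapes = shapes, config = cfg))
}
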