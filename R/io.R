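# Text-first input/output: FASTA core sequences, BED6 TSS annotation, TSV
# signal/expression/tag tables, YAML blueprints. Column orders are fixed so
# pipeline outputs diff cleanly.

write_fasta <- function(ids, seqs, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, filepath = path)
  } else {
    writeLines(paste0(">", ids, "\n", seqs), path)
  }
  invisible(path)
}

read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    tibble(header = names(x), seq = unname(as.character(x)))
  } else {
    lines <- readLines(path)
    heads <- grep("^>", lines)
    ends <- c(heads[-1] - 1L, length(lines))
    tibble(
      header = sub("^>", "", lines[heads]),
      seq = vapply(seq_along(heads), function(i) {
        paste(lines[(heads[i] + 1L):ends[i]], collapse = "")
      }, character(1))
    )
  }
}

#' Export a synthetic cohort as plain-text files
#'
#' Writes the cohort to `dir`: `promoters.fasta` (core sequences, header
#' `promoter_id|strand`), `tss.bed` (BED6, synthetic coordinates with one
#' promoter per 10-kb slot, 0-based half-open), `probe_signals.tsv`,
#' `expression.tsv` and `cage_tags.tsv`.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$promoters
  write_fasta(paste0(p$promoter_id, "|", p$strand), p$core_seq,
              file.path(dir, "promoters.fasta"))
  tss <- 10000L * seq_len(nrow(p))
  bed <- tibble(chrom = "chrS", start = tss - 1L, end = tss,
                name = p$promoter_id, score = 0L, strand = p$strand)
  readr::write_tsv(bed, file.path(dir, "tss.bed"), col_names = FALSE)
  readr::write_tsv(
    select(cohort$signals, all_of(c("promoter_id", "probe_index", "offset",
                                    "factor", "replicate", "log2_ratio"))),
    file.path(dir, "probe_signals.tsv"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(cohort$cage_tags, file.path(dir, "cage_tags.tsv"))
  invisible(dir)
}

#' Read an exported promoter FASTA back into a promoter table
#'
#' @param path FASTA written by [write_cohort()] (header `promoter_id|strand`).
#' @return Tibble with `promoter_id`, `strand`, `core_seq`.
#' @export
read_promoters <- function(path) {
  fa <- read_fasta(path)
  parts <- strsplit(fa$header, "|", fixed = TRUE)
  tibble(
    promoter_id = vapply(parts, `[`, character(1), 1),
    strand = vapply(parts, function(x) if (length(x) > 1) x[2] else "+",
                    character(1)),
    core_seq = fa$seq
  )
}

#' Read a probe-signal TSV
#' @param path TSV written by [write_cohort()].
#' @return Tibble in the probe-signal schema.
#' @export
read_probe_signals <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    promoter_id = readr::col_character(),
    probe_index = readr::col_integer(),
    offset = readr::col_integer(),
    factor = readr::col_character(),
    replicate = readr::col_integer(),
    log2_ratio = readr::col_double()
  ))
}

#' Serialize a cohort blueprint to YAML
#'
#' @param bp A [cohort_blueprint()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_blueprint <- function(bp, path) {
  stopifnot(inherits(bp, "cohort_blueprint"))
  obj <- unclass(bp)
  obj$motif_table <- lapply(seq_len(nrow(bp$motif_table)), function(i) {
    r <- as.list(bp$motif_table[i, ])
    if (is.na(r$anchor)) r$anchor <- NULL
    r
  })
  obj$tss_shape_table <- lapply(seq_len(nrow(bp$tss_shape_table)),
                                function(i) as.list(bp$tss_shape_table[i, ]))
  obj$occupancy_model$location <- as.list(obj$occupancy_model$location)
  obj$occupancy_model$spread <- as.list(obj$occupancy_model$spread)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a cohort blueprint from YAML
#'
#' @param path YAML file written by [write_blueprint()].
#' @return A validated [cohort_blueprint()].
#' @export
read_blueprint <- function(path) {
  obj <- yaml::read_yaml(path)
  mt <- bind_rows(lapply(obj$motif_table, function(r) {
    tibble(promoter = as.integer(r$promoter), class = r$class,
           anchor = if (is.null(r$anchor)) NA_integer_ else as.integer(r$anchor))
  }))
  if (is.null(mt) || nrow(mt) == 0) mt <- NULL
  shp <- bind_rows(lapply(obj$tss_shape_table, function(r) {
    tibble(promoter = as.integer(r$promoter), shape = r$shape)
  }))
  om <- obj$occupancy_model
  om$location <- unlist(om$location)
  om$spread <- unlist(om$spread)
  cohort_blueprint(
    n_promoters = obj$n_promoters,
    background_gc = obj$background_gc,
    motif_table = mt,
    occupancy_model = om,
    expression_model = obj$expression_model,
    footprint = obj$footprint,
    replicate_noise = obj$replicate_noise,
    tss_shape_table = shp,
    tag_mean = obj$tag_mean,
    seed = obj$seed
  )
}

#' Validate pipeline input files
#'
#' Schema checks for exported cohort files: FASTA records must be 100-base
#' A/C/G/T sequences; the probe table must hold exactly 15 probes per
#' promoter per factor/replicate; expression and tag tables must join to the
#' FASTA promoter ids (orphans are reported).
#'
#' @param paths Named list/vector with any of `fasta`, `probes`,
#'   `expression`, `tags`.
#' @return Tibble with `file`, `check`, `pass`, `detail` (first offending
#'   record, if any).
#' @export
validate_inputs <- function(paths) {
  paths <- as.list(paths)
  out <- list()
  add <- function(file, check, pass, detail = "") {
    out[[length(out) + 1L]] <<- tibble(file = file, check = check,
                                       pass = pass, detail = detail)
  }
  ids <- NULL
  if (!is.null(paths$fasta)) {
    if (!file.exists(paths$fasta)) {
      add("fasta", "readable", FALSE, paths$fasta)
    } else {
      prom <- read_promoters(paths$fasta)
      ids <- prom$promoter_id
      len_ok <- nchar(prom$core_seq) == 100L
      add("fasta", "sequences are 100 bases", all(len_ok),
          if (!all(len_ok)) paste0("record '", prom$promoter_id[!len_ok][1],
                                   "' has ", nchar(prom$core_seq[!len_ok][1]),
                                   " bases") else "")
      ab_ok <- grepl("^[ACGTacgt]+$", prom$core_seq)
      add("fasta", "alphabet is A/C/G/T", all(ab_ok),
          if (!all(ab_ok)) prom$promoter_id[!ab_ok][1] else "")
    }
  }
  if (!is.null(paths$probes)) {
    if (!file.exists(paths$probes)) {
      add("probes", "readable", FALSE, paths$probes)
    } else {
      sig <- read_probe_signals(paths$probes)
      cnt <- count(sig, .data$promoter_id, .data$factor, .data$replicate)
      bad <- filter(cnt, n != 15L)
      add("probes", "15 probes per promoter per array", nrow(bad) == 0,
          if (nrow(bad) > 0) paste0("promoter '", bad$promoter_id[1], "' has ",
                                    bad$n[1], " probes") else "")
      if (!is.null(ids)) {
        orphan <- setdiff(unique(sig$promoter_id), ids)
        add("probes", "promoter ids join to FASTA", length(orphan) == 0,
            if (length(orphan) > 0) paste0("orphan id '", orphan[1], "'")
            else "")
      }
    }
  }
  join_check <- function(label, path, id_col = "promoter_id") {
    if (!file.exists(path)) {
      add(label, "readable", FALSE, path)
      return(invisible())
    }
    tab <- readr::read_tsv(path, col_types = readr::cols())
    add(label, "has promoter_id column", id_col %in% names(tab),
        if (!id_col %in% names(tab)) paste(names(tab), collapse = ",") else "")
    if (id_col %in% names(tab) && !is.null(ids)) {
      orphan <- setdiff(unique(tab[[id_col]]), ids)
      add(label, "promoter ids join to FASTA", length(orphan) == 0,
          if (length(orphan) > 0) paste0("orphan id '", orphan[1], "'") else "")
    }
  }
  if (!is.null(paths$expression)) join_check("expression", paths$expression)
  if (!is.null(paths$tags)) join_check("tags", paths$tags)
  bind_rows(out)
}
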