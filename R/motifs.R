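# TSS-anchored IUPAC scanning for core promoter elements.
#
# Seven classes are scanned on the transcribed strand of the 100-base core
# sequence (-50..+50, no position 0):
#
#   tata       TATAW, first T fixed at -31 (an optional +/-w anchor tolerance
#              exists, default 0)
#   tata_like  any WWWW run lying fully inside [-40, -20]
#   breu       SRCGCC occupying [-37, -32] (immediately upstream of the
#              canonical TATA location), exact match
#   breu_like  as breu but allowing one mismatch
#   bred       RTDKKKK occupying [-25, -19], evaluated only in promoters that
#              carry a TATA consensus (the element is defined relative to TATA)
#   inr        YYANWY with the central A anywhere in [-4, +5]
#   dpe        RGWYVT starting anywhere in [+28, +32]
#
# Presence/absence semantics: overlapping hits of one class count once per
# promoter; the leftmost hit anchor is reported.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

MOTIF_CLASSES <- c("tata", "tata_like", "breu", "breu_like", "bred", "inr", "dpe")

iupac_sets <- function(pattern) {
  codes <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(codes, names(IUPAC))
  if (length(bad) > 0) {
    abort(paste0("non-IUPAC symbol(s) in pattern: ", paste(bad, collapse = ", ")))
  }
  IUPAC[codes]
}

# GC weight of an IUPAC code when a base is drawn uniformly from its allowed
# set; used for the background-GC calibration of presets.
iupac_gc_fraction <- function(pattern) {
  sets <- iupac_sets(pattern)
  vapply(sets, function(s) mean(s %in% c("C", "G")), numeric(1))
}

#' Match a sequence against an IUPAC pattern with mismatches
#'
#' Compares a base string to an equal-length IUPAC degenerate pattern. A
#' position mismatches when the observed base is not in the pattern code's
#' allowed set.
#'
#' @param seq Base string (A/C/G/T), same length as `pattern`.
#' @param pattern IUPAC pattern string.
#' @param max_mismatch Maximum number of mismatching positions tolerated.
#' @return A list with `matched` (logical) and `mismatches` (integer count).
#' @examples
#' iupac_match("TATAA", "TATAW", 0)
#' iupac_match("TCTAA", "TATAW", 1)
#' @export
iupac_match <- function(seq, pattern, max_mismatch = 0) {
  seq <- toupper(seq)
  if (nchar(seq) != nchar(pattern)) {
    abort("`seq` and `pattern` must have equal length")
  }
  sets <- iupac_sets(pattern)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    abort("`seq` must contain only A/C/G/T")
  }
  mm <- sum(!mapply(function(ch, set) ch %in% set, chars, sets))
  list(matched = mm <= max_mismatch, mismatches = as.integer(mm))
}

# Internal fast mismatch count on a character vector slice.
mm_at <- function(chars, idx, sets) {
  mm <- 0L
  for (k in seq_along(idx)) {
    if (!(chars[idx[k]] %in% sets[[k]])) mm <- mm + 1L
  }
  mm
}

#' Core promoter motif definitions
#'
#' Returns the scanning rules for the seven motif classes as a named list.
#' Fields can be overridden (patterns, windows, mismatch allowances, TATA
#' anchor tolerance) to explore alternative definitions; defaults encode the
#' field-standard consensus sequences and windows.
#'
#' @param tata_tolerance Anchor tolerance (bp) around -31 for the TATA scan;
#'   default 0 (fixed anchor).
#' @param bred_max_mismatch Mismatch allowance for the BREd scan; default 0
#'   (a relaxed one-mismatch mode can be requested).
#' @param overrides Named list of per-class overrides merged into the defaults.
#' @return Named list of class definitions.
#' @export
motif_defs <- function(tata_tolerance = 0L, bred_max_mismatch = 0L,
                       overrides = list()) {
  defs <- list(
    tata      = list(pattern = "TATAW", anchor = -31L,
                     tolerance = as.integer(tata_tolerance), max_mismatch = 0L),
    tata_like = list(pattern = "WWWW", window = c(-40L, -20L), max_mismatch = 0L),
    breu      = list(pattern = "SRCGCC", start = -37L, max_mismatch = 0L),
    breu_like = list(pattern = "SRCGCC", start = -37L, max_mismatch = 1L),
    bred      = list(pattern = "RTDKKKK", start = -25L,
                     max_mismatch = as.integer(bred_max_mismatch),
                     requires_tata = TRUE),
    inr       = list(pattern = "YYANWY", a_index = 3L, a_window = c(-4L, 5L),
                     max_mismatch = 0L),
    dpe       = list(pattern = "RGWYVT", start_window = c(28L, 32L),
                     max_mismatch = 0L)
  )
  for (nm in names(overrides)) {
    if (!nm %in% names(defs)) abort(paste0("unknown motif class: ", nm))
    defs[[nm]] <- modifyList(defs[[nm]], overrides[[nm]])
  }
  defs
}

# Legal anchor positions (promoter coordinates, skipping 0) for a class.
legal_anchors <- function(class, defs = motif_defs()) {
  d <- defs[[class]]
  drop0 <- function(p) p[p != 0L]
  switch(class,
    tata = drop0(seq.int(d$anchor - d$tolerance, d$anchor + d$tolerance)),
    tata_like = {
      len <- nchar(d$pattern)
      drop0(seq.int(d$window[1], d$window[2] - len + 1L))
    },
    breu = ,
    breu_like = d$start,
    bred = d$start,
    inr = drop0(seq.int(d$a_window[1], d$a_window[2])),
    dpe = drop0(seq.int(d$start_window[1], d$start_window[2])),
    abort(paste0("unknown motif class: ", class))
  )
}

# Indices occupied by a hit of `class` anchored at `anchor`.
anchor_indices <- function(class, anchor, defs = motif_defs()) {
  d <- defs[[class]]
  len <- nchar(d$pattern)
  start_idx <- switch(class,
    inr = pos_to_index(anchor) - (d$a_index - 1L),
    pos_to_index(anchor)
  )
  seq.int(start_idx, start_idx + len - 1L)
}

# Scan a single character vector for one class; returns list(present, anchor,
# mismatches) using the leftmost qualifying anchor.
scan_class <- function(chars, class, defs, tata_present = FALSE) {
  d <- defs[[class]]
  if (isTRUE(d$requires_tata) && !tata_present) {
    return(list(present = FALSE, anchor = NA_integer_, mismatches = NA_integer_))
  }
  sets <- iupac_sets(d$pattern)
  for (a in legal_anchors(class, defs)) {
    idx <- anchor_indices(class, a, defs)
    if (idx[1] < 1L || idx[length(idx)] > 100L) next
    mm <- mm_at(chars, idx, sets)
    if (mm <= d$max_mismatch) {
      return(list(present = TRUE, anchor = as.integer(a), mismatches = mm))
    }
  }
  list(present = FALSE, anchor = NA_integer_, mismatches = NA_integer_)
}

#' Scan promoters for core promoter elements
#'
#' Applies the seven class rules to each promoter's 100-base core sequence.
#' Sequences are assumed to be in transcribed orientation; set
#' `orientation = "genomic"` to have minus-strand records reverse-complemented
#' before scanning.
#'
#' @param promoters Data frame with columns `promoter_id`, `core_seq` and
#'   optionally `strand` (`+`/`-`; required for `orientation = "genomic"`).
#' @param defs Motif definitions from [motif_defs()].
#' @param orientation Either `"transcribed"` (default) or `"genomic"`.
#' @return A tibble with one row per promoter and class: `promoter_id`,
#'   `class`, `present`, `anchor` (promoter position of the leftmost hit
#'   anchor, `NA` if absent), `mismatches` (mismatch count of that hit).
#' @examples
#' p <- tibble::tibble(
#'   promoter_id = "p1",
#'   core_seq = paste(rep("C", 100), collapse = "")
#' )
#' scan_promoters(p)
#' @export
scan_promoters <- function(promoters, defs = motif_defs(),
                           orientation = c("transcribed", "genomic")) {
  orientation <- arg_match(orientation)
  check_promoters(promoters)
  seqs <- toupper(promoters$core_seq)
  if (orientation == "genomic") {
    if (!"strand" %in% names(promoters)) {
      abort("`orientation = \"genomic\"` requires a `strand` column")
    }
    minus <- promoters$strand == "-"
    seqs[minus] <- revcomp(seqs[minus])
  }
  res <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    tata <- scan_class(chars, "tata", defs)
    rows <- lapply(MOTIF_CLASSES, function(cl) {
      hit <- if (cl == "tata") tata else scan_class(chars, cl, defs, tata$present)
      tibble(class = cl, present = hit$present,
             anchor = hit$anchor, mismatches = hit$mismatches)
    })
    res[[i]] <- bind_rows(rows)
    res[[i]]$promoter_id <- promoters$promoter_id[i]
  }
  bind_rows(res) %>%
    select(all_of(c("promoter_id", "class", "present", "anchor", "mismatches")))
}

check_promoters <- function(promoters) {
  if (!is.data.frame(promoters) ||
      !all(c("promoter_id", "core_seq") %in% names(promoters))) {
    abort("`promoters` must be a data frame with `promoter_id` and `core_seq`")
  }
  len <- nchar(promoters$core_seq)
  if (any(len != 100L)) {
    bad <- promoters$promoter_id[len != 100L][1]
    abort(paste0("core_seq of promoter '", bad, "' is not 100 bases"))
  }
  ok <- grepl("^[ACGTacgt]+$", promoters$core_seq)
  if (!all(ok)) {
    abort(paste0("core_seq of promoter '", promoters$promoter_id[!ok][1],
                 "' contains non-ACGT characters"))
  }
  invisible(promoters)
}

#' Pivot a motif annotation table to one row per promoter
#'
#' @param annotations Long annotation tibble from [scan_promoters()].
#' @return Wide tibble: `promoter_id` plus one logical column per class.
#' @export
annotation_wide <- function(annotations) {
  annotations %>%
    select(all_of(c("promoter_id", "class", "present"))) %>%
    tidyr::pivot_wider(names_from = "class", values_from = "present")
}

#' Per-class motif frequencies
#'
#' Counts promoters carrying each motif class and, additionally, the
#' TATA-exclusive variant of the TATA-like class (`tata_like_only`:
#' promoters with a W-run but no TATA consensus), since reported "TATA-like"
#' frequencies can be read either way.
#'
#' @param annotations Annotation tibble from [scan_promoters()].
#' @return Tibble with `class`, `count`, `n`, `percent` (raw, unrounded).
#' @export
motif_frequency <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  wide <- annotation_wide(annotations)
  n <- nrow(wide)
  counts <- vapply(MOTIF_CLASSES, function(cl) sum(wide[[cl]]), integer(1))
  out <- tibble(class = MOTIF_CLASSES, count = as.integer(counts))
  out <- bind_rows(out, tibble(
    class = "tata_like_only",
    count = sum(wide$tata_like & !wide$tata)
  ))
  out %>% mutate(n = n, percent = 100 * .data$count / n)
}

#' GC content of a core-promoter region
#'
#' Pooled G+C fraction over a position interval of all records' core
#' sequences.
#'
#' @param promoters Data frame with `promoter_id`, `core_seq`.
#' @param region Length-2 numeric, promoter positions (within `[-50, 50]`).
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(promoters, region = c(-50, 50)) {
  check_promoters(promoters)
  stopifnot(length(region) == 2, region[1] <= region[2],
            region[1] >= -50, region[2] <= 50)
  pos <- setdiff(seq.int(region[1], region[2]), 0L)
  if (length(pos) == 0) abort("empty region")
  idx <- pos_to_index(pos)
  chars <- unlist(strsplit(toupper(promoters$core_seq), "", fixed = TRUE))
  mat <- matrix(chars, nrow = 100L)
  slice <- mat[idx, , drop = FALSE]
  mean(slice %in% c("C", "G"))
}

#' Per-position nucleotide frequency matrix
#'
#' @param promoters Data frame with `promoter_id`, `core_seq`.
#' @return Tibble with 100 rows: `position` (promoter coordinate) and columns
#'   `A`, `C`, `G`, `T` summing to 1 per row.
#' @export
nucleotide_frequency_matrix <- function(promoters) {
  check_promoters(promoters)
  stopifnot(nrow(promoters) >= 1)
  chars <- unlist(strsplit(toupper(promoters$core_seq), "", fixed = TRUE))
  mat <- matrix(chars, nrow = 100L)
  freq <- t(apply(mat, 1, function(row) {
    tab <- table(factor(row, levels = c("A", "C", "G", "T")))
    as.numeric(tab) / length(row)
  }))
  out <- as_tibble(freq, .name_repair = ~ c("A", "C", "G", "T"))
  out$position <- index_to_pos(1:100)
  select(out, all_of(c("position", "A", "C", "G", "T")))
}
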