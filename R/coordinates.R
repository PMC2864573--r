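# Promoter coordinate conventions.
#
# Core sequences cover positions -50..+50 with the TSS at +1 and *no position
# 0* (standard promoter-biology numbering). A 100-base core sequence therefore
# maps 1-based string indices to promoter positions as
#   index 1..50   -> position -50..-1
#   index 51..100 -> position +1..+50
# All motif windows in this package are stated in promoter positions and
# converted to string indices through these two helpers. Because the numbering
# merely skips the label 0, adjacency in position space equals adjacency in
# index space, so fixed-length motifs occupy contiguous index runs.

#' Convert promoter positions to core-sequence indices
#'
#' @param pos Integer vector of promoter positions in `[-50, 50]`, excluding 0.
#' @return Integer vector of 1-based indices into a 100-base core sequence.
#' @examples
#' pos_to_index(c(-50, -1, 1, 50))
#' @export
pos_to_index <- function(pos) {
  stopifnot(all(pos != 0L), all(pos >= -50L), all(pos <= 50L))
  ifelse(pos < 0L, pos + 51L, pos + 50L)
}

#' Convert core-sequence indices to promoter positions
#'
#' @param idx Integer vector of 1-based indices in `[1, 100]`.
#' @return Integer vector of promoter positions (no 0; TSS is +1).
#' @examples
#' index_to_pos(c(1, 50, 51, 100))
#' @export
index_to_pos <- function(idx) {
  stopifnot(all(idx >= 1L), all(idx <= 100L))
  ifelse(idx <= 50L, idx - 51L, idx - 50L)
}

# Indices occupied by a motif of length `len` whose first base sits at
# promoter position `start_pos`.
motif_indices <- function(start_pos, len) {
  i0 <- pos_to_index(start_pos)
  seq.int(i0, i0 + len - 1L)
}

#' Reverse-complement a nucleotide string
#'
#' Plain-character reverse complement for A/C/G/T (and IUPAC degenerate codes).
#' Used to orient minus-strand promoter sequences into transcribed orientation
#' before scanning.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}
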