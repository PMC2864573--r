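# Motif combination counting and reference-motif co-occurrence fractions.
#
# The default class set collapses consensus and relaxed variants into
# like-motif classes: tata_class = TATA or TATA-like, breu_class = BREu or
# BREu-like, plus INR and DPE. Reported "at least one core promoter motif"
# frequencies are consistent with this like-motif counting, not with a
# consensus-only union; the raw seven classes can be requested instead.

COLLAPSED_CLASSES <- c("tata_class", "breu_class", "inr", "dpe")

# Resolve a (possibly collapsed) class name to a logical presence vector
# over a wide annotation table.
class_membership <- function(wide, class) {
  if (class %in% names(wide)) return(wide[[class]])
  switch(class,
    tata_class = wide$tata | wide$tata_like,
    breu_class = wide$breu | wide$breu_like,
    abort(paste0("unknown motif class: ", class))
  )
}

#' Count motif combinations per promoter
#'
#' Computes, for each promoter, the number of distinct motif classes present
#' (the combination size) and tabulates cohort counts for sizes 0, 1, 2 and
#' 3 or more, together with per-class and per-pair counts.
#'
#' @param annotations Annotation tibble from [scan_promoters()].
#' @param classes Class set to count over; defaults to the collapsed 4-class
#'   set (`tata_class`, `breu_class`, `inr`, `dpe`). Raw class names
#'   (`tata`, `tata_like`, `breu`, `breu_like`, `bred`, `inr`, `dpe`) are
#'   also accepted.
#' @return Object of class `combination_report`: `sizes` (per promoter),
#'   `size_counts` (sizes 0/1/2/3+ with counts and percentages),
#'   `class_counts`, `pair_counts`, `classes`, `n`.
#' @export
combination_counts <- function(annotations, classes = COLLAPSED_CLASSES) {
  if (length(classes) == 0) abort("`classes` must be non-empty")
  wide <- annotation_wide(annotations)
  memb <- vapply(classes, function(cl) class_membership(wide, cl),
                 logical(nrow(wide)))
  memb <- matrix(memb, nrow = nrow(wide),
                 dimnames = list(NULL, classes))
  size <- rowSums(memb)
  n <- nrow(wide)
  size_bin <- cut(size, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                  labels = c("0", "1", "2", "3+"))
  size_counts <- tibble(size = factor(c("0", "1", "2", "3+"),
                                      levels = c("0", "1", "2", "3+"))) %>%
    left_join(count(tibble(size = size_bin), .data$size, name = "count"),
              by = "size") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           percent = 100 * .data$count / n)
  class_counts <- tibble(class = classes,
                         count = as.integer(colSums(memb)),
                         percent = 100 * colSums(memb) / n)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pair_counts <- bind_rows(lapply(pairs, function(p) {
    tibble(class_a = p[1], class_b = p[2],
           count = sum(memb[, p[1]] & memb[, p[2]]))
  }))
  structure(list(
    sizes = tibble(promoter_id = wide$promoter_id, size = as.integer(size)),
    size_counts = size_counts,
    class_counts = class_counts,
    pair_counts = pair_counts,
    classes = classes, n = n
  ), class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat("Motif combinations over", x$n, "promoters (classes:",
      paste(x$classes, collapse = ", "), ")\n")
  print(x$size_counts)
  invisible(x)
}

#' Co-occurrence fraction of two motif classes
#'
#' Fractional co-occurrence with the reference motif set to 100%:
#' `100 * |reference AND second| / |reference|`. Raw numerator and
#' denominator are reported alongside the percentage so rounding never hides
#' counts.
#'
#' @param annotations Annotation tibble from [scan_promoters()].
#' @param reference,second Class names (raw or collapsed).
#' @return One-row tibble: `reference`, `second`, `n_reference`, `n_both`,
#'   `percent`.
#' @export
cooccur_fraction <- function(annotations, reference, second) {
  wide <- annotation_wide(annotations)
  ref <- class_membership(wide, reference)
  sec <- class_membership(wide, second)
  if (sum(ref) == 0) {
    abort(paste0("no promoter carries reference class '", reference,
                 "'; the fraction is undefined"))
  }
  tibble(reference = reference, second = second,
         n_reference = sum(ref), n_both = sum(ref & sec),
         percent = 100 * sum(ref & sec) / sum(ref))
}
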