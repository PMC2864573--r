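# Cohort blueprints: the generative specification for synthetic promoter
# cohorts. A blueprint fixes the number of promoters, the background base
# composition, the planted motif table, the two-factor occupancy model, the
# expression coupling, the PIC footprint used for probe signals, replicate
# noise, TSS shape labels and tag depth, and the seed. Shipped presets encode
# published cohort compositions so that scanning a fixture-mode cohort
# reproduces printed motif percentages exactly.

PRESET_NAMES <- c("top100", "high_tfiib", "low_tfiib", "tfiib_dominated",
                  "nc2_dominated", "cooccur_inr", "cooccur_dpe",
                  "profile_minus50")

#' Construct a cohort blueprint
#'
#' @param n_promoters Number of promoters in the cohort.
#' @param background_gc Background GC fraction for core sequences.
#' @param motif_table Tibble with columns `promoter` (1-based index), `class`
#'   (one of the seven motif classes) and optionally `anchor` (promoter
#'   position; `NA` lets the generator pick a random legal anchor). Implied
#'   memberships must be explicit: every `tata` promoter must also carry a
#'   `tata_like` row and every `breu` promoter a `breu_like` row.
#' @param occupancy_model List: `location` and `spread`, each named numeric
#'   `c(tfiib=, nc2=)` on the log2 scale, and `correlation` in `[-1, 1]`.
#' @param expression_model List: `coupling` (slope of expression on log2 TFIIB
#'   occupancy), `noise` (sd), `present_rate` (probability of a 'present'
#'   detection call).
#' @param footprint List: `center` and `spread` (bp) of the Gaussian PIC
#'   footprint placed on probe signals, plus `baseline` and `probe_noise`
#'   (log2 units).
#' @param replicate_noise Sd of replicate-specific noise added to each probe
#'   value; smaller values give higher replicate concordance.
#' @param tss_shape_table Tibble with columns `promoter`, `shape`
#'   (`focused`/`dispersed`); defaults to all focused.
#' @param tag_mean Mean CAGE-like tag total per promoter.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return A validated object of class `cohort_blueprint`.
#' @export
cohort_blueprint <- function(n_promoters,
                             background_gc = 0.5,
                             motif_table = NULL,
                             occupancy_model = list(
                               location = c(tfiib = 1, nc2 = 1),
                               spread = c(tfiib = 1, nc2 = 1),
                               correlation = 0.8),
                             expression_model = list(
                               coupling = 1, noise = 0.5, present_rate = 1),
                             footprint = list(
                               center = -50, spread = 150,
                               baseline = 0, probe_noise = 0.25),
                             replicate_noise = 0.3,
                             tss_shape_table = NULL,
                             tag_mean = 500,
                             seed = 1L) {
  if (is.null(motif_table)) {
    motif_table <- tibble(promoter = integer(), class = character(),
                          anchor = integer())
  }
  motif_table <- as_tibble(motif_table)
  if (!"anchor" %in% names(motif_table)) motif_table$anchor <- NA_integer_
  if (is.null(tss_shape_table)) {
    tss_shape_table <- tibble(promoter = seq_len(n_promoters),
                              shape = "focused")
  }
  bp <- structure(list(
    n_promoters = as.integer(n_promoters),
    background_gc = background_gc,
    motif_table = motif_table,
    occupancy_model = occupancy_model,
    expression_model = expression_model,
    footprint = footprint,
    replicate_noise = replicate_noise,
    tss_shape_table = as_tibble(tss_shape_table),
    tag_mean = tag_mean,
    seed = as.integer(seed)
  ), class = "cohort_blueprint")
  validate_blueprint(bp)
}

#' Validate a cohort blueprint
#'
#' Checks ranges and the planting implications (TATA planted implies TATA-like
#' planted; BREu implies BREu-like; BREd only in TATA promoters; anchors inside
#' the legal scan window of their class).
#'
#' @param bp A `cohort_blueprint`.
#' @return The blueprint, invisibly usable; errors name the violated rule.
#' @export
validate_blueprint <- function(bp) {
  stopifnot(inherits(bp, "cohort_blueprint"))
  if (bp$n_promoters < 1) abort("n_promoters must be >= 1")
  if (bp$background_gc < 0 || bp$background_gc > 1) {
    abort("background_gc must lie in [0, 1]")
  }
  rho <- bp$occupancy_model$correlation
  if (abs(rho) > 1) abort("occupancy correlation must lie in [-1, 1]")
  mt <- bp$motif_table
  if (nrow(mt) > 0) {
    bad <- setdiff(unique(mt$class), MOTIF_CLASSES)
    if (length(bad) > 0) abort(paste0("unknown motif class in motif_table: ",
                                      paste(bad, collapse = ", ")))
    if (any(mt$promoter < 1 | mt$promoter > bp$n_promoters)) {
      abort("motif_table promoter index outside 1..n_promoters")
    }
    if (anyDuplicated(mt[c("promoter", "class")]) > 0) {
      abort("duplicate (promoter, class) planting")
    }
    carriers <- function(cl) mt$promoter[mt$class == cl]
    miss <- setdiff(carriers("tata"), carriers("tata_like"))
    if (length(miss) > 0) {
      abort(paste0("violated implication TATA => TATA-like: promoters ",
                   paste(miss, collapse = ", "),
                   " plant tata without tata_like"))
    }
    miss <- setdiff(carriers("breu"), carriers("breu_like"))
    if (length(miss) > 0) {
      abort(paste0("violated implication BREu => BREu-like: promoters ",
                   paste(miss, collapse = ", "),
                   " plant breu without breu_like"))
    }
    miss <- setdiff(carriers("bred"), carriers("tata"))
    if (length(miss) > 0) {
      abort(paste0("BREd requires TATA: promoters ",
                   paste(miss, collapse = ", "),
                   " plant bred without tata"))
    }
    defs <- motif_defs()
    for (i in seq_len(nrow(mt))) {
      a <- mt$anchor[i]
      if (!is.na(a) && !(a %in% legal_anchors(mt$class[i], defs))) {
        abort(paste0("anchor ", a, " outside legal scan window of class ",
                     mt$class[i]))
      }
    }
  }
  shp <- bp$tss_shape_table
  if (!all(shp$shape %in% c("focused", "dispersed"))) {
    abort("tss_shape_table shapes must be 'focused' or 'dispersed'")
  }
  bp
}

# Expected GC base count contributed by one planting of a class, when planted
# bases are drawn uniformly from each IUPAC code's allowed set ('_like only'
# plantings carry exactly one mismatch drawn uniformly from the disallowed
# set of a uniformly chosen position).
planting_gc <- function(class) {
  defs <- motif_defs()
  pat <- defs[[class]]$pattern
  gc_allowed <- iupac_gc_fraction(pat)
  if (class == "breu_like") {
    sets <- iupac_sets(pat)
    gc_disallowed <- vapply(sets, function(s) {
      d <- setdiff(c("A", "C", "G", "T"), s)
      mean(d %in% c("C", "G"))
    }, numeric(1))
    sum(gc_allowed) - mean(gc_allowed - gc_disallowed)
  } else {
    sum(gc_allowed)
  }
}

planting_len <- function(class) nchar(motif_defs()[[class]]$pattern)

# Solve the background GC so the expected cohort-wide GC over -50..+50 equals
# `target_gc` given the planted motifs. Printed promoter GC values describe
# whole core regions including their (often AT-rich) elements, so presets
# calibrate the background upward to compensate.
calibrate_background_gc <- function(n_promoters, motif_table, target_gc) {
  total <- 100 * n_promoters
  if (nrow(motif_table) == 0) return(target_gc)
  eff <- effective_plantings(motif_table)
  if (nrow(eff) == 0) return(target_gc)
  bases <- sum(vapply(eff$class, planting_len, numeric(1)))
  gc <- sum(vapply(eff$class, planting_gc, numeric(1)))
  bg <- (target_gc * total - gc) / (total - bases)
  stopifnot(bg >= 0, bg <= 1)
  bg
}

# Collapse a planting table to the motifs that are physically written into the
# sequence: tata subsumes tata_like, breu subsumes breu_like.
effective_plantings <- function(motif_table) {
  mt <- motif_table
  has <- function(p, cl) p %in% mt$promoter[mt$class == cl]
  keep <- vapply(seq_len(nrow(mt)), function(i) {
    cl <- mt$class[i]; p <- mt$promoter[i]
    if (cl == "tata_like" && has(p, "tata")) return(FALSE)
    if (cl == "breu_like" && has(p, "breu")) return(FALSE)
    TRUE
  }, logical(1))
  mt[keep, , drop = FALSE]
}

# Build a long planting table from per-class promoter index vectors.
composition_table <- function(...) {
  sets <- list(...)
  bind_rows(lapply(names(sets), function(cl) {
    if (length(sets[[cl]]) == 0) return(NULL)
    tibble(promoter = as.integer(sets[[cl]]), class = cl,
           anchor = NA_integer_)
  }))
}

#' Load a shipped cohort preset
#'
#' Presets encode published promoter-cohort compositions as exact integer
#' planting counts at the preset's n, so that fixture-mode generation followed
#' by scanning reproduces the printed percentages exactly. Available presets:
#'
#' * `top100`: 100 promoters; TATA 24, TATA-like 66 (incl. TATA), BREu 3,
#'   BREu-like 17, INR 17.
#' * `high_tfiib`: TATA 5, TATA-like 29, BREu 3, BREu-like 19, INR 12;
#'   cohort GC calibrated to 61%.
#' * `low_tfiib`: TATA 1, TATA-like 20, BREu 3, BREu-like 21, INR 10;
#'   cohort GC calibrated to 62%.
#' * `tfiib_dominated`: TATA 39, TATA-like 63, BREu 6, BREu-like 36, INR 20,
#'   DPE 11; combination sizes 0/1/2/3 = 19/43/27/11 under the collapsed
#'   4-class rule; 69% focused TSS shapes; mean tag depth 948.
#' * `nc2_dominated`: TATA 1, TATA-like 16, BREu 1, BREu-like 12, INR 13,
#'   DPE 1; sizes 0/1/2/3 = 62/34/4/0; 32% focused; mean tag depth 279.
#' * `cooccur_inr`: 100 INR promoters, 94 also TATA-like, 56 also TATA.
#' * `cooccur_dpe`: 100 DPE promoters, 89 also TATA-like, 67 also TATA.
#' * `profile_minus50`: no plantings; PIC footprint centered at -50 with a
#'   20-bp spread for binding-profile mode recovery.
#'
#' @param name Preset id.
#' @param seed Seed stored in the returned blueprint.
#' @return A `cohort_blueprint`.
#' @export
load_preset <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1 || !(name %in% PRESET_NAMES)) {
    abort(paste0("unknown preset '", paste(name, collapse = ","),
                 "'; valid presets: ", paste(PRESET_NAMES, collapse = ", ")))
  }
  n <- 100L
  spec <- switch(name,
    top100 = list(
      comp = composition_table(
        tata = 1:24, tata_like = 1:66, breu = 1:3, breu_like = 1:17,
        inr = 84:100),
      gc = 0.61),
    high_tfiib = list(
      comp = composition_table(
        tata = 1:5, tata_like = 1:29, breu = 1:3, breu_like = 1:19,
        inr = 89:100),
      gc = 0.61),
    low_tfiib = list(
      comp = composition_table(
        tata = 1, tata_like = 1:20, breu = 1:3, breu_like = 1:21,
        inr = 91:100),
      gc = 0.62),
    tfiib_dominated = list(
      comp = composition_table(
        tata = 1:39, tata_like = 1:63,
        breu = 1:6, breu_like = c(1:25, 64:74),
        inr = c(1:6, 26:32, 75:81),
        dpe = c(7:11, 33:38)),
      gc = 0.61, focused = 1:69, tag_mean = 948,
      occ = list(location = c(tfiib = 2, nc2 = 0.8),
                 spread = c(tfiib = 1, nc2 = 1), correlation = 0.8)),
    nc2_dominated = list(
      comp = composition_table(
        tata = 1, tata_like = 1:16,
        breu = 3, breu_like = c(3, 17:27),
        inr = c(1:2, 28:38),
        dpe = 4),
      gc = 0.61, focused = 1:32, tag_mean = 279,
      occ = list(location = c(tfiib = 0.8, nc2 = 2),
                 spread = c(tfiib = 1, nc2 = 1), correlation = 0.8)),
    cooccur_inr = list(
      comp = composition_table(
        inr = 1:100, tata = 1:56, tata_like = 1:94),
      gc = 0.61),
    cooccur_dpe = list(
      comp = composition_table(
        dpe = 1:100, tata = 1:67, tata_like = 1:89),
      gc = 0.61),
    profile_minus50 = list(
      comp = NULL, gc = 0.61,
      footprint = list(center = -50, spread = 20,
                       baseline = 0, probe_noise = 0.25))
  )
  comp <- if (is.null(spec$comp)) NULL else spec$comp
  args <- list(
    n_promoters = n,
    background_gc = calibrate_background_gc(
      n, comp %||% tibble(promoter = integer(), class = character()),
      spec$gc),
    motif_table = comp,
    seed = seed
  )
  if (!is.null(spec$occ)) args$occupancy_model <- spec$occ
  if (!is.null(spec$tag_mean)) args$tag_mean <- spec$tag_mean
  if (!is.null(spec$footprint)) args$footprint <- spec$footprint
  if (!is.null(spec$focused)) {
    args$tss_shape_table <- tibble(
      promoter = 1:n,
      shape = ifelse(1:n %in% spec$focused, "focused", "dispersed"))
  }
  do.call(cohort_blueprint, args)
}

#' @export
print.cohort_blueprint <- function(x, ...) {
  cat("<cohort_blueprint>\n")
  cat("  promoters:     ", x$n_promoters, "\n")
  cat("  background GC: ", round(x$background_gc, 4), "\n")
  cat("  plantings:     ", nrow(x$motif_table), "\n")
  cat("  seed:          ", x$seed, "\n")
  invisible(x)
}
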