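# Seeded synthetic promoter-cohort generation.
#
# Fixture mode makes the motif composition of the cohort *exact*: planted
# motifs are written into the core sequences (frozen), and any background
# window that accidentally matches a non-planted class at a legal scan
# position is resampled until no unplanned hit remains ("plant-then-scrub").
# Scanning a fixture cohort therefore returns exactly the planted counts.
# Sampling mode plants without scrubbing, leaving background hit rates at
# their natural stochastic level.

BASES <- c("A", "C", "G", "T")

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Probe offsets of the synthetic tiling design
#'
#' Fifteen probes tile 1.5 kb around the TSS at 100-bp spacing, strand
#' oriented (negative = upstream of the TSS).
#' @return Integer vector of 15 offsets.
#' @export
probe_offsets <- function() seq.int(-700L, 700L, by = 100L)

sample_pattern_bases <- function(pattern, exact_one_mismatch = FALSE) {
  sets <- iupac_sets(pattern)
  bases <- vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1))
  if (exact_one_mismatch) {
    k <- sample.int(length(sets), 1L)
    disallowed <- setdiff(BASES, sets[[k]])
    bases[k] <- disallowed[sample.int(length(disallowed), 1L)]
  }
  unname(bases)
}

# All hits of one class in a promoter (anchor + occupied indices), used by
# the scrubber. `tata_present` gates the BREd scan.
all_class_hits <- function(chars, class, defs, tata_present) {
  d <- defs[[class]]
  if (isTRUE(d$requires_tata) && !tata_present) return(list())
  sets <- iupac_sets(d$pattern)
  hits <- list()
  for (a in legal_anchors(class, defs)) {
    idx <- anchor_indices(class, a, defs)
    if (idx[1] < 1L || idx[length(idx)] > 100L) next
    if (mm_at(chars, idx, sets) <= d$max_mismatch) {
      hits[[length(hits) + 1L]] <- list(anchor = a, idx = idx)
    }
  }
  hits
}

# Resample unplanned hits until the promoter is clean. `frozen` indices are
# planted bases and are never touched.
scrub_promoter <- function(chars, planned, frozen, probs, defs,
                           max_rounds = 200L, promoter_id = "?") {
  scrub_classes <- setdiff(MOTIF_CLASSES, planned)
  for (round in seq_len(max_rounds)) {
    tata_present <- length(all_class_hits(chars, "tata", defs, TRUE)) > 0
    dirty <- integer(0)
    for (cl in scrub_classes) {
      for (hit in all_class_hits(chars, cl, defs, tata_present)) {
        free <- setdiff(hit$idx, frozen)
        if (length(free) == 0) {
          abort(paste0("scrub cannot repair promoter '", promoter_id,
                       "': unplanned ", cl, " hit at anchor ", hit$anchor,
                       " lies entirely within planted bases"))
        }
        dirty <- union(dirty, free)
      }
    }
    if (length(dirty) == 0) return(chars)
    chars[dirty] <- sample(BASES, length(dirty), replace = TRUE, prob = probs)
  }
  abort(paste0("scrub failed to converge for promoter '", promoter_id,
               "' after ", max_rounds, " rounds"))
}

plant_promoter <- function(chars, plantings, probs, defs, promoter_id) {
  frozen <- integer(0)
  # fixed-anchor classes first, windowed classes choose a free anchor
  ord <- order(match(plantings$class,
                     c("tata", "breu", "breu_like", "bred",
                       "tata_like", "inr", "dpe")))
  plantings <- plantings[ord, , drop = FALSE]
  for (i in seq_len(nrow(plantings))) {
    cl <- plantings$class[i]
    anchor <- plantings$anchor[i]
    anchors <- legal_anchors(cl, defs)
    if (!is.na(anchor)) anchors <- anchor
    ok <- anchors[vapply(anchors, function(a) {
      idx <- anchor_indices(cl, a, defs)
      length(intersect(idx, frozen)) == 0
    }, logical(1))]
    if (length(ok) == 0) {
      abort(paste0("no free anchor to plant ", cl, " in promoter '",
                   promoter_id, "'"))
    }
    a <- ok[sample.int(length(ok), 1L)]
    idx <- anchor_indices(cl, a, defs)
    exact_mm <- cl == "breu_like"  # '_like only' plantings carry 1 mismatch
    chars[idx] <- sample_pattern_bases(defs[[cl]]$pattern,
                                       exact_one_mismatch = exact_mm)
    frozen <- union(frozen, idx)
  }
  list(chars = chars, frozen = frozen)
}

#' Generate a synthetic promoter cohort
#'
#' Draws core sequences, two-factor occupancy, probe-level ChIP/input signals
#' with a Gaussian PIC footprint, occupancy-coupled expression, and CAGE-like
#' tag vectors, all from the blueprint's seed.
#'
#' @param blueprint A [cohort_blueprint()].
#' @param mode `"fixture"` (plant-then-scrub: scanner counts equal planted
#'   counts exactly) or `"sampling"` (plant without scrubbing).
#' @param n_replicates Number of replicates per factor (default 2).
#' @return An object of class `synthetic_cohort`: a list of tibbles
#'   (`promoters`, `probes`, `signals`, `occupancy`, `expression`,
#'   `cage_tags`, `tss_shapes`) plus the `blueprint` used.
#' @examples
#' bp <- cohort_blueprint(n_promoters = 5, seed = 42)
#' cohort <- generate_cohort(bp)
#' cohort$promoters
#' @export
generate_cohort <- function(blueprint, mode = c("fixture", "sampling"),
                            n_replicates = 2L) {
  mode <- arg_match(mode)
  validate_blueprint(blueprint)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(blueprint$seed)

  n <- blueprint$n_promoters
  defs <- motif_defs()
  probs <- base_probs(blueprint$background_gc)
  ids <- sprintf("prom_%0*d", max(3L, nchar(n)), seq_len(n))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  mt <- effective_plantings(blueprint$motif_table)
  planned_by_prom <- split(blueprint$motif_table$class,
                           factor(blueprint$motif_table$promoter,
                                  levels = seq_len(n)))
  seqs <- character(n)
  for (p in seq_len(n)) {
    chars <- sample(BASES, 100L, replace = TRUE, prob = probs)
    plant <- mt[mt$promoter == p, , drop = FALSE]
    frozen <- integer(0)
    if (nrow(plant) > 0) {
      res <- plant_promoter(chars, plant, probs, defs, ids[p])
      chars <- res$chars
      frozen <- res$frozen
    }
    if (mode == "fixture") {
      chars <- scrub_promoter(chars, planned_by_prom[[p]], frozen, probs,
                              defs, promoter_id = ids[p])
    }
    seqs[p] <- paste(chars, collapse = "")
  }
  promoters <- tibble(promoter_id = ids, strand = strands, core_seq = seqs)

  offs <- probe_offsets()
  probes <- tidyr::expand_grid(promoter_id = ids, probe_index = 1:15) %>%
    mutate(offset = offs[.data$probe_index])

  om <- blueprint$occupancy_model
  z1 <- rnorm(n)
  z2 <- om$correlation * z1 + sqrt(1 - om$correlation^2) * rnorm(n)
  occ <- tibble(
    promoter_id = rep(ids, 2),
    factor = rep(c("tfiib", "nc2"), each = n),
    log2_enrichment = c(om$location[["tfiib"]] + om$spread[["tfiib"]] * z1,
                        om$location[["nc2"]] + om$spread[["nc2"]] * z2)
  )

  em <- blueprint$expression_model
  expression <- tibble(
    promoter_id = ids,
    signal = em$coupling * (om$location[["tfiib"]] + om$spread[["tfiib"]] * z1) +
      rnorm(n, 0, em$noise),
    present = runif(n) < (em$present_rate %||% 1)
  )

  fp <- blueprint$footprint
  gdens <- exp(-(offs - fp$center)^2 / (2 * fp$spread^2))
  sig_list <- list()
  for (f in c("tfiib", "nc2")) {
    amp <- occ$log2_enrichment[occ$factor == f]
    truth <- fp$baseline +
      outer(amp, gdens) +                              # n x 15
      matrix(rnorm(n * 15L, 0, fp$probe_noise), n, 15L)
    for (r in seq_len(n_replicates)) {
      obs <- truth + matrix(rnorm(n * 15L, 0, blueprint$replicate_noise), n, 15L)
      sig_list[[paste(f, r)]] <- tibble(
        promoter_id = rep(ids, each = 15L),
        probe_index = rep(1:15, n),
        offset = rep(offs, n),
        factor = f,
        replicate = r,
        log2_ratio = as.vector(t(obs))
      )
    }
  }
  signals <- bind_rows(sig_list)

  shapes <- blueprint$tss_shape_table %>%
    mutate(promoter_id = ids[.data$promoter]) %>%
    select(all_of(c("promoter_id", "shape")))
  tags <- generate_cage_tags(ids, shapes$shape[match(ids, shapes$promoter_id)],
                             blueprint$tag_mean)

  structure(list(
    promoters = promoters,
    probes = probes,
    signals = signals,
    occupancy = occ,
    expression = expression,
    cage_tags = tags,
    tss_shapes = shapes,
    blueprint = blueprint,
    mode = mode
  ), class = "synthetic_cohort")
}

# Focused promoters concentrate >= ~80% of tags on one dominant start;
# dispersed promoters spread tags over four modes >= 25 bp apart with no
# mode above 40% of the total.
generate_cage_tags <- function(ids, shapes, tag_mean) {
  out <- vector("list", length(ids))
  scatter <- setdiff(-30:30, 0L)
  modes <- c(-60L, -20L, 20L, 60L)
  mode_w <- c(0.30, 0.25, 0.25, 0.20)
  for (i in seq_along(ids)) {
    total <- max(1L, rpois(1L, tag_mean))
    if (shapes[i] == "focused") {
      n_dom <- rbinom(1L, total, 0.85)
      rest <- total - n_dom
      pos <- c(rep(0L, n_dom),
               if (rest > 0) sample(scatter, rest, replace = TRUE))
    } else {
      counts <- as.vector(stats::rmultinom(1L, total, mode_w))
      pos <- rep(modes, counts)
    }
    tab <- table(pos)
    out[[i]] <- tibble(promoter_id = ids[i],
                       offset = as.integer(names(tab)),
                       count = as.integer(tab))
  }
  bind_rows(out)
}

#' Sample footprint-distributed probe offsets over a uniform background
#'
#' Draws `n_high` high-score probe offsets from the blueprint's Gaussian PIC
#' footprint (rounded to integer bp, clipped to the array's `[-750, 750]`
#' range) and lays them over a deterministic uniform all-probe grid (every
#' integer offset repeated `grid_copies` times). The high probes are included
#' in the all-probe set, as on a real array.
#'
#' @param blueprint A [cohort_blueprint()]; its `footprint` and `seed` are used.
#' @param n_high Number of high-score offsets to draw.
#' @param grid_copies Copies of each integer offset in the background grid.
#' @return List with tibbles `high_probes` and `all_probes`, each with
#'   `promoter_id` and `offset` columns suitable for [build_profile()].
#' @export
sample_profile_probes <- function(blueprint, n_high = 5000L,
                                  grid_copies = 35L) {
  validate_blueprint(blueprint)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(blueprint$seed)
  fp <- blueprint$footprint
  off <- as.integer(round(rnorm(n_high, fp$center, fp$spread)))
  off <- pmin(pmax(off, -750L), 750L)
  high <- tibble(promoter_id = sprintf("hi_%05d", seq_len(n_high)),
                 offset = off)
  grid <- tidyr::expand_grid(copy = seq_len(grid_copies),
                             offset = -750:750) %>%
    mutate(promoter_id = sprintf("bg_%02d", .data$copy)) %>%
    select(all_of(c("promoter_id", "offset")))
  list(high_probes = high, all_probes = bind_rows(grid, high))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> (", x$mode, " mode)\n", sep = "")
  cat("  promoters: ", nrow(x$promoters), "\n")
  cat("  signals:   ", nrow(x$signals), " probe values (",
      length(unique(x$signals$factor)), " factors x ",
      length(unique(x$signals$replicate)), " replicates)\n", sep = "")
  cat("  plantings: ", nrow(x$blueprint$motif_table), "\n")
  invisible(x)
}
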