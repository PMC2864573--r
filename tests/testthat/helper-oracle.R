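# Independent brute-force motif scanner used as an oracle. It shares nothing
# with the package implementation: positions are resolved through an explicit
# position map, and every window of the sequence is tested against the class
# rule by direct containment checks.

oracle_codes <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), D = c("A", "G", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# promoter position of each string index (TSS = +1, no 0)
oracle_pos_map <- c(-50:-1, 1:50)

oracle_mm <- function(chars, start, pattern) {
  codes <- strsplit(pattern, "")[[1]]
  if (start + length(codes) - 1L > length(chars)) return(Inf)
  sum(vapply(seq_along(codes), function(k) {
    !(chars[start + k - 1L] %in% oracle_codes[[codes[k]]])
  }, logical(1)))
}

# Scan one sequence for all seven classes by exhaustive window enumeration.
oracle_scan <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  hit <- function(positions_ok, pattern, maxmm = 0) {
    any(vapply(seq_along(chars), function(i) {
      positions_ok(i) && oracle_mm(chars, i, pattern) <= maxmm
    }, logical(1)))
  }
  pm <- oracle_pos_map
  tata <- hit(function(i) pm[i] == -31, "TATAW")
  tata_like <- hit(function(i) {
    j <- i + 3L
    j <= 100L && pm[i] >= -40 && pm[j] <= -20
  }, "WWWW")
  breu <- hit(function(i) pm[i] == -37, "SRCGCC", 0)
  breu_like <- hit(function(i) pm[i] == -37, "SRCGCC", 1)
  bred <- tata && hit(function(i) pm[i] == -25, "RTDKKKK", 0)
  inr <- hit(function(i) {
    j <- i + 2L  # central A of YYANWY
    j <= 100L && i + 5L <= 100L && pm[j] >= -4 && pm[j] <= 5
  }, "YYANWY")
  dpe <- hit(function(i) pm[i] >= 28 && pm[i] <= 32, "RGWYVT")
  c(tata = tata, tata_like = tata_like, breu = breu, breu_like = breu_like,
    bred = bred, inr = inr, dpe = dpe)
}

random_seq <- function(n = 100, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# A sequence with no motif hits anywhere (all-C background fails every class)
blank_seq <- function() paste(rep("C", 100), collapse = "")

# Write a motif into a blank core sequence at given promoter positions
with_motif <- function(seq, start_pos, bases) {
  chars <- strsplit(seq, "")[[1]]
  idx <- which(oracle_pos_map == start_pos) + seq_along(strsplit(bases, "")[[1]]) - 1L
  chars[idx] <- strsplit(bases, "")[[1]]
  paste(chars, collapse = "")
}
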