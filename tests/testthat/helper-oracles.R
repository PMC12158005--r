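# Independent brute-force oracles used by the oracle-equivalence tests.
# These deliberately re-derive each quantity from its definition with naive
# loops, sharing no code with the package implementations they check.

# All end-to-end Hamming alignments of one tag on both strands.
oracle_align <- function(tag, genome_seq, max_mm = 2) {
  glen <- nchar(genome_seq)
  L <- nchar(tag)
  gv <- strsplit(genome_seq, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else
      paste(rev(chartr("ACGT", "TGCA", strsplit(tag, "")[[1]])), collapse = "")
    qv <- strsplit(q, "")[[1]]
    for (s0 in 0:(glen - L)) {
      mm <- sum(gv[(s0 + 1):(s0 + L)] != qv)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(start = s0, strand = strand,
                                             mismatches = mm)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), strand = character(0),
               mismatches = integer(0))
}

# Hypergeometric upper tail by explicit enumeration of all draws of n
# positions out of N (the first m positions are the in-register ones).
oracle_hyper_tail <- function(N, m, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)
  mean(hits >= k)
}

# Benjamini-Hochberg adjusted p-values straight from the definition:
# adj_i = min over { j : p_(j) >= p_i } of n * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(n * ps[i:n] / (i:n)))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- adj_sorted
  out
}

# Degradome category re-derived from the category definitions.
oracle_category <- function(density, pos0) {
  r <- density[pos0 + 1]
  occ <- density[density > 0]
  M <- max(occ)
  med <- stats::median(occ)
  if (r == 1) return(4L)
  if (r == M && sum(occ == M) == 1) return(0L)
  if (r == M) return(1L)
  if (r > med && r < M) return(2L)
  3L
}

# Model predicates evaluated verbatim.
oracle_classify <- function(mi, ph, mr) {
  s <- (mi * mr < 0) && (abs(mi) > 1) && (abs(mr) > 1)
  m1 <- s && ((mi * ph < 0) || (abs(ph) < 1))
  m2 <- s && ((mi * ph > 0) && (abs(ph) > 1))
  if (m2) "model2" else if (m1) "model1" else "none"
}

# Naive enumeration of every duplex alignment (ungapped, one unpaired sRNA
# base, one bulged transcript base) with its Allen score and raw penalty.
oracle_duplex_scan <- function(srna, tx, max_raw = 4) {
  L <- nchar(srna); Tn <- nchar(tx)
  sv <- strsplit(srna, "")[[1]]
  tv <- strsplit(tx, "")[[1]]
  ptype <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) "match"
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) "GU"
    else "mismatch"
  }
  pen_of <- function(cl) c(match = 0, GU = 0.5, mismatch = 1)[[cl]]
  mult <- function(j) if (j >= 2 && j <= 13) 2 else 1
  rows <- list()
  add <- function(start0, gap_type, gap_pos, raw, allen) {
    if (raw <= max_raw) {
      rows[[length(rows) + 1]] <<- data.frame(
        site_start = start0, gap_type = gap_type,
        gap_pos = gap_pos, allen = allen, raw = raw)
    }
  }
  for (o in 0:(Tn - L)) {            # ungapped: s[j] pairs tx[o + L + 1 - j]
    raw <- 0; al <- 0
    for (j in 1:L) {
      p <- pen_of(ptype(sv[j], tv[o + L + 1 - j]))
      raw <- raw + p; al <- al + p * mult(j)
    }
    add(o, "none", NA, raw, al)
  }
  for (g in 2:(L - 1)) {             # unpaired sRNA base g, site length L-1
    for (o in 0:(Tn - (L - 1))) {
      raw <- 2; al <- 2 * mult(g)
      for (j in 1:L) {
        if (j == g) next
        i <- if (j < g) o + L - j else o + L + 1 - j
        p <- pen_of(ptype(sv[j], tv[i]))
        raw <- raw + p; al <- al + p * mult(j)
      }
      add(o, "srna_bulge", g, raw, al)
    }
  }
  for (g in 1:(L - 1)) {             # bulged transcript base after g
    for (o in 0:(Tn - (L + 1))) {
      raw <- 2; al <- 2 * mult(g + 1)
      for (j in 1:L) {
        i <- if (j <= g) o + L + 2 - j else o + L + 1 - j
        p <- pen_of(ptype(sv[j], tv[i]))
        raw <- raw + p; al <- al + p * mult(j)
      }
      add(o, "t_bulge", g, raw, al)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(site_start = integer(0), gap_type = character(0),
               gap_pos = integer(0), allen = numeric(0), raw = numeric(0))
}
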