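test_that("phase-stat enumeration matches the stated position model", {
  hits <- tibble::tibble(start = c(0L, 21L, 42L), strand = "+",
                         length = 21L, abundance = 10)
  st <- enumerate_phase_stats(hits, 21, 0, 0, 231)
  expect_equal(st$k, 3L)
  expect_equal(st$n, 3L)
  expect_equal(st$m, 22L)
  expect_equal(st$N, 462L)
  expect_equal(st$P, 30)
  expect_equal(st$U, 0)

  # minus-strand 5' end at 19 has phase coordinate 21: register 0
  minus <- tibble::tibble(start = 19L - 20L + 21L - 21L, strand = "-",
                          length = 21L, abundance = 1)
  # leftmost = 5'end - (len-1) = -1; use a shifted window instead
  minus <- tibble::tibble(start = 20L, strand = "-", length = 21L,
                          abundance = 1)   # 5' end at 40, phase 42
  st2 <- enumerate_phase_stats(minus, 21, 0, 0, 231)
  expect_equal(st2$k, 1L)

  # empty window
  st3 <- enumerate_phase_stats(hits[0, ], 21, 0, 0, 231)
  expect_equal(st3$n, 0L)
  expect_equal(st3$P + st3$U, 0)

  expect_error(enumerate_phase_stats(hits, 21, 0, 0, 230),
               "multiple of the period")

  # the coarse register-class model
  stg <- enumerate_phase_stats(hits, 21, 0, 0, 231, position_model = "grid")
  expect_equal(stg$N, 42L)
  expect_equal(stg$m, 2L)
  expect_equal(stg$k, 1L)
  expect_equal(stg$n, 1L)
})

test_that("phase coordinates fold the minus-strand 2-nt overhang", {
  # 5' end of a minus-strand hit is its rightmost base
  expect_equal(phase_coord(0L, "-", 20L), 21L)   # 5' end 19 -> 21
  expect_equal(phase_coord(10L, "+", 21L), 10L)
})

test_that("the hypergeometric tail is exact", {
  expect_equal(phasing_pvalue(40, 10, 5, 5), choose(10, 5) / choose(40, 5))
  expect_equal(phasing_pvalue(462, 22, 5, 0), 1)
  # all positions drawn: the full tail is certain
  expect_equal(phasing_pvalue(20, 6, 20, 6), 1)
  expect_error(phasing_pvalue(40, 10, 5, 6), "k exceeds")
  expect_error(phasing_pvalue(40, 10, 0, 0), "at least 1")
})

test_that("hypergeometric tail agrees with full enumeration for N <= 12", {
  got <- numeric(0)
  want <- numeric(0)
  for (N in 2:12) {
    for (n in 1:N) {
      draws <- utils::combn(N, n)
      for (m in 1:N) {
        hits <- colSums(draws <= m)
        for (k in seq_len(min(n, m))) {
          got <- c(got, phasing_pvalue(N, m, n, k))
          want <- c(want, mean(hits >= k))
        }
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_gt(length(got), 2000)
})

test_that("hypergeometric tail agrees with Monte-Carlo for larger N", {
  set.seed(202)
  for (case in list(c(60, 12, 20, 6), c(50, 10, 15, 4))) {
    N <- case[1]; m <- case[2]; n <- case[3]; k <- case[4]
    draws <- replicate(1e5, sum(sample.int(N, n) <= m) >= k)
    phat <- mean(draws)
    se <- sqrt(phat * (1 - phat) / 1e5)
    expect_lt(abs(phasing_pvalue(N, m, n, k) - phat), 3 * se + 1e-12)
  }
})

test_that("the phasing score follows its closed form and monotonicities", {
  expect_equal(phasing_score(100, 0, 2), 0)
  expect_equal(phasing_score(100, 0, 5), 3 * log(1001))
  # doubling U strictly decreases the score at fixed P, k
  expect_lt(phasing_score(100, 20, 5), phasing_score(100, 10, 5))
  # increasing P or k never decreases it
  expect_gte(phasing_score(200, 10, 5), phasing_score(100, 10, 5))
  expect_gte(phasing_score(100, 10, 6), phasing_score(100, 10, 5))
})

make_phased_hits <- function(q, cycles, period = 21L, abundance = 20,
                             length = period) {
  tibble::tibble(tag_id = sprintf("p%02d", seq_len(cycles)),
                 chrom = "chr1",
                 start = q + (seq_len(cycles) - 1L) * period,
                 strand = "+", mismatches = 0L, length = length)
}

phased_tags <- function(hits, abundance = 20) {
  tibble::tibble(tag_id = hits$tag_id,
                 seq = vapply(seq_len(nrow(hits)), function(i)
                   rand_dna(hits$length[i]), character(1)),
                 length = hits$length, total = abundance,
                 lib1 = abundance)
}

test_that("a clean phased run is called as exactly one locus", {
  set.seed(9)
  hits <- make_phased_hits(105L, 10L)
  tags <- phased_tags(hits)
  cfg <- phas_config(multimap_phas = FALSE)
  loci <- suppressMessages(scan_phas(hits, tags, 21L,
                                     c(chr1 = 2000L), cfg))
  expect_equal(nrow(loci), 1)
  expect_equal(loci$register, 105L %% 21L)
  expect_equal(loci$start, 105L)
  expect_equal(loci$end, 105L + 10L * 21L)
  expect_lt(loci$p_value, 0.001)
  expect_gt(loci$phasing_score, 10)
  expect_equal(loci$dominant_length, 21L)
  expect_equal(loci$phased_fraction, 1)
})

test_that("wrong dominant length and short runs are rejected", {
  set.seed(10)
  # same positions but 20-nt reads: not the period length
  hits20 <- make_phased_hits(105L, 10L, length = 20L)
  tags20 <- phased_tags(hits20)
  cfg <- phas_config(multimap_phas = FALSE)
  expect_equal(nrow(suppressMessages(
    scan_phas(hits20, tags20, 21L, c(chr1 = 2000L), cfg))), 0)

  # 4 cycles span 84 bp <= 100: length filter rejects
  hits4 <- make_phased_hits(105L, 4L)
  tags4 <- phased_tags(hits4, abundance = 50)
  expect_equal(nrow(suppressMessages(
    scan_phas(hits4, tags4, 21L, c(chr1 = 2000L), cfg))), 0)

  # 5 cycles span 105 bp > 100: accepted
  hits5 <- make_phased_hits(105L, 5L)
  tags5 <- phased_tags(hits5, abundance = 50)
  expect_equal(nrow(suppressMessages(
    scan_phas(hits5, tags5, 21L, c(chr1 = 2000L), cfg))), 1)
})

test_that("the 30% phased-abundance filter is strict", {
  set.seed(11)
  cfg <- phas_config(multimap_phas = FALSE)
  base <- make_phased_hits(105L, 12L)
  # 12 in-register species at 5 = 60 phased; unphased ballast at seven
  # distinct non-zero residues totalling 140: fraction exactly 0.30
  off <- tibble::tibble(tag_id = sprintf("o%02d", 1:7), chrom = "chr1",
                        start = 105L + c(3L, 25L, 47L, 69L, 91L, 113L, 135L),
                        strand = "+", mismatches = 0L, length = 21L)
  hits <- dplyr::bind_rows(base, off)
  tags <- dplyr::bind_rows(phased_tags(base, abundance = 5),
                           phased_tags(off, abundance = 20))
  expect_equal(nrow(suppressMessages(
    scan_phas(hits, tags, 21L, c(chr1 = 2000L), cfg))), 0)
  # one extra phased read tips it above 30%
  tags2 <- tags
  tags2$total[1] <- 6
  loci <- suppressMessages(scan_phas(hits, tags2, 21L, c(chr1 = 2000L), cfg))
  expect_equal(nrow(loci), 1)
  expect_gt(loci$phased_fraction, 0.30)
})

test_that("locus calls are equivariant under a one-period shift", {
  set.seed(12)
  hits <- make_phased_hits(105L, 8L)
  tags <- phased_tags(hits)
  cfg <- phas_config(multimap_phas = FALSE)
  a <- suppressMessages(scan_phas(hits, tags, 21L, c(chr1 = 2000L), cfg))
  hits2 <- dplyr::mutate(hits, start = start + 21L)
  b <- suppressMessages(scan_phas(hits2, tags, 21L, c(chr1 = 2021L), cfg))
  expect_equal(b$start, a$start + 21L)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$phasing_score, a$phasing_score)
  expect_equal(b$register, a$register)
})

test_that("reverse-complementing the genome mirrors the loci", {
  study <- small_study(404)
  tags <- suppressMessages(collapse_reads(study$reads[c("library_id", "seq")]))
  genome <- study$sim$genome
  hits <- suppressMessages(align_tags(tags, genome))
  cfg <- phas_config()
  a <- suppressMessages(scan_phas(hits, tags, 21L,
                                  setNames(nchar(genome$seq), genome$id),
                                  cfg))
  rc <- tibble::tibble(id = genome$id,
                       seq = phasnet:::revcomp(genome$seq))
  hits_rc <- suppressMessages(align_tags(tags, rc))
  b <- suppressMessages(scan_phas(hits_rc, tags, 21L,
                                  setNames(nchar(rc$seq), rc$id), cfg))
  expect_equal(nrow(b), nrow(a))
  expect_true(all(b$p_value < 0.001) && all(b$phasing_score > 10))
  # the sliding-window grid is anchored at the chromosome origin, so the
  # per-locus maximum window score can shift by one cycle under mirroring;
  # spans mirror exactly: a phase coordinate x maps to glen + 1 - x, and the
  # span closes with one period on the other side
  glen <- nchar(genome$seq)
  expect_equal(sort(glen + 22L - b$end), sort(a$start))
  expect_equal(sort(glen + 22L - b$start), sort(a$end))
  expect_equal(sort(b$period), sort(a$period))
})

test_that("top phasiRNA selection ranks by abundance with coordinate ties", {
  phasi <- tibble::tibble(seq = replicate(40, rand_dna(21)),
                          position = seq(0, by = 21, length.out = 40),
                          strand = "+",
                          abundance = c(rep(100, 5), rep(50, 35)))
  locus <- tibble::tibble(phasirnas = list(phasi))
  top <- top_phasirnas(locus, 30L)
  expect_equal(nrow(top), 30)
  # tie block: lower coordinates win the tail ranks
  tied <- top[top$abundance == 50, ]
  expect_equal(tied$position, sort(tied$position))
  expect_equal(max(tied$position), (5 + 25 - 1) * 21)

  few <- top_phasirnas(tibble::tibble(phasirnas = list(phasi[1:5, ])), 30L)
  expect_equal(nrow(few), 5)
})
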