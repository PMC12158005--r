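revcomp_chr <- function(x) phasnet:::revcomp(x)

test_that("perfect and near-perfect duplexes score as the Allen scheme dictates", {
  set.seed(21)
  srna <- rand_dna(21)
  tx <- paste0(rand_dna(50), revcomp_chr(srna), rand_dna(50))
  sites <- find_candidate_sites(srna, tx)
  perfect <- sites[sites$allen == 0, ]
  expect_equal(nrow(perfect), 1)
  expect_equal(perfect$site_start, 50)
  expect_equal(perfect$mfe_ratio, 1.0)
  expect_equal(allen_score(perfect[1, ]), 0)
  expect_equal(mfe_ratio(perfect[1, ]), 1.0)
})

test_that("G:U and mismatch penalties double inside positions 2-13", {
  # an sRNA ending in ...G paired with a site whose opposite base is T gives
  # a G:U wobble exactly at the chosen position
  make_site <- function(srna, pos, new_base) {
    site <- revcomp_chr(srna)
    # sRNA position j pairs site position L + 1 - j (1-based)
    L <- nchar(srna)
    i <- L + 1 - pos
    substr(site, i, i) <- new_base
    site
  }
  srna <- paste(rep("A", 21), collapse = "")          # pairs T everywhere
  srna <- "AAGAAAAAAAAAAAGAAAAAA"                     # G at 3 and 15
  # G:U at position 15: sRNA G opposite T(U) -> 0.5, outside the 2-13 window
  site15 <- make_site(srna, 15, "T")
  d15 <- find_candidate_sites(srna, site15)
  expect_equal(min(d15$allen), 0.5)
  # the same wobble at position 3 doubles to 1.0
  srna3 <- "AAGAAAAAAAAAAAAAAAAAA"
  site3 <- make_site(srna3, 3, "T")
  d3 <- find_candidate_sites(srna3, site3)
  expect_equal(min(d3$allen), 1.0)
  # mismatch at 3 (doubled) plus G:U at 20 (not doubled): 2.5
  srna_m <- "AAGAAAAAAAAAAAAAAAAGA"
  site_m <- make_site(srna_m, 20, "T")        # G:U at 20
  site_m <- local({ s <- site_m; i <- 21 + 1 - 3; substr(s, i, i) <- "A"; s })
  d_m <- find_candidate_sites(srna_m, site_m)
  expect_equal(min(d_m$allen), 2.5)
})

test_that("the MFE ratio follows the simplified pair-energy model", {
  # 21-mer with perfect energy -50: 8 G/C (-3 each = -24) + 13 A/T (-2 each)
  srna <- paste(c(rep("G", 8), rep("A", 13)), collapse = "")
  expect_equal(phasnet:::perfect_energy(srna), -50)
  site <- revcomp_chr(srna)
  # knock out one GC pair (mismatch): energy -47, ratio 0.94
  substr(site, 21, 21) <- "A"    # pairs sRNA position 1 (G)
  d <- find_candidate_sites(srna, site)
  expect_equal(min(d$allen), 1)  # mismatch at position 1 is not doubled
  best <- d[which.min(d$allen), ]
  expect_equal(best$mfe_ratio, 47 / 50)
  # an all-mismatch duplex has ratio 0
  pairs <- tibble::tibble(srna_pos = 1:21,
                          srna_base = strsplit(srna, "")[[1]],
                          site_base = strsplit(srna, "")[[1]],
                          class = "mismatch")
  expect_equal(mfe_ratio(pairs), 0)
})

test_that("candidate search reports planted sites 5'-most first", {
  set.seed(22)
  srna <- rand_dna(21)
  tx <- paste0(rand_dna(30), revcomp_chr(srna), rand_dna(40),
               revcomp_chr(srna), rand_dna(30))
  sites <- find_candidate_sites(srna, tx)
  hits0 <- sites[sites$allen == 0, ]
  expect_equal(hits0$site_start, c(30, 91))

  # a random 21-mer against a random 1-kb transcript is typically empty
  empties <- vapply(1:5, function(i) {
    nrow(find_candidate_sites(rand_dna(21), rand_dna(1000)))
  }, numeric(1))
  expect_lt(stats::median(empties), 1)
})

test_that("the duplex engine matches a naive enumeration oracle", {
  set.seed(23)
  for (rep in 1:4) {
    srna <- rand_dna(sample(19:22, 1))
    tx <- paste0(rand_dna(40), revcomp_chr(srna), rand_dna(40))
    # add mutations so near-threshold alignments appear
    tx_v <- strsplit(tx, "")[[1]]
    for (p in sample(41:(40 + nchar(srna)), 2)) {
      tx_v[p] <- sample(c("A", "C", "G", "T"), 1)
    }
    tx <- paste(tx_v, collapse = "")
    got <- find_candidate_sites(srna, tx, max_raw = 4)
    want <- oracle_duplex_scan(srna, tx, max_raw = 4)
    key <- function(d) {
      k <- sprintf("%d|%s|%s|%.3f|%.3f", d$site_start, d$gap_type,
                   ifelse(is.na(d$gap_pos), "-", d$gap_pos), d$allen, d$raw)
      sort(k)
    }
    expect_equal(key(got), key(want))
  }
})

test_that("scores are invariant under transcript coordinate shifts", {
  set.seed(24)
  srna <- rand_dna(21)
  core <- paste0(rand_dna(10), revcomp_chr(srna), rand_dna(10))
  shifted <- paste0(rand_dna(37), core)
  a <- find_candidate_sites(srna, core)
  b <- find_candidate_sites(srna, shifted)
  a0 <- a[which.min(a$allen), ]
  b0 <- b[which.min(b$allen), ]
  expect_equal(b0$site_start, a0$site_start + 37)
  expect_equal(b0$allen, a0$allen)
  expect_equal(b0$mfe_ratio, a0$mfe_ratio)
})

test_that("target acceptance applies both published thresholds strictly", {
  set.seed(25)
  srna <- rand_dna(21)
  tx_good <- paste0(rand_dna(20), revcomp_chr(srna), rand_dna(20))
  cfg <- phas_config()
  good <- predict_targets(tibble::tibble(id = "s", seq = srna),
                          tibble::tibble(id = "t", seq = tx_good), cfg)
  expect_true(good$accepted)
  expect_equal(good$cleavage_pos, 20 + 21 - 10)

  # exactly 7.0: seven mismatches outside the doubled window
  srna7 <- paste(rep("A", 21), collapse = "")
  site7 <- revcomp_chr(srna7)
  for (i in 21 + 1 - c(1, 14, 15, 16, 17, 18, 19)) {
    substr(site7, i, i) <- "C"
  }
  tx7 <- paste0(rand_dna(20), site7, rand_dna(20))
  out7 <- predict_targets(tibble::tibble(id = "s", seq = srna7),
                          tibble::tibble(id = "t", seq = tx7),
                          phas_config(site_max_raw = 7))
  expect_equal(out7$allen_score, 7.0)
  expect_false(out7$accepted)

  # MFE ratio exactly at the cut-off is rejected while the Allen score
  # still passes: an 18G+3A 21-mer has perfect energy -60; six G:U wobbles
  # (energy -1 each, penalty 0.5) and three G:G mismatches (energy 0,
  # penalty 1) at undoubled positions lose exactly 21 units:
  # ratio 39/60 = 0.65, Allen score 6 < 7
  srna_r <- paste(ifelse(seq_len(21) %in% c(5, 9, 12), "A", "G"),
                  collapse = "")
  site_r <- revcomp_chr(srna_r)
  gu_pos <- c(1, 14, 15, 16, 17, 18)
  mm_pos <- c(19, 20, 21)
  for (j in gu_pos) substr(site_r, 22 - j, 22 - j) <- "T"
  for (j in mm_pos) substr(site_r, 22 - j, 22 - j) <- "G"
  out_r <- predict_targets(tibble::tibble(id = "s", seq = srna_r),
                           tibble::tibble(id = "t", seq = site_r),
                           phas_config(site_max_raw = 8))
  expect_equal(out_r$allen_score, 6)
  expect_equal(out_r$mfe_ratio, 0.65)
  expect_false(out_r$accepted)
})

test_that("trigger assignment honours the inclusive penalty cut-off", {
  set.seed(26)
  sim <- make_genome(6000, seed = 26)
  mir <- rand_dna(21)
  sim <- plant_phas(sim, period = 21L, cycles = 11L, trigger = mir,
                    at = 2000L, id = "p1")
  locus <- tibble::tibble(locus_id = "PHAS21-1", chrom = "chr1",
                          start = 2000L, end = 2000L + 231L, period = 21L,
                          register = 2000L %% 21L)
  trig <- identify_triggers(tibble::tibble(id = "mir1", seq = mir),
                            locus, sim$genome)
  expect_equal(nrow(trig), 1)
  expect_equal(trig$penalty, 0)
  expect_true(trig$in_register)
  expect_equal(trig$cleavage_coord, 2000L)

  # penalty exactly 5 is reported; 5.5 is not
  mir5 <- paste(rep("A", 21), collapse = "")
  site5 <- revcomp_chr(mir5)
  for (i in 21 + 1 - c(14:18)) substr(site5, i, i) <- "C"   # five mismatches
  g5 <- paste0(rand_dna(300), site5, rand_dna(300))
  t5 <- identify_triggers(
    tibble::tibble(id = "m", seq = mir5),
    tibble::tibble(locus_id = "L", chrom = "chr1", start = 310L, end = 320L,
                   period = 21L, register = 0L),
    tibble::tibble(id = "chr1", seq = g5))
  expect_equal(t5$penalty, 5)

  site55 <- revcomp_chr(mir5)
  for (i in 21 + 1 - c(14:17)) substr(site55, i, i) <- "C"  # 4 mismatches
  substr(site55, 21 + 1 - 13, 21 + 1 - 13) <- "C"           # +1 doubled = 6
  g55 <- paste0(rand_dna(300), site55, rand_dna(300))
  t55 <- identify_triggers(
    tibble::tibble(id = "m", seq = mir5),
    tibble::tibble(locus_id = "L", chrom = "chr1", start = 310L, end = 320L,
                   period = 21L, register = 0L),
    tibble::tibble(id = "chr1", seq = g55))
  expect_equal(nrow(t55), 0)
})

test_that("planted triggers are recovered in register; decoys stay clean", {
  hits <- 0L; misses <- 0L; decoy_hits <- 0L
  for (seed in 501:505) {
    study <- small_study(seed)
    truth <- study$sim$phas
    mirs <- tibble::tibble(id = study$sim$mir$id,
                           seq = study$sim$mir$mature_seq)
    loci <- tibble::tibble(locus_id = truth$id, chrom = truth$chrom,
                           start = truth$start, end = truth$end,
                           period = truth$period,
                           register = truth$register)
    trig <- suppressMessages(identify_triggers(mirs, loci,
                                               study$sim$genome))
    for (i in which(!is.na(truth$trigger_id))) {
      row <- trig[trig$phas_id == truth$id[i] &
                    trig$mirna_id == truth$trigger_id[i], ]
      if (nrow(row) == 1 && row$in_register) hits <- hits + 1L
      else misses <- misses + 1L
    }
    decoys <- truth$id[is.na(truth$trigger_id)]
    decoy_hits <- decoy_hits + sum(trig$phas_id %in% decoys)
  }
  expect_equal(misses, 0L)
  expect_equal(decoy_hits, 0L)
})
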