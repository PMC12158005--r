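test_that("candidate clustering splits stacks by the gap rule", {
  mk <- function(start) tibble::tibble(tag_id = paste0("t", start),
                                       chrom = "chr1", start = start,
                                       strand = "+", mismatches = 0L,
                                       length = 21L)
  close_by <- dplyr::bind_rows(mk(100L), mk(150L))
  expect_equal(nrow(cluster_candidate_loci(close_by, 200L)), 1)
  far <- dplyr::bind_rows(mk(100L), mk(600L))
  expect_equal(nrow(cluster_candidate_loci(far, 200L)), 2)
  expect_equal(nrow(cluster_candidate_loci(close_by[0, ], 200L)), 0)
  # opposite strands never cluster together
  two_str <- dplyr::bind_rows(mk(100L),
                              dplyr::mutate(mk(130L), strand = "-"))
  expect_equal(nrow(cluster_candidate_loci(two_str, 200L)), 2)
})

test_that("duplex evaluation recovers a planted hairpin and rejects bad geometry", {
  set.seed(5)
  sim <- make_genome(4000, seed = 5)
  sim <- plant_mir(sim, star_gap = 40L, at = 1000L, id = "m1")
  truth <- sim$mir
  stack <- tibble::tibble(
    tag_id = c("mat", "star"),
    seq = c(truth$mature_seq, truth$star_seq),
    start = c(truth$mature_start, truth$star_start),
    length = c(nchar(truth$mature_seq), nchar(truth$star_seq)),
    total = c(80L, 15L))
  d <- evaluate_duplex(stack)
  expect_true(d$valid)
  expect_equal(d$mature$tag_id, "mat")
  expect_equal(d$star$tag_id, "star")
  expect_lte(d$unpaired, 5)

  # a 19-nt "mature" is not of legal length
  stack19 <- stack
  stack19$seq[1] <- substr(stack19$seq[1], 1, 19)
  stack19$length[1] <- 19L
  stack19$total[2] <- 5L
  d19 <- evaluate_duplex(stack19[1, ])
  expect_false(d19$valid)
  expect_equal(d19$reason, "no_tag_of_legal_length")

  # star 4 nt from the mature violates the 5-300 spacing window
  stack4 <- stack
  stack4$start[2] <- stack4$start[1] + stack4$length[1] + 4L
  d4 <- evaluate_duplex(stack4)
  expect_false(d4$valid)
  expect_equal(d4$reason, "no_star_in_spacing_window")

  # spacing of exactly 5 nt is allowed
  stack5 <- stack
  stack5$start[2] <- stack5$start[1] + stack5$length[1] + 5L
  expect_true(evaluate_duplex(stack5)$valid)
})

test_that("the 75% duplex-abundance rule is applied with its boundary", {
  sim <- make_genome(4000, seed = 6)
  sim <- plant_mir(sim, star_gap = 30L, at = 1500L, id = "m1")
  truth <- sim$mir
  lm <- nchar(truth$mature_seq)
  mk_cand <- function(other_total) {
    other_seq <- substr(sim$genome$seq, truth$mature_start + 6L,
                        truth$mature_start + 6L + 20L)
    stack <- tibble::tibble(
      tag_id = c("mat", "star", "oth"),
      seq = c(truth$mature_seq, truth$star_seq, other_seq),
      start = c(truth$mature_start, truth$star_start,
                truth$mature_start + 5L),
      length = c(lm, nchar(truth$star_seq), 21L),
      total = c(70L, 10L, other_total))
    tibble::tibble(candidate_id = "c1", chrom = "chr1", strand = "+",
                   start = min(stack$start),
                   end = max(stack$start + stack$length),
                   hits = list(stack))
  }
  accept <- mk_cand(20L)     # 80/100 = 0.80
  d <- evaluate_duplex(accept$hits[[1]])
  expect_true(d$valid)
  loc <- call_mir_locus(accept, d)
  expect_equal(loc$duplex_fraction, 0.80)

  reject <- mk_cand(30L + 4L + 9L)  # 80/(80 + 43) < 0.75 -> hmm exact below
  d2 <- evaluate_duplex(reject$hits[[1]])
  expect_null(call_mir_locus(reject, d2))

  # exactly 75% is accepted ("at least 75%"): 75/(75+25)
  border <- mk_cand(floor(80 / 3))   # 80/(80+26.66) no; build exact instead
  border$hits[[1]]$total <- c(65L, 10L, 25L)
  d3 <- evaluate_duplex(border$hits[[1]])
  loc3 <- call_mir_locus(border, d3)
  expect_equal(loc3$duplex_fraction, 0.75)

  # no other reads -> fraction 1
  solo <- mk_cand(0L)
  solo$hits[[1]] <- solo$hits[[1]][1:2, ]
  d4 <- evaluate_duplex(solo$hits[[1]])
  expect_equal(call_mir_locus(solo, d4)$duplex_fraction, 1.0)
})

test_that("naming maps to known families and numbers novels deterministically", {
  known <- tibble::tibble(id = c("gbi-miR159a", "gbi-miR396b"),
                          seq = c("TTTGGATTGAAGGGAGCTCTA",
                                  "TTCCACAGCTTTCTTGAACTG"))
  exact <- known$seq[1]
  mism3 <- exact
  for (p in c(2, 9, 17)) {
    substr(mism3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mism3, p, p))[1]
  }
  novel2 <- "GGGGGGGGGGCCCCCCCCCCG"
  nm <- assign_name(c(exact, mism3, novel2), known)
  expect_equal(nm$family[1], "miR159")
  expect_false(nm$novel[1])
  expect_equal(nm$name[2], "miRN1")
  expect_true(nm$novel[2])
  expect_equal(nm$name[3], "miRN2")

  # within 2 mismatches and +/-1 length still maps to the family
  near <- substr(exact, 1, 20)
  substr(near, 5, 5) <- "A"
  nm2 <- assign_name(near, known)
  expect_false(nm2$novel)

  # no reference: everything is novel, numbered in input order,
  # repeated sequences share a name
  nm3 <- assign_name(c(novel2, exact, novel2), NULL)
  expect_equal(nm3$name, c("miRN1", "miRN2", "miRN1"))
})

test_that("MIR calling is invariant to hit row order", {
  study <- small_study(301)
  tags <- suppressMessages(collapse_reads(study$reads[c("library_id", "seq")]))
  hits <- suppressMessages(align_tags(tags, study$sim$genome))
  mir1 <- suppressMessages(call_mirnas(hits, tags, study$known_mirnas))
  set.seed(1)
  hits_shuf <- hits[sample(nrow(hits)), ]
  mir2 <- suppressMessages(call_mirnas(hits_shuf, tags, study$known_mirnas))
  expect_equal(mir1, mir2)
})

test_that("every accepted locus satisfies the numeric acceptance criteria", {
  study <- small_study(77)
  tags <- suppressMessages(collapse_reads(study$reads[c("library_id", "seq")]))
  hits <- suppressMessages(align_tags(tags, study$sim$genome))
  mir <- suppressMessages(call_mirnas(hits, tags, study$known_mirnas))
  expect_gt(nrow(mir), 0)
  expect_true(all(mir$duplex_fraction >= 0.75))
  expect_true(all(nchar(mir$mature_seq) >= 20 & nchar(mir$mature_seq) <= 22))
  gap <- abs(mir$star_start - (mir$mature_start + nchar(mir$mature_seq)))
  gap2 <- abs(mir$mature_start - (mir$star_start + nchar(mir$star_seq)))
  expect_true(all(pmin(gap, gap2) >= 5 & pmin(gap, gap2) <= 300))
})

test_that("the probably flag uses strict RP10M < 10 with the all-library rule", {
  loci <- tibble::tibble(locus_id = c("MIR001", "MIR002", "MIR003"),
                         mature_tag = c("t1", "t2", "t3"))
  expr <- tibble::tibble(feature_id = c("t1", "t2", "t3"),
                         l1 = c(50, 9.9, 10), l2 = c(3, 5, 2))
  out <- flag_probably(loci, expr)
  expect_equal(out$probably, c(FALSE, TRUE, FALSE))  # 10 exactly: not < 10
  out_any <- flag_probably(loci, expr, phas_config(probably_mode = "any"))
  expect_equal(out_any$probably, c(TRUE, TRUE, TRUE))
})
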