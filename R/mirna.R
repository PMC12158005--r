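# Watson-Crick or G:U wobble classification of a single sRNA/partner base
# pair (DNA alphabet, T standing for U).
pair_type <- function(a, b) {
  wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

#' Cluster aligned tags into candidate loci
#'
#' Groups same-strand hits into maximal intervals in which consecutive tag
#' starts are at most `max_gap` apart. Candidate assembly precedes all MIR
#' acceptance criteria; the gap default (200 nt) merely has to exceed the
#' largest mature/star spacing contribution while splitting distant stacks.
#'
#' @param hits hit tibble from [align_tags()].
#' @param max_gap maximum start-to-start gap within a candidate.
#' @return tibble with one row per candidate (`candidate_id`, `chrom`,
#'   `strand`, `start`, `end`) and a nested `hits` list-column.
#' @export
cluster_candidate_loci <- function(hits, max_gap = 200L) {
  if (nrow(hits) == 0) {
    return(tibble(candidate_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  hits = list()))
  }
  hits <- hits[order(hits$chrom, hits$strand, hits$start), ]
  out <- hits |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::mutate(block = cumsum(c(0L, diff(.data$start) > max_gap))) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$block) |>
    tidyr::nest(hits = -c("chrom", "strand", "block")) |>
    dplyr::ungroup()
  out$start <- vapply(out$hits, function(h) min(h$start), integer(1))
  out$end <- vapply(out$hits, function(h) max(h$start + h$length), integer(1))
  out <- out[order(out$chrom, out$start, out$strand), ]
  out$candidate_id <- sprintf("cand%04d", seq_len(nrow(out)))
  out[c("candidate_id", "chrom", "strand", "start", "end", "hits")]
}

# Count mature positions that fail to form a Watson-Crick or G:U pair with
# the star under the canonical Dicer duplex register (2-nt 3' overhangs):
# mature position i pairs star position Lm - 1 - i. The two 3'-overhang
# positions are structurally unpaired and count toward the total.
duplex_unpaired <- function(mature, star) {
  lm <- nchar(mature); ls <- nchar(star)
  mv <- strsplit(mature, "", fixed = TRUE)[[1]]
  sv <- strsplit(star, "", fixed = TRUE)[[1]]
  i <- seq_len(lm)
  j <- lm - 1L - i
  valid <- j >= 1L & j <= ls
  unp <- sum(!valid)
  if (any(valid)) {
    pt <- pair_type(mv[i[valid]], sv[j[valid]])
    unp <- unp + sum(pt == "mismatch")
  }
  unp
}

#' Evaluate the mature/star duplex of a candidate locus
#'
#' The mature is the most abundant tag of legal length (20-22 nt); the star
#' is the co-clustered tag that best pairs with it under the hairpin duplex
#' register with 2-nt 3' overhangs. The duplex is valid when the inner
#' mature-star spacing lies in the 5-300 nt window, the mature length is
#' 20-22 nt, and at most `max_unpaired` mature positions (default 5,
#' including the two overhang positions) fail to pair.
#'
#' Duplex validity is assessed by direct mature:star complementarity
#' (Watson-Crick plus G:U) rather than a full thermodynamic fold; the
#' pairing register is fixed by the Dicer 2-nt overhang geometry.
#'
#' @param stack tibble of the candidate's tags: columns `tag_id`, `seq`,
#'   `start`, `length`, `total`.
#' @param config a [phas_config()].
#' @return list with `valid`, `reason`, `mature`, `star` (rows of `stack`)
#'   and `unpaired`.
#' @export
evaluate_duplex <- function(stack, config = phas_config()) {
  stack <- dplyr::distinct(stack, .data$tag_id, .keep_all = TRUE)
  legal <- stack$length >= config$mature_len[1] &
           stack$length <= config$mature_len[2]
  if (!any(legal)) {
    return(list(valid = FALSE, reason = "no_tag_of_legal_length",
                mature = NULL, star = NULL, unpaired = NA_integer_))
  }
  cand_m <- stack[legal, ]
  mature <- cand_m[order(-cand_m$total, cand_m$start), ][1, ]
  others <- stack[stack$tag_id != mature$tag_id, , drop = FALSE]
  if (nrow(others) == 0) {
    return(list(valid = FALSE, reason = "star_unsequenced",
                mature = mature, star = NULL, unpaired = NA_integer_))
  }
  m_start <- mature$start; m_end <- mature$start + mature$length
  gap <- ifelse(others$start >= m_end, others$start - m_end,
                ifelse(m_start >= others$start + others$length,
                       m_start - (others$start + others$length), -1L))
  spaced <- gap >= config$star_spacing[1] & gap <= config$star_spacing[2]
  if (!any(spaced)) {
    return(list(valid = FALSE, reason = "no_star_in_spacing_window",
                mature = mature, star = NULL, unpaired = NA_integer_))
  }
  cand_s <- others[spaced, ]
  unp <- vapply(cand_s$seq, duplex_unpaired, integer(1), mature = mature$seq)
  best <- order(unp, -cand_s$total)[1]
  star <- cand_s[best, ]
  list(valid = unp[best] <= config$max_unpaired,
       reason = if (unp[best] <= config$max_unpaired) NA_character_
                else "duplex_too_unpaired",
       mature = mature, star = star, unpaired = as.integer(unp[best]))
}

#' Apply the duplex-abundance criterion and build a MIR locus record
#'
#' A candidate is accepted when the combined abundance of the mature and
#' star (matched with a +/-1-nt isomiR tolerance at both ends) makes up at
#' least 75\% of all reads in the locus.
#'
#' @param candidate one row of [cluster_candidate_loci()] output.
#' @param duplex result of [evaluate_duplex()] on that candidate's stack.
#' @param config a [phas_config()].
#' @return a one-row locus tibble, or `NULL` when rejected.
#' @export
call_mir_locus <- function(candidate, duplex, config = phas_config()) {
  if (!isTRUE(duplex$valid)) return(NULL)
  stack <- candidate$hits[[1]]
  tol <- config$isomir_tol
  near <- function(ref) {
    abs(stack$start - ref$start) <= tol &
      abs((stack$start + stack$length) - (ref$start + ref$length)) <= tol
  }
  dup_ab <- sum(stack$total[near(duplex$mature) | near(duplex$star)])
  frac <- dup_ab / sum(stack$total)
  if (frac < config$duplex_fraction) return(NULL)
  tibble(
    chrom = candidate$chrom, strand = candidate$strand,
    start = candidate$start, end = candidate$end,
    mature_seq = duplex$mature$seq, mature_start = duplex$mature$start,
    mature_tag = duplex$mature$tag_id,
    star_seq = duplex$star$seq, star_start = duplex$star$start,
    duplex_fraction = frac, unpaired = duplex$unpaired
  )
}

#' Name mature miRNAs against a known-miRNA reference
#'
#' A mature sequence inherits the family of its best reference match when it
#' is within 2 mismatches and within 1 nt of the reference length (ties:
#' fewest mismatches, then lexicographic reference id). Sequences with no
#' qualifying match are novel and receive fresh `miRN<k>` names in input
#' (genomic) order, one number per distinct novel sequence. Naming is a pure
#' function of the sequence set and the reference.
#'
#' @param mature_seqs character vector of mature sequences in genomic order.
#' @param known tibble from [read_fasta()] of known mature miRNAs (may be
#'   empty or NULL).
#' @param config a [phas_config()].
#' @return tibble with `name`, `family`, `novel`.
#' @export
assign_name <- function(mature_seqs, known = NULL, config = phas_config()) {
  n <- length(mature_seqs)
  fam <- rep(NA_character_, n); nm <- rep(NA_character_, n)
  novel <- rep(TRUE, n)
  if (!is.null(known) && nrow(known) > 0) {
    kid <- known$id[order(known$id)]
    kseq <- known$seq[order(known$id)]
    for (i in seq_len(n)) {
      d <- vapply(kseq, seq_dist, numeric(1), a = mature_seqs[i],
                  max_shift = 1L)
      if (min(d) <= config$naming_max_mismatch) {
        best <- which.min(d)  # ties: fewest mismatches then lexicographic id
        hit <- kid[best]
        m <- stringr::str_match(hit, stringr::regex("(miRN?[0-9]+)",
                                                    ignore_case = TRUE))[, 2]
        fam[i] <- if (is.na(m)) hit else m
        nm[i] <- hit
        novel[i] <- FALSE
      }
    }
  }
  if (any(novel)) {
    distinct_novel <- unique(mature_seqs[novel])
    k <- match(mature_seqs[novel], distinct_novel)
    fam[novel] <- sprintf("miRN%d", k)
    nm[novel] <- fam[novel]
  }
  tibble(name = nm, family = fam, novel = novel)
}

#' Call MIR loci from aligned tag stacks
#'
#' Runs the full MIR annotation: multi-mapping filter (more than
#' `max_genome_hits` placements), candidate clustering, mature/star duplex
#' evaluation, the 75\% duplex-abundance rule, and naming against a known
#' reference.
#'
#' @param hits hit tibble from [align_tags()].
#' @param tags tag tibble from [collapse_reads()].
#' @param known optional known-miRNA reference tibble ([read_fasta()]).
#' @param config a [phas_config()].
#' @return tibble of accepted MIR loci in genomic order, one row per locus,
#'   with mature/star evidence, `duplex_fraction`, `family`, `novel` and a
#'   `locus_id`.
#' @export
call_mirnas <- function(hits, tags, known = NULL, config = phas_config()) {
  hits <- filter_multimap(hits, config$max_genome_hits)
  hits <- dplyr::left_join(hits, tags[c("tag_id", "seq", "total")],
                           by = "tag_id")
  cands <- cluster_candidate_loci(hits, config$candidate_gap)
  loci <- vector("list", 0)
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, ]
    duplex <- evaluate_duplex(cand$hits[[1]], config)
    row <- call_mir_locus(cand, duplex, config)
    if (!is.null(row)) loci[[length(loci) + 1]] <- row
  }
  if (length(loci) == 0) {
    pn_log("call_mirnas", "0 loci accepted from %d candidates", nrow(cands))
    return(tibble(locus_id = character(0), name = character(0),
                  family = character(0), novel = logical(0),
                  chrom = character(0), strand = character(0),
                  start = integer(0), end = integer(0),
                  mature_seq = character(0), mature_start = integer(0),
                  mature_tag = character(0), star_seq = character(0),
                  star_start = integer(0), duplex_fraction = numeric(0),
                  unpaired = integer(0)))
  }
  out <- dplyr::bind_rows(loci)
  out <- out[order(out$chrom, out$start), ]
  nm <- assign_name(out$mature_seq, known, config)
  out <- dplyr::bind_cols(tibble(locus_id = sprintf("MIR%03d",
                                                    seq_len(nrow(out)))),
                          nm, out)
  pn_log("call_mirnas", "%d loci accepted from %d candidates",
         nrow(out), nrow(cands))
  out
}

#' Flag lowly expressed miRNA annotations as "probably"
#'
#' @param loci MIR locus tibble from [call_mirnas()].
#' @param rp10m expression tibble (`feature_id` + one RP10M column per
#'   library) whose feature ids are the mature tag ids of `loci`.
#' @param config a [phas_config()]; `probably_mode = "all"` (default) flags
#'   a locus only when RP10M stays below `min_rp10m` in every library,
#'   `"any"` when any single library falls below the cut-off. A library at
#'   exactly the cut-off never triggers the flag (strict `<`).
#' @return `loci` with a logical `probably` column.
#' @export
flag_probably <- function(loci, rp10m, config = phas_config()) {
  libs <- setdiff(names(rp10m), "feature_id")
  idx <- match(loci$mature_tag, rp10m$feature_id)
  if (anyNA(idx)) {
    stop("mature tag(s) missing from expression table: ",
         paste(loci$mature_tag[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(rp10m[idx, libs, drop = FALSE])
  below <- mat < config$min_rp10m
  loci$probably <- if (config$probably_mode == "all") {
    apply(below, 1, all)
  } else {
    apply(below, 1, any)
  }
  loci
}
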