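#' Align sequence tags to a genome
#'
#' End-to-end ungapped alignment of 18-34 nt tags with up to `max_mismatches`
#' substitutions (Hamming distance, no indels), reporting *all* placements on
#' both strands. The search is a pigeonhole seed-and-extend: each tag is cut
#' into `max_mismatches + 1` segments, any alignment within the mismatch
#' budget must contain at least one segment exactly, exact segment hits are
#' found with a `Biostrings` PDict dictionary, and every candidate diagonal
#' is verified by direct base comparison. The result is therefore identical
#' to a brute-force Hamming scan over every genome window, in canonical
#' (chrom, start, strand) order.
#'
#' @param tags tag tibble with `tag_id` and `seq` columns.
#' @param genome tibble from [read_fasta()].
#' @param max_mismatches maximum substitutions per alignment (default 2).
#' @return tibble with `tag_id`, `chrom`, `start` (0-based), `strand`,
#'   `mismatches` and `length`. Minus-strand hits report the leftmost
#'   forward-strand coordinate.
#' @export
align_tags <- function(tags, genome, max_mismatches = 2L) {
  ok <- !grepl("[^ACGT]", tags$seq)
  if (!all(ok)) {
    warning(sum(!ok), " tag(s) with ambiguous bases skipped by alignment",
            call. = FALSE)
    tags <- tags[ok, , drop = FALSE]
  }
  empty <- tibble(tag_id = character(0), chrom = character(0),
                  start = integer(0), strand = character(0),
                  mismatches = integer(0), length = integer(0))
  if (nrow(tags) == 0 || nrow(genome) == 0) return(empty)

  res <- vector("list", 0)
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$id[ci]
    cseq <- genome$seq[ci]
    subject <- Biostrings::DNAString(cseq)
    glen <- nchar(cseq)
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") tags$seq else revcomp(tags$seq)
      by_len <- split(seq_along(qseq), nchar(qseq))
      for (idx in by_len) {
        L <- nchar(qseq[idx[1]])
        if (L > glen) next
        hits <- match_length_group(qseq[idx], L, subject, cseq, glen,
                                   max_mismatches)
        if (nrow(hits) == 0) next
        res[[length(res) + 1]] <- tibble(
          tag_id = tags$tag_id[idx[hits$qi]],
          chrom = chrom, start = hits$start0, strand = strand,
          mismatches = hits$mm, length = L)
      }
    }
  }
  if (length(res) == 0) return(empty)
  out <- dplyr::bind_rows(res)
  out <- out[order(out$chrom, out$start, out$strand, out$tag_id), ]
  pn_log("align_tags", "%d hits for %d tags", nrow(out),
         length(unique(out$tag_id)))
  out
}

# Seed-and-extend for one (strand, length) group against one chromosome.
# Returns tibble(qi, start0, mm) with qi indexing into `patterns`.
match_length_group <- function(patterns, L, subject, cseq, glen,
                               max_mismatches) {
  nseg <- max_mismatches + 1L
  bounds <- as.integer(round(seq(0, L, length.out = nseg + 1L)))
  cand_qi <- integer(0)
  cand_s0 <- integer(0)
  for (s in seq_len(nseg)) {
    off <- bounds[s]
    w <- bounds[s + 1L] - off
    segs <- Biostrings::DNAStringSet(substr(patterns, off + 1L, off + w))
    m <- Biostrings::matchPDict(Biostrings::PDict(segs), subject)
    starts <- Biostrings::startIndex(m)
    n_per <- lengths(starts)
    if (sum(n_per) == 0) next
    cand_qi <- c(cand_qi, rep.int(seq_along(patterns), n_per))
    cand_s0 <- c(cand_s0, unlist(starts, use.names = FALSE) - 1L - off)
  }
  keep <- cand_s0 >= 0L & cand_s0 + L <= glen
  cand_qi <- cand_qi[keep]; cand_s0 <- cand_s0[keep]
  if (length(cand_qi) == 0) {
    return(tibble(qi = integer(0), start0 = integer(0), mm = integer(0)))
  }
  dup <- duplicated(cbind(cand_qi, cand_s0))
  cand_qi <- cand_qi[!dup]; cand_s0 <- cand_s0[!dup]
  # verify candidates by direct comparison on the forward strand
  windows <- substring(cseq, cand_s0 + 1L, cand_s0 + L)
  wmat <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                 ncol = L, byrow = TRUE)
  pmat <- matrix(unlist(strsplit(patterns[cand_qi], "", fixed = TRUE),
                        use.names = FALSE), ncol = L, byrow = TRUE)
  mm <- as.integer(rowSums(wmat != pmat))
  ok <- mm <= max_mismatches
  tibble(qi = cand_qi[ok], start0 = cand_s0[ok], mm = mm[ok])
}
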