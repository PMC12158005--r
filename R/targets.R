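# Base coding and pair lookup tables for the duplex engine. Codes: A=1, C=2,
# G=3, T=4, anything else 5 (always a mismatch). Rows: sRNA base; columns:
# transcript base. Penalties follow the Allen convention (mismatch 1, G:U
# wobble 0.5, gap 2, doubled at sRNA positions 2-13); energies use the
# simplified pair model GC -3, AU -2, GU -1, mismatch/gap 0.
.pn_code <- function(chars) {
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

.pn_pair_tables <- local({
  raw <- matrix(1, 4, 5)
  en <- matrix(0, 4, 5)
  cls <- matrix("mismatch", 4, 5)
  wc <- rbind(c(1, 4), c(2, 3), c(3, 2), c(4, 1))       # A:T C:G G:C T:A
  gu <- rbind(c(3, 4), c(4, 3))                          # G:U U:G
  raw[wc] <- 0; raw[gu] <- 0.5
  cls[wc] <- "match"; cls[gu] <- "GU"
  en[wc] <- c(-2, -3, -3, -2)                            # by sRNA base
  en[gu] <- -1
  list(raw = raw, energy = en, class = cls)
})

# Positional multiplier of the Allen scheme: penalties double at sRNA
# positions 2-13 (the seed and central region).
.pn_mult <- function(L) ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)

# Perfect-complement energy of an sRNA under the pair model.
perfect_energy <- function(srna) {
  code <- .pn_code(strsplit(srna, "", fixed = TRUE)[[1]])
  if (all(code == 5L)) stop("sRNA has no unambiguous bases", call. = FALSE)
  sum(c(-2, -3, -3, -2, 0)[code])
}

# Exhaustive antiparallel duplex scan of one sRNA against one transcript:
# every ungapped offset plus every single-gap variant (one unpaired sRNA
# base, or one bulged transcript base). Alignments are parameterised by the
# diagonal c = i + j (i = 1-based transcript position, j = 1-based sRNA
# position; ungapped pairing is i = c - j). Returns every alignment whose
# raw penalty (undoubled: mismatch 1, G:U 0.5, gap 2) is at most `max_raw`.
scan_duplexes <- function(srna, transcript, max_raw = 4) {
  L <- nchar(srna)
  Tn <- nchar(transcript)
  if (Tn < L) {
    return(tibble(site_start = integer(0), site_end = integer(0),
                  gap_type = character(0), gap_pos = integer(0),
                  allen = numeric(0), raw = numeric(0),
                  mfe_ratio = numeric(0), energy = numeric(0)))
  }
  scode <- .pn_code(strsplit(srna, "", fixed = TRUE)[[1]])
  tcode <- .pn_code(strsplit(transcript, "", fixed = TRUE)[[1]])
  C <- Tn + L
  tidx <- outer(-seq_len(L), seq_len(C), "+")   # transcript index c - j
  valid <- tidx >= 1L & tidx <= Tn
  look <- function(tab, fill) {
    m <- matrix(fill, L, C)
    sc <- scode[row(tidx)[valid]]
    m[valid] <- tab[cbind(sc, tcode[tidx[valid]])]
    m
  }
  pen <- look(.pn_pair_tables$raw, Inf)
  en <- look(.pn_pair_tables$energy, 0)
  mult <- .pn_mult(L)
  penw <- pen * mult
  cp_r <- apply(pen, 2, cumsum)                 # prefix sums over j
  cp_w <- apply(penw, 2, cumsum)
  cp_e <- apply(en, 2, cumsum)
  ss_r <- apply(pen[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  ss_w <- apply(penw[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  ss_e <- apply(en[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  eperf <- perfect_energy(srna)
  rows <- vector("list", 0)
  add <- function(cs, raw, allen, energy, gap_type, gap_pos,
                  start0, site_len) {
    keep <- which(is.finite(raw) & raw <= max_raw)
    if (!length(keep)) return()
    rows[[length(rows) + 1]] <<- tibble(
      site_start = start0[keep], site_end = start0[keep] + site_len,
      gap_type = gap_type, gap_pos = gap_pos,
      allen = allen[keep], raw = raw[keep],
      mfe_ratio = pmin(1, pmax(0, energy[keep] / eperf)),
      energy = energy[keep])
  }
  # ungapped: diagonals with every sRNA base on the transcript
  cs <- (L + 1L):(Tn + 1L)
  add(cs, cp_r[L, cs], cp_w[L, cs], cp_e[L, cs],
      "none", NA_integer_, cs - L - 1L, L)
  # one unpaired sRNA base at g (site one base shorter)
  for (g in if (L >= 4L) 2:(L - 1L) else integer(0)) {
    cs <- L:Tn
    raw <- cp_r[g - 1L, cs] + 2 + ss_r[g + 1L, cs + 1L]
    allen <- cp_w[g - 1L, cs] + 2 * mult[g] + ss_w[g + 1L, cs + 1L]
    energy <- cp_e[g - 1L, cs] + ss_e[g + 1L, cs + 1L]
    add(cs, raw, allen, energy, "srna_bulge", g, cs - L, L - 1L)
  }
  # one bulged transcript base between sRNA positions g and g+1 (site one
  # base longer); the gap takes the positional weight of position g+1
  for (g in if (L >= 2L && Tn >= L + 1L) 1:(L - 1L) else integer(0)) {
    cs <- (L + 2L):(Tn + 1L)
    raw <- cp_r[g, cs] + 2 + ss_r[g + 1L, cs - 1L]
    allen <- cp_w[g, cs] + 2 * mult[g + 1L] + ss_w[g + 1L, cs - 1L]
    energy <- cp_e[g, cs] + ss_e[g + 1L, cs - 1L]
    add(cs, raw, allen, energy, "t_bulge", g, cs - L - 2L, L + 1L)
  }
  if (!length(rows)) {
    return(tibble(site_start = integer(0), site_end = integer(0),
                  gap_type = character(0), gap_pos = integer(0),
                  allen = numeric(0), raw = numeric(0),
                  mfe_ratio = numeric(0), energy = numeric(0)))
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$site_start, out$allen, out$gap_type, out$gap_pos), ]
}

# Per-position pairing table of one alignment: sRNA position, transcript
# position (0-based), bases, pair class ("match"/"GU"/"mismatch"/"gap").
duplex_pairs <- function(srna, transcript, site_start, gap_type = "none",
                         gap_pos = NA_integer_) {
  L <- nchar(srna)
  sv <- strsplit(srna, "", fixed = TRUE)[[1]]
  tv <- strsplit(transcript, "", fixed = TRUE)[[1]]
  j <- seq_len(L)
  if (gap_type == "none") {
    c0 <- site_start + L + 1L
    i <- c0 - j
    tab <- tibble(srna_pos = j, site_pos = i - 1L, srna_base = sv,
                  site_base = tv[i],
                  class = .pn_pair_tables$class[cbind(.pn_code(sv),
                                                      .pn_code(tv[i]))])
  } else if (gap_type == "srna_bulge") {
    c0 <- site_start + L
    i <- ifelse(j < gap_pos, c0 - j, c0 + 1L - j)
    cls <- .pn_pair_tables$class[cbind(.pn_code(sv), .pn_code(tv[i]))]
    cls[gap_pos] <- "gap"
    tab <- tibble(srna_pos = j, site_pos = ifelse(j == gap_pos, NA, i - 1L),
                  srna_base = sv,
                  site_base = ifelse(j == gap_pos, "-", tv[i]), class = cls)
  } else {
    c0 <- site_start + L + 2L
    i <- ifelse(j <= gap_pos, c0 - j, c0 - 1L - j)
    tab <- tibble(srna_pos = j, site_pos = i - 1L, srna_base = sv,
                  site_base = tv[i],
                  class = .pn_pair_tables$class[cbind(.pn_code(sv),
                                                      .pn_code(tv[i]))])
    bulge <- tibble(srna_pos = NA_integer_, site_pos = c0 - gap_pos - 2L,
                    srna_base = "-", site_base = tv[c0 - gap_pos - 1L],
                    class = "gap")
    tab <- dplyr::bind_rows(tab[seq_len(gap_pos), ], bulge,
                            tab[(gap_pos + 1L):L, ])
  }
  tab
}

# Compact pairing-string notation, written 5'->3' along the sRNA:
# ":" Watson-Crick, "o" G:U wobble, "." mismatch, "-" gap.
pairing_string <- function(pairs) {
  paste(c(":" = ":", match = ":", GU = "o", mismatch = ".",
          gap = "-")[pairs$class], collapse = "")
}

#' Allen score of a duplex alignment
#'
#' Additive complementarity penalty: mismatch 1, G:U wobble 0.5, each gapped
#' position 2, with every penalty doubled at sRNA positions 2-13. A perfect
#' complement scores 0.
#'
#' @param duplex a duplex object from [find_candidate_sites()] (one row) or
#'   a pairing table from the engine.
#' @return the score (non-negative).
#' @export
allen_score <- function(duplex) {
  pairs <- if (is.data.frame(duplex) && "class" %in% names(duplex)) duplex
           else duplex$pairs[[1]]
  base_pen <- c(match = 0, GU = 0.5, mismatch = 1, gap = 2)[pairs$class]
  # a transcript bulge sits between two sRNA positions; it takes the weight
  # of the following position
  pos <- pairs$srna_pos
  if (anyNA(pos)) {
    nxt <- which(is.na(pos))
    pos[nxt] <- pairs$srna_pos[pmin(nxt + 1L, nrow(pairs))]
  }
  mult <- ifelse(pos >= 2 & pos <= 13, 2, 1)
  sum(base_pen * mult)
}

#' MFE ratio of a duplex alignment
#'
#' Duplex energy divided by the energy of the sRNA's perfect complement
#' under the simplified pair model (GC -3, AU -2, GU -1, mismatch/gap 0;
#' arbitrary units). Because only the ratio is thresholded, the model is
#' scale-free: a perfect duplex scores exactly 1 and the ratio is clipped
#' to [0, 1]. A nearest-neighbour thermodynamic backend can be swapped in
#' by replacing the pair-energy table.
#'
#' @inheritParams allen_score
#' @return ratio in `[0, 1]`.
#' @export
mfe_ratio <- function(duplex) {
  pairs <- if (is.data.frame(duplex) && "class" %in% names(duplex)) duplex
           else duplex$pairs[[1]]
  srna <- paste(pairs$srna_base[pairs$srna_base != "-"], collapse = "")
  e <- sum(ifelse(pairs$class == "match",
                  c(-2, -3, -3, -2, 0)[.pn_code(pairs$srna_base)],
                  ifelse(pairs$class == "GU", -1, 0)))
  min(1, max(0, e / perfect_energy(srna)))
}

#' Find candidate target sites of an sRNA on a transcript
#'
#' Exhaustive antiparallel complementarity scan (all ungapped offsets plus
#' all single-gap variants) reporting every alignment within `max_raw`
#' mismatch-equivalents (undoubled penalty units), 5'-most site first.
#'
#' @param srna sRNA sequence (5'->3').
#' @param transcript transcript sequence.
#' @param max_raw raw-penalty cut-off for reporting (default 4).
#' @return tibble of alignments with site coordinates (0-based half-open),
#'   `allen`, `mfe_ratio`, a `pairing` string and a nested `pairs` table.
#' @export
find_candidate_sites <- function(srna, transcript, max_raw = 4) {
  hits <- scan_duplexes(srna, transcript, max_raw = max_raw)
  if (nrow(hits) == 0) {
    hits$pairing <- character(0)
    hits$pairs <- list()
    return(hits)
  }
  pr <- lapply(seq_len(nrow(hits)), function(i) {
    duplex_pairs(srna, transcript, hits$site_start[i], hits$gap_type[i],
                 hits$gap_pos[i])
  })
  hits$pairing <- vapply(pr, pairing_string, character(1))
  hits$pairs <- pr
  hits
}

#' Predict sRNA targets with the dual Allen/MFE criterion
#'
#' For every sRNA x transcript pair the best alignment by Allen score
#' (ties: lowest transcript coordinate) is retained and accepted when
#' `allen < allen_max` (strict) and `mfe_ratio > mfe_ratio_min` (strict) --
#' both published thresholds applied conjointly on one alignment engine.
#' The predicted cleavage position is the transcript base opposite sRNA
#' position 10 (canonical AGO slicing between positions 10 and 11).
#'
#' @param srnas tibble with `id`, `seq` and optionally `class` (miRNA /
#'   phasiRNA) and `phas_id` columns.
#' @param transcripts tibble from [read_fasta()].
#' @param config a [phas_config()].
#' @return tibble of interactions: ids, site span, `allen_score`,
#'   `mfe_ratio`, `cleavage_pos` (0-based transcript coordinate), `pairing`
#'   and the `accepted` flag.
#' @export
predict_targets <- function(srnas, transcripts, config = phas_config()) {
  res <- vector("list", 0)
  for (si in seq_len(nrow(srnas))) {
    for (ti in seq_len(nrow(transcripts))) {
      hits <- scan_duplexes(srnas$seq[si], transcripts$seq[ti],
                            max_raw = config$site_max_raw)
      if (nrow(hits) == 0) next
      best <- hits[order(hits$allen, hits$site_start), ][1, ]
      pairs <- duplex_pairs(srnas$seq[si], transcripts$seq[ti],
                            best$site_start, best$gap_type, best$gap_pos)
      cleav <- pairs$site_pos[which(pairs$srna_pos == 10L)][1]
      res[[length(res) + 1]] <- tibble(
        srna_id = srnas$id[si],
        srna_class = if ("class" %in% names(srnas)) srnas$class[si]
                     else NA_character_,
        phas_id = if ("phas_id" %in% names(srnas)) srnas$phas_id[si]
                  else NA_character_,
        transcript_id = transcripts$id[ti],
        site_start = best$site_start, site_end = best$site_end,
        allen_score = best$allen, mfe_ratio = best$mfe_ratio,
        cleavage_pos = cleav, pairing = pairing_string(pairs),
        accepted = best$allen < config$allen_max &
          best$mfe_ratio > config$mfe_ratio_min)
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble(srna_id = character(0), srna_class = character(0),
           phas_id = character(0), transcript_id = character(0),
           site_start = integer(0), site_end = integer(0),
           allen_score = numeric(0), mfe_ratio = numeric(0),
           cleavage_pos = integer(0), pairing = character(0),
           accepted = logical(0))
  pn_log("predict_targets", "%d interactions, %d accepted",
         nrow(out), sum(out$accepted))
  out
}

#' Assign trigger miRNAs to PHAS loci
#'
#' Aligns each candidate miRNA against both strands of every PHAS locus
#' extended by flanking sequence (400 bp of added flank in total, 200 nt per
#' side, by default). An assignment is reported when the best alignment
#' penalty (Allen score) is at most `trigger_max_penalty` (inclusive). The
#' predicted cleavage coordinate is the genomic base opposite sRNA positions
#' 10-11, and `in_register` records whether that cleavage sets the locus
#' register (taking the minus-strand 2-nt overhang convention into account).
#'
#' @param mirnas tibble with `id` and `seq` (mature sequences, 5'->3').
#' @param phas_loci locus tibble from [scan_phas()].
#' @param genome genome tibble ([read_fasta()]).
#' @param config a [phas_config()].
#' @return tibble with `mirna_id`, `phas_id`, `penalty`, `strand`,
#'   `cleavage_coord` (0-based genomic) and `in_register`.
#' @export
identify_triggers <- function(mirnas, phas_loci, genome,
                              config = phas_config()) {
  flank <- if (config$trigger_flank_mode == "total") {
    config$trigger_window %/% 2L
  } else {
    config$trigger_window
  }
  res <- vector("list", 0)
  for (pi in seq_len(nrow(phas_loci))) {
    locus <- phas_loci[pi, ]
    gseq <- genome$seq[genome$id == locus$chrom]
    if (length(gseq) != 1) stop("chromosome not in genome: ", locus$chrom,
                                call. = FALSE)
    wstart <- max(0L, locus$start - flank)
    wend <- min(nchar(gseq), locus$end + flank)
    wseq <- substr(gseq, wstart + 1L, wend)
    wlen <- nchar(wseq)
    for (mi in seq_len(nrow(mirnas))) {
      cand <- dplyr::bind_rows(
        dplyr::mutate(scan_duplexes(mirnas$seq[mi], wseq,
                                    max_raw = config$trigger_max_penalty),
                      strand = "+", tseq = wseq),
        dplyr::mutate(scan_duplexes(mirnas$seq[mi], revcomp(wseq),
                                    max_raw = config$trigger_max_penalty),
                      strand = "-", tseq = revcomp(wseq)))
      if (nrow(cand) == 0) next
      best <- cand[order(cand$allen, cand$site_start), ][1, ]
      if (best$allen > config$trigger_max_penalty) next
      pairs <- duplex_pairs(mirnas$seq[mi], best$tseq, best$site_start,
                            best$gap_type, best$gap_pos)
      cleav_local <- pairs$site_pos[which(pairs$srna_pos == 10L)][1]
      if (best$strand == "+") {
        g <- wstart + cleav_local
        in_reg <- (g %% locus$period) == locus$register
      } else {
        g <- wstart + (wlen - 1L - cleav_local)
        in_reg <- ((g + 2L) %% locus$period) == locus$register
      }
      res[[length(res) + 1]] <- tibble(
        mirna_id = mirnas$id[mi], phas_id = locus$locus_id,
        penalty = best$allen, strand = best$strand,
        cleavage_coord = as.integer(g), in_register = in_reg)
    }
  }
  out <- if (length(res)) dplyr::bind_rows(res) else
    tibble(mirna_id = character(0), phas_id = character(0),
           penalty = numeric(0), strand = character(0),
           cleavage_coord = integer(0), in_register = logical(0))
  pn_log("identify_triggers", "%d assignments", nrow(out))
  out
}
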