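#' Phase coordinate of aligned reads
#'
#' A read's phase coordinate is its 5' end for plus-strand hits and its 5'
#' end plus 2 for minus-strand hits, folding in the 2-nt 3' overhang left by
#' Dicer so that the two strands of one phased duplex share a register. The
#' 5' end of a minus-strand hit is its rightmost forward-strand base.
#'
#' @param start 0-based leftmost forward coordinate of the hit.
#' @param strand `"+"` or `"-"`.
#' @param length read length.
#' @return integer phase coordinates.
#' @export
phase_coord <- function(start, strand, length) {
  ifelse(strand == "+", start, start + length - 1L + 2L)
}

#' Phase-register occupancy statistics for one window
#'
#' Enumerates the hypergeometric inputs for a candidate period and register
#' over a window: `N` eligible 5'-end positions, `m` of them in register,
#' `n` occupied positions (a position is occupied when at least one read of
#' length equal to the period starts there), `k` occupied in-register
#' positions, and the in-register (`P`) and out-of-register (`U`) abundance
#' sums. In-register abundance counts only reads of the period length;
#' reads of any other length always contribute to `U`.
#'
#' Under the default position model (`"all"`) every nucleotide of the window
#' on both strands is an eligible position: `N = 2 * window length` and
#' `m = 2 * window length / period`. The alternative `"grid"` model is a
#' coarse register-class test: the `2 * period` strand/residue classes form
#' the population (`N`), the two in-register classes are the successes
#' (`m = 2`), and occupancy is counted per class.
#'
#' @param hits tibble with `start`, `strand`, `length` and `abundance`
#'   columns (abundance = total read count of the tag at that position).
#' @param period phasing period (21 or 24).
#' @param register target register, an integer in `[0, period)` relative to
#'   `window_start`.
#' @param window_start 0-based window start.
#' @param window_length window length; must be a multiple of `period`.
#' @param position_model `"all"` (default) or `"grid"`.
#' @return one-row tibble with `N`, `m`, `n`, `k`, `P`, `U`.
#' @export
enumerate_phase_stats <- function(hits, period, register, window_start,
                                  window_length,
                                  position_model = c("all", "grid")) {
  position_model <- match.arg(position_model)
  if (window_length %% period != 0) {
    stop("window length must be a multiple of the period", call. = FALSE)
  }
  x <- phase_coord(hits$start, hits$strand, hits$length)
  inw <- x >= window_start & x < window_start + window_length
  h <- hits[inw, , drop = FALSE]
  x <- x[inw]
  res <- (x - window_start) %% period
  is_period <- h$length == period
  in_reg <- res == register & is_period
  P <- sum(h$abundance[in_reg])
  U <- sum(h$abundance) - P
  occ <- !duplicated(data.frame(h$strand, x)[is_period, , drop = FALSE])
  occ_strand <- h$strand[is_period][occ]
  occ_x <- x[is_period][occ]
  occ_res <- res[is_period][occ]
  if (position_model == "all") {
    N <- 2L * window_length
    m <- 2L * window_length %/% period
    n <- length(occ_x)
    k <- sum(occ_res == register)
  } else {
    N <- 2L * period
    m <- 2L
    cls <- !duplicated(data.frame(occ_strand, occ_res))
    n <- sum(cls)
    k <- sum(cls & occ_res == register)
  }
  tibble(N = N, m = m, n = n, k = as.integer(k), P = P, U = U)
}

#' Hypergeometric phasing p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` in-register
#' positions when `n` occupied positions are drawn without replacement from
#' `N` eligible positions of which `m` are in register. Returns 1 when
#' `k = 0`; the tail is an exact summation of hypergeometric point masses.
#'
#' @param stats one-row tibble from [enumerate_phase_stats()], or `N`
#'   supplied directly with `m`, `n`, `k`.
#' @param m,n,k see above.
#' @return p-value in `[0, 1]`.
#' @export
phasing_pvalue <- function(stats, m = NULL, n = NULL, k = NULL) {
  if (is.null(m)) {
    m <- stats$m; n <- stats$n; k <- stats$k; N <- stats$N
  } else {
    N <- stats
  }
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k > min(n, m)) {
    stop("inconsistent phase stats: k exceeds min(n, m)", call. = FALSE)
  }
  if (k == 0) return(1)
  sum(stats::dhyper(k:min(n, m), m, N - m, n))
}

#' Phasing score
#'
#' `score = (k - 2) * ln(1 + 10 * P / (1 + U))` when at least three occupied
#' cycles are in register (`k >= 3`), and 0 otherwise. The score grows with
#' in-register abundance `P` and occupancy `k`, and shrinks with
#' out-of-register abundance `U`; the `1 + U` denominator guards `U = 0`.
#'
#' @param stats one-row tibble from [enumerate_phase_stats()], or `P`
#'   supplied directly with `U` and `k`.
#' @param U,k see above.
#' @return non-negative score.
#' @export
phasing_score <- function(stats, U = NULL, k = NULL) {
  if (is.null(U)) {
    P <- stats$P; U <- stats$U; k <- stats$k
  } else {
    P <- stats
  }
  ifelse(k >= 3, (k - 2) * log1p(10 * P / (1 + U)), 0)
}

#' Scan a genome for PHAS loci
#'
#' Slides a window of `phas_cycles * period` nt in steps of one period over
#' each chromosome, evaluates every register of every window, retains
#' windows whose best register reaches `p < phas_pmax` and
#' `score > phas_min_score`, merges overlapping or bookended retained
#' windows that share an absolute register, and applies the remaining
#' acceptance filters per merged locus: span above `phas_min_len`, phased
#' fraction `P/(P+U)` above `phas_min_phased_frac`, and abundance-weighted
#' dominant read length equal to the period. Reported loci carry their
#' maximum phasing score and minimum window p-value, plus the full
#' occupancy bookkeeping for audit.
#'
#' @param hits hit tibble from [align_tags()] (optionally multimap-filtered
#'   according to `config$multimap_phas`).
#' @param tags tag tibble from [collapse_reads()] supplying abundances.
#' @param period 21 or 24.
#' @param chrom_lengths named integer vector of chromosome lengths (defaults
#'   to the rightmost hit per chromosome).
#' @param config a [phas_config()].
#' @return tibble of accepted loci: `locus_id` (`PHAS<period>-<k>` in
#'   genomic order), `chrom`, `start`, `end`, `period`, `register`
#'   (absolute phase-coordinate residue), `p_value`, `phasing_score`,
#'   `phased_fraction`, `dominant_length`, occupancy stats, and a nested
#'   `phasirnas` tibble of in-register reads.
#' @export
scan_phas <- function(hits, tags, period, chrom_lengths = NULL,
                      config = phas_config()) {
  if (config$multimap_phas) hits <- filter_multimap(hits, config$max_genome_hits)
  hits <- dplyr::left_join(hits, tags[c("tag_id", "seq", "total")],
                           by = "tag_id")
  hits$abundance <- hits$total
  win_len <- config$phas_cycles * period
  loci <- vector("list", 0)
  for (chrom in unique(hits$chrom)) {
    h <- hits[hits$chrom == chrom, , drop = FALSE]
    clen <- if (!is.null(chrom_lengths) && chrom %in% names(chrom_lengths)) {
      chrom_lengths[[chrom]]
    } else {
      max(h$start + h$length) + period
    }
    kept <- scan_chrom_windows(h, period, win_len, clen, config)
    if (nrow(kept) == 0) next
    loci[[length(loci) + 1]] <- merge_windows(kept, h, period, chrom, config)
  }
  out <- if (length(loci)) dplyr::bind_rows(loci) else empty_phas_loci()
  if (nrow(out) > 0) {
    out <- out[order(out$chrom, out$start), ]
    out$locus_id <- sprintf("PHAS%d-%d", period, seq_len(nrow(out)))
    out <- out[c("locus_id", setdiff(names(out), "locus_id"))]
  }
  pn_log("scan_phas", "period %d: %d loci", period, nrow(out))
  out
}

empty_phas_loci <- function() {
  tibble(locus_id = character(0), chrom = character(0), start = integer(0),
         end = integer(0), period = integer(0), register = integer(0),
         p_value = numeric(0), phasing_score = numeric(0),
         phased_fraction = numeric(0), dominant_length = integer(0),
         N = integer(0), m = integer(0), n = integer(0), k = integer(0),
         P = numeric(0), U = numeric(0), phasirnas = list())
}

# Evaluate all registers of all windows on one chromosome; returns retained
# windows with their best register (absolute residue class) and stats.
scan_chrom_windows <- function(h, period, win_len, clen, config) {
  x <- phase_coord(h$start, h$strand, h$length)
  is_period <- h$length == period
  starts <- seq(0L, max(0L, clen - win_len), by = period)
  rows <- vector("list", 0)
  ord <- order(x)
  xs <- x[ord]; hs <- h[ord, , drop = FALSE]
  for (ws in starts) {
    lo <- findInterval(ws - 0.5, xs) + 1L
    hi <- findInterval(ws + win_len - 0.5, xs)
    if (hi < lo) next
    idx <- lo:hi
    xi <- xs[idx]
    res <- (xi - ws) %% period
    isp <- is_period[ord][idx]
    ab <- hs$abundance[idx]
    tot_ab <- sum(ab)
    # occupancy: distinct (strand, phase coordinate) among period-length reads
    occ_res <- res[isp][!duplicated(data.frame(hs$strand[idx][isp], xi[isp]))]
    n <- length(occ_res)
    if (n == 0) next
    k_r <- tabulate(occ_res + 1L, nbins = period)
    P_r <- vapply(0:(period - 1L),
                  function(r) sum(ab[isp & res == r]), numeric(1))
    U_r <- tot_ab - P_r
    score_r <- ifelse(k_r >= 3, (k_r - 2) * log1p(10 * P_r / (1 + U_r)), 0)
    if (max(score_r) <= config$phas_min_score) next
    N <- 2L * win_len
    m <- 2L * win_len %/% period
    best <- order(-score_r, seq_len(period))[1]
    p_best <- phasing_pvalue(N, m, n, k_r[best])
    if (p_best >= config$phas_pmax) next
    rows[[length(rows) + 1]] <- tibble(
      wstart = ws, wend = ws + win_len,
      register_abs = as.integer((ws + best - 1L) %% period),
      N = N, m = m, n = n, k = k_r[best], P = P_r[best], U = U_r[best],
      p_value = p_best, score = score_r[best])
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble(wstart = integer(0), wend = integer(0), register_abs = integer(0),
           N = integer(0), m = integer(0), n = integer(0), k = integer(0),
           P = numeric(0), U = numeric(0), p_value = numeric(0),
           score = numeric(0))
}

# Merge retained windows sharing a register into loci and apply the
# remaining locus-level filters.
merge_windows <- function(kept, h, period, chrom, config) {
  kept <- kept[order(kept$register_abs, kept$wstart), ]
  nr <- nrow(kept)
  new_grp <- c(TRUE, kept$register_abs[-1] != kept$register_abs[-nr] |
                 kept$wstart[-1] > kept$wend[-nr])
  grp <- cumsum(new_grp)
  x <- phase_coord(h$start, h$strand, h$length)
  out <- vector("list", 0)
  for (g in unique(grp)) {
    w <- kept[grp == g, ]
    reg <- w$register_abs[1]
    lo <- min(w$wstart); hi <- max(w$wend)
    in_span <- x >= lo & x < hi
    in_reg <- in_span & h$length == period & (x %% period) == reg
    if (!any(in_reg)) next
    span_lo <- min(x[in_reg]); span_hi <- max(x[in_reg]) + period
    in_locus <- x >= span_lo & x < span_hi
    in_reg_l <- in_locus & h$length == period & (x %% period) == reg
    P <- sum(h$abundance[in_reg_l])
    U <- sum(h$abundance[in_locus]) - P
    phased_frac <- P / (P + U)
    lens <- h$length[in_locus]
    dom <- as.integer(names(which.max(tapply(h$abundance[in_locus], lens,
                                             sum))))
    accept <- (span_hi - span_lo) > config$phas_min_len &&
      phased_frac > config$phas_min_phased_frac && dom == period
    if (!accept) next
    phasi <- tibble(seq = h$seq[in_reg_l], position = h$start[in_reg_l],
                    strand = h$strand[in_reg_l],
                    abundance = h$abundance[in_reg_l])
    phasi <- phasi[order(-phasi$abundance, phasi$position), ]
    out[[length(out) + 1]] <- tibble(
      chrom = chrom, start = as.integer(span_lo), end = as.integer(span_hi),
      period = as.integer(period), register = as.integer(reg),
      p_value = min(w$p_value), phasing_score = max(w$score),
      phased_fraction = phased_frac, dominant_length = dom,
      N = w$N[1], m = w$m[1], n = max(w$n), k = max(w$k),
      P = P, U = U, phasirnas = list(phasi))
  }
  if (length(out)) dplyr::bind_rows(out) else empty_phas_loci()[0, ]
}

#' Select the most abundant phasiRNAs of a locus
#'
#' In-register reads ranked by total abundance (ties broken toward the
#' lower coordinate); at most `top_n` (default 30) are returned.
#'
#' @param locus a one-row locus tibble from [scan_phas()], or its nested
#'   `phasirnas` tibble directly.
#' @param top_n maximum number of phasiRNAs to return.
#' @return ranked phasiRNA tibble with a `rank` column.
#' @export
top_phasirnas <- function(locus, top_n = 30L) {
  phasi <- if ("phasirnas" %in% names(locus)) locus$phasirnas[[1]] else locus
  phasi <- phasi[order(-phasi$abundance, phasi$position), ]
  phasi <- utils::head(phasi, top_n)
  phasi$rank <- seq_len(nrow(phasi))
  phasi
}
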