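#' Map degradome reads to transcripts
#'
#' Each read's 5' end is assigned to its exact-match position(s) on the
#' transcriptome (degradome tags are transcript-derived, so no mismatches
#' are allowed by default). A read matching t positions receives fractional
#' weight 1/t at each; the rounded integer profile is retained alongside the
#' exact fractional one. Unmapped reads are counted and logged.
#'
#' @param reads tibble with a `seq` column (degradome reads, sense strand).
#' @param transcripts tibble from [read_fasta()].
#' @return tibble with `transcript_id`, `position` (0-based 5'-end
#'   coordinate), `frac` (fractional weight) and `reads` (rounded), sorted
#'   by transcript and position; the unmapped read count is attached as the
#'   `unmapped` attribute.
#' @export
map_degradome <- function(reads, transcripts) {
  uniq <- reads |> dplyr::count(.data$seq, name = "n_reads")
  subj <- Biostrings::DNAStringSet(stats::setNames(transcripts$seq,
                                                   transcripts$id))
  rows <- vector("list", 0)
  unmapped <- 0L
  for (i in seq_len(nrow(uniq))) {
    m <- Biostrings::vmatchPattern(uniq$seq[i], subj)
    starts <- Biostrings::startIndex(m)
    tot <- sum(lengths(starts))
    if (tot == 0) {
      unmapped <- unmapped + uniq$n_reads[i]
      next
    }
    for (ti in which(lengths(starts) > 0)) {
      rows[[length(rows) + 1]] <- tibble(
        transcript_id = transcripts$id[ti],
        position = starts[[ti]] - 1L,
        frac = uniq$n_reads[i] / tot)
    }
  }
  out <- if (length(rows)) {
    dplyr::bind_rows(rows) |>
      dplyr::group_by(.data$transcript_id, .data$position) |>
      dplyr::summarise(frac = sum(.data$frac), .groups = "drop") |>
      dplyr::arrange(.data$transcript_id, .data$position)
  } else {
    tibble(transcript_id = character(0), position = integer(0),
           frac = numeric(0))
  }
  out$reads <- as.integer(round(out$frac))
  pn_log("map_degradome", "%d positions covered, %d reads unmapped",
         nrow(out), unmapped)
  attr(out, "unmapped") <- unmapped
  out
}

# Dense 5'-end density vector (1-based indexing of 0-based positions) for
# one transcript from the sparse profile table.
degradome_density <- function(profile, transcript_id, length) {
  d <- numeric(length)
  p <- profile[profile$transcript_id == transcript_id, ]
  d[p$position + 1L] <- p$reads
  d
}

#' Degradome site category
#'
#' CleaveLand-style 0-4 ranking of the signal at one position relative to
#' the whole transcript profile. With `r` the reads at the query position,
#' `M` the maximum and `med` the median over *occupied* positions (zeros
#' excluded): category 4 when `r = 1`; 0 when `r > 1` and `r` is the unique
#' maximum; 1 when `r > 1` equals a shared maximum; 2 when
#' `med < r < M`; 3 when `1 < r <= med`. Querying a position with no signal
#' is an error.
#'
#' @param density numeric vector of per-position 5'-end counts for one
#'   transcript (index 1 is position 0).
#' @param position 0-based transcript position.
#' @return integer category 0-4.
#' @export
categorize_site <- function(density, position) {
  r <- density[position + 1L]
  if (is.na(r) || r == 0) stop("no degradome signal at position ", position,
                               call. = FALSE)
  occ <- density[density > 0]
  M <- max(occ)
  med <- stats::median(occ)
  if (r == 1) return(4L)
  if (r == M) {
    return(if (sum(occ == M) == 1L) 0L else 1L)
  }
  if (r > med) return(2L)
  3L
}

#' Validate predicted interactions against a degradome profile
#'
#' For each predicted interaction the degradome signal at the predicted
#' cleavage position, plus or minus `degradome_slop` nt (best position of
#' the three by default), is categorised; the site is validated when the
#' category is at most `degradome_max_category` (0-3), the interaction's
#' alignment penalty is at most `degradome_max_penalty` (6) and at least
#' one read supports the position.
#'
#' @param interactions tibble from [predict_targets()] (needs
#'   `transcript_id`, `cleavage_pos`, `allen_score`).
#' @param profile sparse profile tibble from [map_degradome()].
#' @param transcripts transcript tibble (for lengths).
#' @param config a [phas_config()].
#' @return `interactions` with `deg_position`, `deg_reads`, `category` and
#'   `validated` columns appended.
#' @export
validate_interactions <- function(interactions, profile, transcripts,
                                  config = phas_config()) {
  n <- nrow(interactions)
  deg_pos <- rep(NA_integer_, n)
  deg_reads <- rep(0L, n)
  category <- rep(NA_integer_, n)
  dens_cache <- list()
  for (i in seq_len(n)) {
    tid <- interactions$transcript_id[i]
    cp <- interactions$cleavage_pos[i]
    if (is.na(cp)) next
    if (is.null(dens_cache[[tid]])) {
      tlen <- nchar(transcripts$seq[transcripts$id == tid])
      dens_cache[[tid]] <- degradome_density(profile, tid, tlen)
    }
    d <- dens_cache[[tid]]
    cand <- (cp - config$degradome_slop):(cp + config$degradome_slop)
    cand <- cand[cand >= 0 & cand < length(d)]
    if (!length(cand)) next
    best <- cand[which.max(d[cand + 1L])]
    deg_pos[i] <- best
    deg_reads[i] <- as.integer(d[best + 1L])
    if (deg_reads[i] >= 1L) category[i] <- categorize_site(d, best)
  }
  interactions$deg_position <- deg_pos
  interactions$deg_reads <- deg_reads
  interactions$category <- category
  interactions$validated <- !is.na(category) &
    category <= config$degradome_max_category &
    interactions$allen_score <= config$degradome_max_penalty &
    deg_reads >= 1L
  pn_log("validate_interactions", "%d of %d interactions validated",
         sum(interactions$validated), n)
  interactions
}
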