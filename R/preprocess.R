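#' Clean raw small-RNA reads
#'
#' Trims the 3' adapter at the first exact match of its 8-nt prefix, then
#' discards reads that are shorter than `min_len` after trimming or that
#' contain an ambiguous base (N). The number of removals is logged to stderr.
#'
#' @param reads tibble from [read_fastq()] (columns `id`, `seq`, optional
#'   `qual`).
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param min_len minimum retained read length after trimming (default 18).
#' @param config optional [phas_config()]; supplies `min_read_len` and the
#'   adapter seed length when `min_len` is not given explicitly.
#' @return tibble of retained reads with updated `seq` (and `qual`).
#' @export
clean_reads <- function(reads, adapter = NULL, min_len = NULL,
                        config = phas_config()) {
  min_len <- min_len %||% config$min_read_len
  n_in <- nrow(reads)
  seqs <- toupper(reads$seq)
  if (!is.null(adapter) && nzchar(adapter)) {
    seed <- toupper(substr(adapter, 1L, config$adapter_seed_len))
    if (nchar(seed) < config$adapter_seed_len) {
      warning("adapter shorter than the ", config$adapter_seed_len,
              "-nt seed; using the full adapter as seed", call. = FALSE)
    }
    pos <- as.integer(regexpr(seed, seqs, fixed = TRUE))
    hit <- pos > 0L
    seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
    if ("qual" %in% names(reads)) {
      reads$qual[hit] <- substr(reads$qual[hit], 1L, pos[hit] - 1L)
    }
  }
  reads$seq <- seqs
  keep <- nchar(seqs) >= min_len & !grepl("N", seqs, fixed = TRUE)
  out <- reads[keep, , drop = FALSE]
  pn_log("clean_reads", "%d reads in, %d retained, %d removed",
         n_in, nrow(out), n_in - nrow(out))
  out
}

#' Collapse reads to unique sequence tags
#'
#' Merges redundant sequences into one tag per distinct sequence, with a
#' per-library count column for every library in the input. Collapse
#' conserves the total read count of each library.
#'
#' @param reads tibble with columns `library_id` and `seq` (one row per
#'   read); typically several cleaned libraries bound together.
#' @return tibble with `tag_id`, `seq`, `length`, `total` and one count
#'   column per library, ordered by decreasing total abundance.
#' @export
collapse_reads <- function(reads) {
  stopifnot(all(c("library_id", "seq") %in% names(reads)))
  libs <- unique(reads$library_id)
  tags <- reads |>
    dplyr::count(.data$seq, .data$library_id) |>
    tidyr::pivot_wider(names_from = "library_id", values_from = "n",
                       values_fill = 0L)
  missing_libs <- setdiff(libs, names(tags))
  for (ml in missing_libs) tags[[ml]] <- 0L
  tags$total <- rowSums(tags[libs])
  tags$length <- nchar(tags$seq)
  tags <- tags[order(-tags$total, tags$seq), ]
  tags$tag_id <- sprintf("tag%06d", seq_len(nrow(tags)))
  out <- tags[c("tag_id", "seq", "length", "total", libs)]
  pn_log("collapse_reads", "%d reads collapsed to %d tags",
         nrow(reads), nrow(out))
  out
}

# Library count columns of a tag table.
tag_libraries <- function(tags) {
  setdiff(names(tags), c("tag_id", "seq", "length", "total"))
}

#' Remove tags matching a non-coding RNA blacklist
#'
#' A tag is removed if and only if it occurs as an exact substring of any
#' blacklist sequence (rRNA, tRNA, snoRNA, organellar contaminants) on
#' either strand. One mismatch is enough to retain a tag.
#'
#' @param tags tag tibble from [collapse_reads()].
#' @param blacklist tibble from [read_fasta()] with the contaminant
#'   sequences; an empty blacklist returns the input with a warning.
#' @return filtered tag tibble.
#' @export
filter_blacklist <- function(tags, blacklist) {
  if (nrow(blacklist) == 0) {
    warning("empty blacklist: no tags removed", call. = FALSE)
    return(tags)
  }
  # one subject string with a separator outside the alphabet, searched with
  # each tag (and its reverse complement) as a fixed pattern
  subject <- paste(blacklist$seq, collapse = "|")
  hit_fwd <- stringr::str_detect(subject, stringr::fixed(tags$seq))
  hit_rev <- stringr::str_detect(subject, stringr::fixed(revcomp(tags$seq)))
  drop <- hit_fwd | hit_rev
  pn_log("filter_blacklist", "%d of %d tags removed", sum(drop), nrow(tags))
  tags[!drop, , drop = FALSE]
}

#' Remove tags with too many genomic placements
#'
#' Tags with more than `max_hits` placements are dropped entirely (all their
#' hits removed) to minimise interference from repetitive sequence; a tag
#' with exactly `max_hits` placements is kept (the cut is strict).
#'
#' @param hits hit tibble from [align_tags()].
#' @param max_hits maximum allowed placements per tag (default 20).
#' @return filtered hit tibble.
#' @export
filter_multimap <- function(hits, max_hits = 20L) {
  n_hits <- table(hits$tag_id)
  bad <- names(n_hits)[n_hits > max_hits]
  pn_log("filter_multimap", "%d tags with > %d hits removed",
         length(bad), max_hits)
  hits[!hits$tag_id %in% bad, , drop = FALSE]
}
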