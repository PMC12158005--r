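#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Complement without reversal.
comp <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Structured progress log to stderr; every pipeline stage reports record counts.
pn_log <- function(stage, ...) {
  message(sprintf("[phasnet] %s: %s", stage, sprintf(...)))
}

# Internal: validate a DNA alphabet after normalisation.
check_dna <- function(seqs, what = "sequence") {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,U,N}: e.g. '%s'",
                 what, seqs[which(bad)[1]]), call. = FALSE)
  }
  invisible(seqs)
}

# Normalise raw sequence text: upper-case, U -> T (one DNA alphabet internally).
normalize_seq <- function(seqs) {
  s <- toupper(seqs)
  s <- gsub("U", "T", s, fixed = TRUE)
  check_dna(s)
  s
}

# min Hamming distance between two sequences whose lengths differ by at most
# `max_shift`, sliding the shorter along the longer (overhangs cost nothing).
seq_dist <- function(a, b, max_shift = 1L) {
  la <- nchar(a); lb <- nchar(b)
  if (abs(la - lb) > max_shift) return(Inf)
  if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- Inf
  for (off in 0:(lb - la)) {
    d <- sum(av != bv[(1 + off):(off + la)])
    best <- min(best, d)
  }
  best
}
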