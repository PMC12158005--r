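#' Read a FASTQ file (Phred+33)
#'
#' A deliberately small, strict reader for single-end short-read FASTQ: four
#' lines per record; malformed records raise a parse error that names the
#' offending record number. Compressed (`.gz`) input is handled transparently.
#'
#' @param path FASTQ path.
#' @return tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  if (length(lines) == 0) {
    return(tibble(id = character(0), seq = character(0), qual = character(0)))
  }
  if (length(lines) %% 4 != 0) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d",
                 path, length(lines) %/% 4 + 1), call. = FALSE)
  }
  n <- length(lines) %/% 4
  hd <- lines[seq(1, by = 4, length.out = n)]
  sq <- lines[seq(2, by = 4, length.out = n)]
  pl <- lines[seq(3, by = 4, length.out = n)]
  ql <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))[1]
  if (!is.na(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d", path, bad), call. = FALSE)
  }
  tibble(id = sub("\\s.*$", "", substring(hd, 2)),
         seq = toupper(sq), qual = ql)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads tibble with `id`, `seq` and optionally `qual` (a constant
#'   high quality is emitted when absent).
#' @param path output path (gzip when it ends in `.gz`).
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual
          else strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}
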