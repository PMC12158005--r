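#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased and U is normalised to T so that reads, genome
#' and transcripts share one DNA alphabet. Record order is preserved.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return A tibble with columns `id` and `seq`. An empty file returns an
#'   empty tibble with a warning; duplicated record ids are an error.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGU"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      if (grepl("no line starting with", conditionMessage(e)) ||
          file.size(path) == 0) {
        return(NULL)
      }
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(set) || length(set) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble(id = character(0), seq = character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble(id = ids, seq = unname(normalize_seq(as.character(set))))
}

#' Write sequences to FASTA
#'
#' @param x a tibble with columns `id` and `seq`.
#' @param path output path.
#' @export
write_fasta <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  lines <- character(0)
  if (nrow(x) > 0) {
    lines <- as.vector(rbind(paste0(">", x$id), x$seq))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write called loci to GFF3
#'
#' Internal coordinates are 0-based half-open; GFF3 emission converts to the
#' standard 1-based inclusive convention. miRNA loci are written as
#' `miRNA_primary_transcript`, PHAS loci as `siRNA_locus`. Scores, p-values,
#' periods and family names travel as attributes so the file parses back to
#' identical records.
#'
#' @param loci tibble of called loci; must carry `locus_id`, `chrom`,
#'   `start`, `end` (0-based half-open) and `strand`. Optional columns
#'   `p_value`, `phasing_score`, `period`, `family` become GFF3 attributes.
#' @param path output path.
#' @param type feature type; defaults to `siRNA_locus` when a `period`
#'   column is present and `miRNA_primary_transcript` otherwise.
#' @export
write_gff3 <- function(loci, path, type = NULL) {
  if (nrow(loci) > 0 && any(loci$start > loci$end)) {
    stop("locus with start > end", call. = FALSE)
  }
  if (is.null(type)) {
    type <- if ("period" %in% names(loci)) "siRNA_locus"
            else "miRNA_primary_transcript"
  }
  header <- "##gff-version 3"
  if (nrow(loci) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  attr_of <- function(i) {
    parts <- sprintf("ID=%s", loci$locus_id[i])
    for (key in c("p_value", "phasing_score", "period", "family")) {
      if (key %in% names(loci) && !is.na(loci[[key]][i])) {
        nm <- c(p_value = "p_value", phasing_score = "score",
                period = "period", family = "family")[[key]]
        parts <- c(parts, sprintf("%s=%s", nm, format(loci[[key]][i],
                                                      digits = 6)))
      }
    }
    paste(parts, collapse = ";")
  }
  rows <- vapply(seq_len(nrow(loci)), function(i) {
    paste(loci$chrom[i], "phasnet", type,
          loci$start[i] + 1L, loci$end[i],  # 1-based inclusive
          ".", loci$strand[i], ".", attr_of(i), sep = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phasnet GFF3 file back into a tibble
#'
#' Coordinates are converted back to the internal 0-based half-open
#' convention, so `write_gff3()` followed by `read_gff3()` round-trips.
#'
#' @param path GFF3 path.
#' @return tibble with `locus_id`, `chrom`, `start`, `end`, `strand`, `type`
#'   and any recognised attributes.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(locus_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), type = character(0)))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(attrs, key) {
    has <- grepl(paste0("(^|;)", key, "="), attrs)
    out <- rep(NA_character_, length(attrs))
    out[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", attrs[has])
    out
  }
  attrs <- vapply(f, `[`, character(1), 9)
  out <- tibble(
    locus_id = get_attr(attrs, "ID"),
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
    end = as.integer(vapply(f, `[`, character(1), 5)),
    strand = vapply(f, `[`, character(1), 7),
    type = vapply(f, `[`, character(1), 3)
  )
  for (key in c("p_value", "score", "period", "family")) {
    v <- get_attr(attrs, key)
    if (any(!is.na(v))) {
      col <- c(p_value = "p_value", score = "phasing_score",
               period = "period", family = "family")[[key]]
      out[[col]] <- if (key == "family") v else as.numeric(v)
    }
  }
  out
}

#' Library manifest
#'
#' Builds and validates the sample sheet mapping libraries to tissues and to
#' the fixed reproductive/vegetative contrast: ovule, embryo, FB (female
#' flower buds), OS (ovulate strobili), MB (male flower buds) and MS
#' (microstrobili) are reproductive; leaf and cambium are vegetative.
#'
#' @param library_id character vector of library names.
#' @param tissue tissue per library (one of the eight recognised tissues).
#' @param total_clean_reads positive integer totals used for RP10M.
#' @param path optional file path per library.
#' @return tibble with columns `library_id`, `tissue`, `group`, `path`,
#'   `total_clean_reads`.
#' @export
make_manifest <- function(library_id, tissue, total_clean_reads,
                          path = NA_character_) {
  grp <- tissue_group(tissue)
  if (any(total_clean_reads <= 0)) {
    stop("total_clean_reads must be positive", call. = FALSE)
  }
  if (anyDuplicated(library_id)) stop("duplicate library_id", call. = FALSE)
  tibble(library_id = as.character(library_id), tissue = tissue, group = grp,
         path = path, total_clean_reads = as.numeric(total_clean_reads))
}

#' @rdname make_manifest
#' @param tissues character vector of tissue labels to map to groups.
#' @export
tissue_group <- function(tissues) {
  map <- c(ovule = "reproductive", embryo = "reproductive",
           FB = "reproductive", OS = "reproductive",
           MB = "reproductive", MS = "reproductive",
           leaf = "vegetative", cambium = "vegetative")
  unknown <- setdiff(unique(tissues), names(map))
  if (length(unknown)) {
    stop("unknown tissue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(map[tissues])
}

#' Read a manifest TSV
#'
#' @param path TSV with columns `library_id`, `tissue`, `total_clean_reads`
#'   and optionally `path`.
#' @export
read_manifest <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  make_manifest(x$library_id, x$tissue, x$total_clean_reads,
                path = if ("path" %in% names(x)) x$path else NA_character_)
}

#' Read a raw count table
#'
#' @param path TSV whose first column is the feature id and whose remaining
#'   columns are library ids present in the manifest.
#' @param manifest a manifest tibble from [make_manifest()].
#' @return tibble with `feature_id` plus one integer column per library.
#'   Missing cells and negative counts are errors: counts are never silently
#'   zero-filled.
#' @export
read_count_table <- function(path, manifest) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  libs <- setdiff(names(x), "feature_id")
  unknown <- setdiff(libs, manifest$library_id)
  if (length(unknown)) {
    stop("count table column(s) not in manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  mat <- x[libs]
  if (anyNA(mat)) stop("missing cells in count table", call. = FALSE)
  if (any(unlist(mat) < 0)) stop("negative count in count table", call. = FALSE)
  if (any(unlist(mat) != round(unlist(mat)))) {
    stop("non-integer count in count table", call. = FALSE)
  }
  x[libs] <- lapply(mat, as.integer)
  as_tibble(x)
}

#' Write a count table TSV
#'
#' @param counts tibble with `feature_id` plus library columns.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
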