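#' RP10M normalisation
#'
#' Reads Per 10 Million: `rp10m = raw * 1e7 / library_total`.
#'
#' @param counts tibble with `feature_id` plus one raw-count column per
#'   library.
#' @param totals named vector of per-library totals (e.g.
#'   `setNames(manifest$total_clean_reads, manifest$library_id)`).
#' @return tibble of the same shape with RP10M values.
#' @export
rp10m <- function(counts, totals) {
  libs <- setdiff(names(counts), "feature_id")
  missing <- setdiff(libs, names(totals))
  if (length(missing)) stop("no library total for: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (any(totals[libs] <= 0)) stop("library totals must be positive",
                                   call. = FALSE)
  out <- counts
  for (l in libs) out[[l]] <- counts[[l]] * 1e7 / totals[[l]]
  out
}

#' log2 view of an RP10M table
#'
#' `log2(rp10m + 1)`, the transform used for heatmaps and correlations.
#'
#' @param rp10m_tbl tibble from [rp10m()].
#' @return tibble of the same shape.
#' @export
log2_rp10m <- function(rp10m_tbl) {
  libs <- setdiff(names(rp10m_tbl), "feature_id")
  out <- rp10m_tbl
  for (l in libs) out[[l]] <- log2(rp10m_tbl[[l]] + 1)
  out
}

#' Row-wise Z-scores
#'
#' Standardises each feature (row) to mean 0 and sample standard deviation
#' 1 across libraries. Constant rows become all-zero with a warning.
#'
#' @param x tibble with `feature_id` plus numeric library columns.
#' @return tibble of the same shape.
#' @export
zscore_rows <- function(x) {
  libs <- setdiff(names(x), "feature_id")
  if (length(libs) < 2) stop("need at least 2 libraries", call. = FALSE)
  m <- as.matrix(x[libs])
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  if (any(sd == 0)) {
    warning(sum(sd == 0), " constant row(s) mapped to zero", call. = FALSE)
  }
  z <- (m - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  out <- x
  out[libs] <- as.data.frame(z)
  out
}

#' Differential expression between reproductive and vegetative tissues
#'
#' Features are gated on expression first (`RP10M > min_rp10m` in at least
#' one library by default), then tested. The fold change is
#' `log2((mean RP10M_rep + 0.5) / (mean RP10M_veg + 0.5))` and the p-value
#' comes from a two-sided exact binomial test on pooled raw counts,
#' conditioned on the pooled library-size proportion of the two groups;
#' FDR is Benjamini-Hochberg. A feature passes with `|log2FC|` at or above
#' the class threshold (2 for miRNA, 1 for PHAS and mRNA) and FDR at or
#' below 0.05.
#'
#' @param counts raw count tibble (`feature_id` + library columns).
#' @param manifest manifest tibble covering the count libraries.
#' @param class `"miRNA"`, `"PHAS"` or `"mRNA"` (sets the fold-change
#'   threshold).
#' @param config a [phas_config()].
#' @return a `phasnet_de` tibble: `feature_id`, `class`, group means,
#'   `log2fc`, `p`, `fdr`, `passes`.
#' @export
differential <- function(counts, manifest, class = c("miRNA", "PHAS", "mRNA"),
                         config = phas_config()) {
  class <- match.arg(class)
  libs <- setdiff(names(counts), "feature_id")
  man <- manifest[match(libs, manifest$library_id), ]
  if (anyNA(man$library_id)) stop("count libraries missing from manifest",
                                  call. = FALSE)
  rep_libs <- libs[man$group == "reproductive"]
  veg_libs <- libs[man$group == "vegetative"]
  if (!length(rep_libs) || !length(veg_libs)) {
    stop("both tissue groups must be present", call. = FALSE)
  }
  totals <- stats::setNames(man$total_clean_reads, man$library_id)
  norm <- rp10m(counts, totals)
  gate <- apply(as.matrix(norm[libs]), 1, function(v) {
    if (config$rp10m_gate_mode == "any") any(v > config$min_rp10m)
    else all(v > config$min_rp10m)
  })
  kept <- counts[gate, , drop = FALSE]
  normk <- norm[gate, , drop = FALSE]
  mean_rep <- rowMeans(as.matrix(normk[rep_libs]))
  mean_veg <- rowMeans(as.matrix(normk[veg_libs]))
  log2fc <- log2((mean_rep + 0.5) / (mean_veg + 0.5))
  tot_rep <- sum(totals[rep_libs]); tot_veg <- sum(totals[veg_libs])
  if (tot_rep <= 0 || tot_veg <= 0) stop("zero group totals", call. = FALSE)
  p0 <- tot_rep / (tot_rep + tot_veg)
  x_rep <- rowSums(as.matrix(kept[rep_libs]))
  x_all <- x_rep + rowSums(as.matrix(kept[veg_libs]))
  p <- vapply(seq_along(x_rep), function(i) {
    if (x_all[i] == 0) return(1)
    stats::binom.test(x_rep[i], x_all[i], p = p0)$p.value
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  fc_min <- switch(class, miRNA = config$mirna_fc, PHAS = config$phas_fc,
                   mRNA = config$mrna_fc)
  out <- tibble(feature_id = kept$feature_id, class = class,
                mean_rep = mean_rep, mean_veg = mean_veg,
                log2fc = log2fc, p = p, fdr = fdr,
                passes = abs(log2fc) >= fc_min & fdr <= config$fdr)
  pn_log("differential", "%s: %d gated in, %d pass",
         class, nrow(out), sum(out$passes))
  class(out) <- c("phasnet_de", class(out))
  attr(out, "fc_min") <- fc_min
  attr(out, "fdr_max") <- config$fdr
  out
}
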