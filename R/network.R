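#' Classify a regulatory triple into Model 1 / Model 2 / none
#'
#' The shared requirement S is miRNA-mediated repression of the mRNA:
#' `log2FC(miRNA) * log2FC(mRNA) < 0` with `|log2FC(miRNA)| > 1` and
#' `|log2FC(mRNA)| > 1`. A triple is Model 1 (miRNA-only regulation) when S
#' holds and the PHAS locus is discordant or flat:
#' `log2FC(miRNA) * log2FC(PHAS) < 0` or `|log2FC(PHAS)| < 1`. It is
#' Model 2 (miRNA and phasiRNA co-regulation) when S holds and the PHAS
#' locus moves with the miRNA: `log2FC(miRNA) * log2FC(PHAS) > 0` and
#' `|log2FC(PHAS)| > 1`. All inequalities are strict, so boundary values
#' (products of 0, magnitudes of exactly 1) classify as neither; the two
#' models are mutually exclusive by construction. A missing PHAS fold
#' change (no triggered locus) makes the Model-1 PHAS clause vacuously
#' true and the Model-2 clause false.
#'
#' @param fc_mirna,fc_phas,fc_mrna log2 fold changes (reproductive vs
#'   vegetative); vectors are classified elementwise. `fc_phas` may be NA.
#' @return character vector: `"model1"`, `"model2"` or `"none"`.
#' @export
classify_triple <- function(fc_mirna, fc_phas, fc_mrna) {
  n <- max(length(fc_mirna), length(fc_phas), length(fc_mrna))
  fc_mirna <- rep_len(fc_mirna, n)
  fc_phas <- rep_len(fc_phas, n)
  fc_mrna <- rep_len(fc_mrna, n)
  s <- fc_mirna * fc_mrna < 0 & abs(fc_mirna) > 1 & abs(fc_mrna) > 1
  phas_absent <- is.na(fc_phas)
  m1_clause <- ifelse(phas_absent, TRUE,
                      fc_mirna * fc_phas < 0 | abs(fc_phas) < 1)
  m2_clause <- ifelse(phas_absent, FALSE,
                      fc_mirna * fc_phas > 0 & abs(fc_phas) > 1)
  ifelse(s & m2_clause, "model2", ifelse(s & m1_clause, "model1", "none"))
}

#' Filter candidate pairs by expression correlation
#'
#' Pearson correlation (Spearman by configuration) of the two features'
#' `log2(RP10M + 1)` profiles across all libraries; pairs are kept when
#' `r > r_min` (strict). Constant profiles have undefined correlation and
#' are dropped with a warning.
#'
#' @param log2_expr tibble (`feature_id` + library columns) of log2 RP10M.
#' @param pairs tibble with `source` and `target` feature ids.
#' @param config a [phas_config()] (uses `r_min`, `cor_method`).
#' @return `pairs` with an `r` column, filtered to `r > r_min`.
#' @export
correlation_edges <- function(log2_expr, pairs, config = phas_config()) {
  libs <- setdiff(names(log2_expr), "feature_id")
  m <- as.matrix(log2_expr[libs])
  rownames(m) <- log2_expr$feature_id
  missing <- setdiff(unique(c(pairs$source, pairs$target)), rownames(m))
  if (length(missing)) stop("pair feature(s) missing from expression: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- m[pairs$source[i], ]; b <- m[pairs$target[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = config$cor_method)
  }, numeric(1))
  if (anyNA(r)) warning(sum(is.na(r)),
                        " pair(s) with constant profiles dropped",
                        call. = FALSE)
  pairs$r <- r
  pairs[!is.na(r) & r > config$r_min, , drop = FALSE]
}

#' Assemble the miRNA-PHAS-mRNA regulatory network
#'
#' Joins trigger assignments (miRNA -> PHAS) with accepted target
#' predictions (miRNA -> mRNA, phasiRNA -> mRNA), maps the three fold
#' changes on, classifies every triple with [classify_triple()], and emits
#' an edge table. miRNAs with accepted mRNA targets but no trigger enter as
#' Model-1 candidates with no PHAS locus. Features that never reach the FDR
#' cut-off contribute a fold change of 0 (not differentially expressed).
#' miRNA -> PHAS trigger edges are filtered by expression correlation
#' `r > r_min`; miRNA -> mRNA edges are annotated with `r` but not
#' filtered.
#'
#' @param triggers tibble from [identify_triggers()].
#' @param targets tibble from [predict_targets()] (both miRNA and phasiRNA
#'   rows; phasiRNA rows carry `phas_id`).
#' @param de named list of `phasnet_de` tibbles: `mirna`, `phas`, `mrna`.
#' @param log2_expr tibble of log2 RP10M across all feature classes, for
#'   correlation.
#' @param config a [phas_config()].
#' @return object of class `phasnet_network`: list with `triples` (one row
#'   per miRNA-PHAS-mRNA combination with fold changes, correlation and
#'   model label) and `edges` (source, target, edge_type, sign, r).
#' @export
assemble_network <- function(triggers, targets, de, log2_expr,
                             config = phas_config()) {
  acc <- targets[targets$accepted, , drop = FALSE]
  mi_tg <- acc[acc$srna_class == "miRNA", , drop = FALSE]
  ph_tg <- acc[acc$srna_class == "phasiRNA", , drop = FALSE]
  de_all <- dplyr::bind_rows(de)
  fc_of <- function(ids) {
    idx <- match(ids, de_all$feature_id)
    fc <- ifelse(de_all$fdr[idx] <= config$fdr, de_all$log2fc[idx], 0)
    fc[is.na(idx) & is.na(ids)] <- NA
    fc
  }
  referenced <- c(triggers$mirna_id, triggers$phas_id, mi_tg$srna_id,
                  mi_tg$transcript_id, ph_tg$transcript_id)
  dangling <- setdiff(unique(referenced), de_all$feature_id)
  if (length(dangling)) {
    stop("feature id(s) not quantified: ", paste(dangling, collapse = ", "),
         call. = FALSE)
  }
  trig <- triggers[c("mirna_id", "phas_id")]
  base <- dplyr::left_join(mi_tg[c("srna_id", "transcript_id")],
                           trig, by = c(srna_id = "mirna_id"),
                           relationship = "many-to-many")
  triples <- tibble(
    mirna_id = base$srna_id,
    phas_id = base$phas_id,
    mrna_id = base$transcript_id)
  triples$log2fc_mirna <- fc_of(triples$mirna_id)
  triples$log2fc_phas <- ifelse(is.na(triples$phas_id), NA,
                                fc_of(triples$phas_id))
  triples$log2fc_mrna <- fc_of(triples$mrna_id)
  # phasiRNA support: some phasiRNA of the triggered locus also targets the
  # same mRNA
  triples$phasi_support <- mapply(function(ph, mr) {
    !is.na(ph) && any(ph_tg$phas_id == ph & ph_tg$transcript_id == mr)
  }, triples$phas_id, triples$mrna_id)
  triples$model <- classify_triple(triples$log2fc_mirna, triples$log2fc_phas,
                                   triples$log2fc_mrna)
  # edges: miRNA->PHAS (positive, correlation-filtered), miRNA->mRNA
  # (negative, annotated with r)
  trig_pairs <- unique(trig)
  names(trig_pairs) <- c("source", "target")
  trig_edges <- if (nrow(trig_pairs)) {
    e <- correlation_edges(log2_expr, trig_pairs, config)
    if (nrow(e)) dplyr::mutate(e, edge_type = "trigger", sign = "positive")
    else NULL
  } else NULL
  mi_pairs <- unique(tibble(source = mi_tg$srna_id,
                            target = mi_tg$transcript_id))
  mi_edges <- if (nrow(mi_pairs)) {
    libs <- setdiff(names(log2_expr), "feature_id")
    m <- as.matrix(log2_expr[libs]); rownames(m) <- log2_expr$feature_id
    mi_pairs$r <- vapply(seq_len(nrow(mi_pairs)), function(i) {
      a <- m[mi_pairs$source[i], ]; b <- m[mi_pairs$target[i], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b, method = config$cor_method)
    }, numeric(1))
    dplyr::mutate(mi_pairs, edge_type = "target", sign = "negative")
  } else NULL
  edges <- dplyr::bind_rows(trig_edges, mi_edges)
  pn_log("assemble_network", "%d triples (%d model1, %d model2), %d edges",
         nrow(triples), sum(triples$model == "model1"),
         sum(triples$model == "model2"), if (is.null(edges)) 0L
         else nrow(edges))
  structure(list(triples = triples, edges = edges %||%
                   tibble(source = character(0), target = character(0),
                          r = numeric(0), edge_type = character(0),
                          sign = character(0))),
            class = "phasnet_network")
}

#' @export
print.phasnet_network <- function(x, ...) {
  cat("<phasnet_network>\n")
  cat("  triples:", nrow(x$triples),
      sprintf("(model1 %d, model2 %d)\n",
              sum(x$triples$model == "model1"),
              sum(x$triples$model == "model2")))
  cat("  edges:  ", nrow(x$edges), "\n")
  invisible(x)
}
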