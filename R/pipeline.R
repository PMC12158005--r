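#' Run the complete annotation and network pipeline on a study
#'
#' Executes every stage in order on a study object (typically from
#' [simulate_srna_study()], or assembled from real inputs with the same
#' fields): collapse and blacklist-filter reads, align tags, call MIR and
#' PHAS loci, assign triggers, quantify and test differential expression,
#' predict miRNA and phasiRNA targets, validate them against the
#' degradome, and assemble the regulatory network.
#'
#' @param study list with `reads`, `blacklist`, `sim$genome` (or `genome`),
#'   `known_mirnas`, `manifest`, `transcripts`, `mrna_counts`,
#'   `mrna_manifest`, `degradome`.
#' @param config a [phas_config()].
#' @return list of all stage outputs: `tags`, `hits`, `mir` (all calls),
#'   `mir_unique` (one row per distinct mature tag), `phas`, `triggers`,
#'   `counts`, `de` (list of `phasnet_de`), `targets`, `deg_profile`,
#'   `validated`, `network`.
#' @export
run_pipeline <- function(study, config = phas_config()) {
  genome <- study$genome %||% study$sim$genome
  tags <- collapse_reads(study$reads[c("library_id", "seq")])
  tags <- filter_blacklist(tags, study$blacklist %||%
                             tibble(id = character(0), seq = character(0)))
  hits <- align_tags(tags, genome, config$max_mismatches)
  mir <- call_mirnas(hits, tags, known = study$known_mirnas, config = config)
  mir_u <- mir[!duplicated(mir$mature_tag), , drop = FALSE]
  chrom_lengths <- stats::setNames(nchar(genome$seq), genome$id)
  phas <- dplyr::bind_rows(
    scan_phas(hits, tags, 21L, chrom_lengths, config),
    scan_phas(hits, tags, 24L, chrom_lengths, config))
  triggers <- identify_triggers(
    tibble(id = mir_u$locus_id, seq = mir_u$mature_seq),
    phas, genome, config)

  libs <- tag_libraries(tags)
  totals <- stats::setNames(study$manifest$total_clean_reads,
                            study$manifest$library_id)
  mir_counts <- dplyr::bind_cols(
    tibble(feature_id = mir_u$locus_id),
    tags[match(mir_u$mature_tag, tags$tag_id), libs, drop = FALSE])
  phas_counts <- dplyr::bind_rows(lapply(seq_len(nrow(phas)), function(i) {
    ph <- phas$phasirnas[[i]]
    sel <- tags$seq %in% ph$seq
    dplyr::bind_cols(tibble(feature_id = phas$locus_id[i]),
                     as_tibble(as.list(colSums(tags[sel, libs,
                                                    drop = FALSE]))))
  }))
  if (nrow(mir_u) > 0) {
    mature_expr <- rp10m(dplyr::bind_cols(tibble(feature_id = mir_u$mature_tag),
                                          mir_counts[libs]), totals)
    mir_u <- flag_probably(mir_u, mature_expr, config)
  }

  de <- list(
    mirna = differential(mir_counts, study$manifest, "miRNA", config),
    phas = if (nrow(phas_counts) > 0) {
      differential(phas_counts, study$manifest, "PHAS", config)
    } else NULL,
    mrna = differential(study$mrna_counts, study$mrna_manifest, "mRNA",
                        config))

  srnas <- dplyr::bind_rows(
    tibble(id = mir_u$locus_id, seq = mir_u$mature_seq, class = "miRNA",
           phas_id = NA_character_),
    dplyr::bind_rows(lapply(seq_len(nrow(phas)), function(i) {
      top <- top_phasirnas(phas[i, ], config$top_n_phasirna)
      tibble(id = sprintf("%s_p%d", phas$locus_id[i], top$rank),
             seq = top$seq, class = "phasiRNA", phas_id = phas$locus_id[i])
    })))
  targets <- predict_targets(srnas, study$transcripts, config)
  deg_profile <- map_degradome(study$degradome, study$transcripts)
  validated <- validate_interactions(
    targets[targets$accepted, , drop = FALSE], deg_profile,
    study$transcripts, config)

  log2_expr <- dplyr::bind_rows(
    log2_rp10m(rp10m(dplyr::bind_rows(mir_counts, phas_counts), totals)),
    log2_rp10m(rp10m(study$mrna_counts,
                     stats::setNames(study$mrna_manifest$total_clean_reads,
                                     study$mrna_manifest$library_id))))
  network <- assemble_network(triggers, targets,
                              de[!vapply(de, is.null, logical(1))],
                              log2_expr, config)
  list(tags = tags, hits = hits, mir = mir, mir_unique = mir_u, phas = phas,
       triggers = triggers,
       counts = list(mirna = mir_counts, phas = phas_counts,
                     mrna = study$mrna_counts),
       de = de, targets = targets, deg_profile = deg_profile,
       validated = validated, network = network)
}
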