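#' Annotation inventory bookkeeping
#'
#' Derives the headline inventory of an annotation run from its category
#' counts: total miRNAs (known + novel), total PHAS loci (21-nt + 24-nt),
#' the percentage of PHAS loci with an assigned trigger, the percentage of
#' miRNAs acting as triggers, and the total number of network pairs
#' (Model 1 + Model 2). Percentages are rounded to whole numbers, the
#' reporting convention of the annotation literature.
#'
#' @param inventory named list (or the path-free result of
#'   [read_inventory()]) with counts `mirna_known`, `mirna_novel`,
#'   `phas21_loci`, `phas24_loci`, `phas_triggered`, `trigger_mirnas`,
#'   `model1_pairs`, `model2_pairs`.
#' @return tibble with `quantity` and `value` columns.
#' @examples
#' summarize_inventory(read_inventory())
#' @export
summarize_inventory <- function(inventory) {
  req <- c("mirna_known", "mirna_novel", "phas21_loci", "phas24_loci",
           "phas_triggered", "trigger_mirnas", "model1_pairs",
           "model2_pairs")
  missing <- setdiff(req, names(inventory))
  if (length(missing)) stop("inventory missing: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  inv <- lapply(inventory, as.numeric)
  mirna_total <- inv$mirna_known + inv$mirna_novel
  phas_total <- inv$phas21_loci + inv$phas24_loci
  tibble(
    quantity = c("mirna_total", "phas_total", "pct_phas_triggered",
                 "pct_mirna_triggering", "network_pairs_total"),
    value = c(mirna_total, phas_total,
              round(100 * inv$phas_triggered / phas_total),
              round(100 * inv$trigger_mirnas / mirna_total),
              inv$model1_pairs + inv$model2_pairs))
}

#' Read a stored annotation inventory
#'
#' @param path JSON file of category counts; defaults to the packaged
#'   Ginkgo biloba inventory.
#' @return named list of counts.
#' @export
read_inventory <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ginkgo_inventory.json",
                                package = "phasnet")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Summarise an annotation run
#'
#' Counts the same inventory categories from live pipeline outputs, so a
#' run's headline numbers come from the same reporting code path as stored
#' inventories.
#'
#' @param result list from [run_pipeline()].
#' @return named list of counts suitable for [summarize_inventory()].
#' @export
run_inventory <- function(result) {
  mir <- result$mir_unique
  phas <- result$phas
  trig <- result$triggers
  triples <- result$network$triples
  list(
    mirna_known = sum(!mir$novel),
    mirna_novel = sum(mir$novel),
    phas21_loci = sum(phas$period == 21),
    phas24_loci = sum(phas$period == 24),
    phas_triggered = length(unique(trig$phas_id)),
    trigger_mirnas = length(unique(trig$mirna_id)),
    model1_pairs = sum(triples$model == "model1"),
    model2_pairs = sum(triples$model == "model2"))
}
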