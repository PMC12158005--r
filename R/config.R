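#' Pipeline configuration with published defaults
#'
#' Every numeric cut-off used anywhere in the pipeline lives in this one flat
#' configuration object; no operation hard-codes a threshold. The defaults are
#' the published values of the analysis the package implements: read cleaning
#' (minimum 18 nt), genome alignment (at most 2 mismatches), the MIR locus
#' criteria (5-300 nt mature/star spacing, 20-22 nt mature, at most 20 genomic
#' hits, mature+star at least 75\% of locus reads), the PHAS locus criteria
#' (locus longer than 100 bp, phased abundance above 30\%, p-value below 0.001,
#' phasing score above 10), trigger assignment (400 bp of added flank, penalty
#' at most 5), target prediction (Allen score below 7, MFE ratio above 0.65),
#' degradome validation (categories 0-3, penalty at most 6), the top-30
#' phasiRNA selection, and the expression thresholds (|log2FC| >= 2 for
#' miRNAs, >= 1 for PHAS loci and mRNAs, FDR <= 0.05, RP10M > 10, r > 0.7).
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `phasnet_config`.
#'
#' @details Non-threshold switches:
#' \describe{
#'   \item{position_model}{`"all"` (default): every nucleotide on both strands
#'     of a window is an eligible 5' end in the hypergeometric phasing test;
#'     `"grid"`: the coarse register-class model (see the methods vignette).}
#'   \item{probably_mode}{`"all"` flags a miRNA as "probably" only when its
#'     RP10M is below `min_rp10m` in every library; `"any"` flags when any
#'     single library is below the cut-off.}
#'   \item{rp10m_gate_mode}{`"any"`: a feature enters differential testing if
#'     RP10M exceeds `min_rp10m` in at least one library; `"group"` requires
#'     the whole of one tissue group.}
#'   \item{trigger_flank_mode}{`"total"`: the 400 bp of flanking sequence is
#'     split 200 bp per side of the PHAS locus; `"per_side"` adds 400 bp on
#'     each side.}
#'   \item{multimap_phas}{apply the 20-hit multi-mapping filter before PHAS
#'     scanning as well as before miRNA calling (default TRUE).}
#' }
#'
#' @examples
#' cfg <- phas_config(allen_max = 6)
#' cfg$allen_max
#' @export
phas_config <- function(...) {
  cfg <- list(
    # preprocessing
    min_read_len = 18L,
    max_read_len = 34L,
    max_mismatches = 2L,
    adapter_seed_len = 8L,
    # miRNA locus calling
    max_genome_hits = 20L,
    duplex_fraction = 0.75,
    mature_len = c(20L, 22L),
    star_spacing = c(5L, 300L),
    max_unpaired = 5L,
    isomir_tol = 1L,
    candidate_gap = 200L,
    naming_max_mismatch = 2L,
    # PHAS locus calling
    phas_min_len = 100L,
    phas_pmax = 0.001,
    phas_min_score = 10,
    phas_min_phased_frac = 0.30,
    phas_cycles = 11L,
    position_model = "all",
    multimap_phas = TRUE,
    # trigger assignment
    trigger_window = 400L,
    trigger_flank_mode = "total",
    trigger_max_penalty = 5,
    # target prediction
    allen_max = 7,
    mfe_ratio_min = 0.65,
    site_max_raw = 4,
    # degradome validation
    degradome_max_category = 3L,
    degradome_max_penalty = 6,
    degradome_slop = 1L,
    # phasiRNA selection
    top_n_phasirna = 30L,
    # expression / network
    mirna_fc = 2,
    phas_fc = 1,
    mrna_fc = 1,
    fdr = 0.05,
    min_rp10m = 10,
    r_min = 0.7,
    cor_method = "pearson",
    probably_mode = "all",
    rp10m_gate_mode = "any",
    random_seed = 1L
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  structure(cfg, class = "phasnet_config")
}

#' Read and write a configuration file
#'
#' Configurations serialise to YAML and round-trip losslessly.
#'
#' @param config a `phasnet_config` object.
#' @param path file path.
#' @return `read_phas_config()` returns a `phasnet_config`.
#' @export
write_phas_config <- function(config, path) {
  stopifnot(inherits(config, "phasnet_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_phas_config
#' @export
read_phas_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(phas_config, vals)
}

#' @export
print.phasnet_config <- function(x, ...) {
  cat("<phasnet_config> with", length(x), "settings\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' @importFrom utils str
NULL
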