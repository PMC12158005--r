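#' Generate a random background genome
#'
#' I.i.d. background sequence at a given GC content; deterministic for a
#' given seed. The returned object is a simulation container that tracks
#' planted features so later plants cannot overlap.
#'
#' @param length genome length in nt (must be positive).
#' @param gc GC fraction.
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param chrom chromosome name.
#' @return a `phasnet_sim` object; its `$genome` field is a [read_fasta()]
#'   style tibble.
#' @export
make_genome <- function(length, gc = 0.4, seed = NULL, chrom = "chr1") {
  if (length <= 0) stop("genome length must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  structure(list(
    genome = tibble(id = chrom, seq = seq),
    planted = tibble(chrom = character(0), start = integer(0),
                     end = integer(0), what = character(0)),
    mir = NULL, phas = NULL
  ), class = "phasnet_sim")
}

# Reserve [start, end) on the simulated genome; overlapping plants error.
reserve_span <- function(sim, start, end, what, chrom = sim$genome$id[1]) {
  clash <- sim$planted$chrom == chrom &
    sim$planted$start < end & start < sim$planted$end
  if (any(clash)) {
    stop(sprintf("plant '%s' at [%d,%d) overlaps existing '%s'", what,
                 start, end, sim$planted$what[which(clash)[1]]),
         call. = FALSE)
  }
  sim$planted <- dplyr::bind_rows(sim$planted,
                                  tibble(chrom = chrom, start = start,
                                         end = end, what = what))
  sim
}

# Random unoccupied position keeping `margin` nt clear of previous plants
# and of the genome ends.
free_position <- function(sim, span, margin = 500L) {
  glen <- nchar(sim$genome$seq[1])
  for (i in 1:1000) {
    at <- sample.int(glen - span - 2L * margin, 1L) + margin
    clash <- any(sim$planted$start < at + span + margin &
                   at - margin < sim$planted$end)
    if (!clash) return(at)
  }
  stop("could not place a feature; genome too crowded", call. = FALSE)
}

splice_genome <- function(sim, at, insert) {
  g <- sim$genome$seq[1]
  sim$genome$seq[1] <- paste0(substr(g, 1, at),
                              insert,
                              substr(g, at + nchar(insert) + 1L, nchar(g)))
  sim
}

# Star sequence forming a perfect duplex with 2-nt 3' overhangs: star
# positions 1..L-2 pair mature positions L-2..1, the last two star bases
# are free.
star_of <- function(mature) {
  L <- nchar(mature)
  paste0(substr(revcomp(mature), 3L, L), "CA")
}

#' Plant a MIR hairpin
#'
#' Writes mature + loop + star (or star + loop + mature for the 3' arm)
#' into the genome so that the mature/star duplex criteria hold by
#' construction: perfect complementarity with 2-nt 3' overhangs and an
#' inner spacing of `star_gap` nt. Spacing outside 5-300 nt is refused.
#'
#' @param sim a `phasnet_sim` from [make_genome()].
#' @param mature mature sequence (20-22 nt); random 21-mer when NULL.
#' @param star_gap inner mature-star spacing (loop length), 5-300.
#' @param arm `"5p"` (mature upstream) or `"3p"`.
#' @param at 0-based insertion offset; chosen automatically when NULL.
#' @param id feature id recorded in the truth table.
#' @param fc planted log2 fold change (reproductive vs vegetative).
#' @param seed optional seed.
#' @return the updated `phasnet_sim`; the `$mir` truth table gains a row
#'   with mature/star coordinates and sequences.
#' @export
plant_mir <- function(sim, mature = NULL, star_gap = 40L, arm = "5p",
                      at = NULL, id = NULL, fc = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (star_gap < 5L || star_gap > 300L) {
    stop("star_gap must be within 5-300 nt", call. = FALSE)
  }
  if (is.null(mature)) {
    mature <- paste(sample(c("A", "C", "G", "T"), 21L, replace = TRUE),
                    collapse = "")
  }
  star <- star_of(mature)
  loop <- paste(sample(c("A", "C", "G", "T"), star_gap, replace = TRUE),
                collapse = "")
  hairpin <- if (arm == "5p") paste0(mature, loop, star)
             else paste0(star, loop, mature)
  if (is.null(at)) at <- free_position(sim, nchar(hairpin))
  id <- id %||% sprintf("mir_%d", nrow(sim$mir %||% tibble()) + 1L)
  sim <- reserve_span(sim, at, at + nchar(hairpin), id)
  sim <- splice_genome(sim, at, hairpin)
  lm <- nchar(mature); ls <- nchar(star)
  mstart <- if (arm == "5p") at else at + ls + star_gap
  sstart <- if (arm == "5p") at + lm + star_gap else at
  row <- tibble(id = id, chrom = sim$genome$id[1], start = at,
                end = at + nchar(hairpin), arm = arm,
                mature_seq = mature, mature_start = mstart,
                star_seq = star, star_start = sstart,
                star_gap = as.integer(star_gap), fc = fc)
  sim$mir <- dplyr::bind_rows(sim$mir, row)
  sim
}

#' Plant a PHAS locus
#'
#' Reserves a phased region of `cycles * period` nt and, when a trigger
#' miRNA is given, writes its perfectly complementary site so that the
#' predicted cleavage coordinate (opposite sRNA positions 10-11) is exactly
#' the first phased position: the cleavage sets register 0 of the run. The
#' phased reads themselves are emitted by [simulate_libraries()] from the
#' final genome sequence.
#'
#' @param sim a `phasnet_sim`.
#' @param period 21 or 24.
#' @param cycles number of phased cycles (at least 3).
#' @param trigger optional trigger: either the id of a planted MIR (its
#'   mature sequence is used) or an explicit sRNA sequence.
#' @param at 0-based start of the phased run; automatic when NULL.
#' @param id feature id.
#' @param fc planted log2 fold change.
#' @param seed optional seed.
#' @return the updated `phasnet_sim`; `$phas` gains a truth row with the
#'   register and trigger site coordinates.
#' @export
plant_phas <- function(sim, period = 21L, cycles = 11L, trigger = NULL,
                       at = NULL, id = NULL, fc = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cycles < 3L) stop("cycles must be at least 3", call. = FALSE)
  span <- period * cycles
  trig_seq <- NULL
  trig_id <- NA_character_
  if (!is.null(trigger)) {
    if (!is.null(sim$mir) && trigger %in% sim$mir$id) {
      trig_id <- trigger
      trig_seq <- sim$mir$mature_seq[sim$mir$id == trigger]
    } else {
      trig_id <- "explicit"
      trig_seq <- trigger
    }
  }
  lead <- if (is.null(trig_seq)) 0L else nchar(trig_seq) - 10L  # site lead-in
  if (is.null(at)) at <- free_position(sim, span + lead) + lead
  id <- id %||% sprintf("phas_%d", nrow(sim$phas %||% tibble()) + 1L)
  sim <- reserve_span(sim, at - lead, at + span, id)
  site_start <- NA_integer_
  if (!is.null(trig_seq)) {
    L <- nchar(trig_seq)
    site_start <- at + 10L - L  # cleavage (opposite position 10) lands at `at`
    sim <- splice_genome(sim, site_start, revcomp(trig_seq))
  }
  row <- tibble(id = id, chrom = sim$genome$id[1], start = at,
                end = at + span, period = as.integer(period),
                cycles = as.integer(cycles),
                register = as.integer(at %% period),
                trigger_id = trig_id, trigger_site = site_start, fc = fc)
  sim$phas <- dplyr::bind_rows(sim$phas, row)
  sim
}

#' Plant a target site on a transcript
#'
#' Inserts the perfect reverse complement of an sRNA so the duplex engine
#' finds a site with Allen score 0 and MFE ratio 1; the predicted cleavage
#' coordinate is `at + length(srna) - 10` (0-based).
#'
#' @param transcripts transcript tibble.
#' @param srna_seq sRNA sequence.
#' @param transcript_id which transcript to modify.
#' @param at 0-based site start on the transcript.
#' @param srna_ref label recorded in the truth row.
#' @param cleavable whether [simulate_degradome()] should pile reads at the
#'   cleavage position.
#' @return list with `transcripts` (updated) and `site` (truth row).
#' @export
plant_target_site <- function(transcripts, srna_seq, transcript_id, at,
                              srna_ref = NA_character_, cleavable = TRUE) {
  i <- match(transcript_id, transcripts$id)
  if (is.na(i)) stop("unknown transcript: ", transcript_id, call. = FALSE)
  L <- nchar(srna_seq)
  tseq <- transcripts$seq[i]
  if (at + L > nchar(tseq)) {
    stop("target site extends past the end of ", transcript_id,
         call. = FALSE)
  }
  transcripts$seq[i] <- paste0(substr(tseq, 1, at), revcomp(srna_seq),
                               substr(tseq, at + L + 1L, nchar(tseq)))
  site <- tibble(srna_ref = srna_ref, srna_seq = srna_seq,
                 transcript_id = transcript_id, site_start = at,
                 site_end = at + L,
                 cleavage = at + L - 10L, cleavable = cleavable)
  list(transcripts = transcripts, site = site)
}

# Enumerate the read species of all planted features plus background noise.
# Returns tibble(species_id, feature, feature_class, seq, length, base, fc).
planted_species <- function(sim, mature_base = 80, star_base = 15,
                            other_base = 3, phased_base = 12,
                            offreg_base = 2, n_noise = 150L,
                            noise_base = 5) {
  g <- sim$genome$seq[1]
  sp <- vector("list", 0)
  gsub_at <- function(start0, len) substr(g, start0 + 1L, start0 + len)
  for (i in seq_len(nrow(sim$mir %||% tibble()))) {
    m <- sim$mir[i, ]
    lm <- nchar(m$mature_seq)
    # mature, star, and two low-abundance bystander reads (an offset isomiR
    # beyond the +/-1 tolerance and a loop fragment)
    sp[[length(sp) + 1]] <- tibble(
      feature = m$id, feature_class = "mirna",
      part = c("mature", "star", "other1", "other2"),
      seq = c(m$mature_seq, m$star_seq,
              gsub_at(m$mature_start + 4L, lm),
              gsub_at(m$mature_start + lm + 2L, 21L)),
      base = c(mature_base, star_base, other_base, other_base),
      fc = m$fc)
  }
  for (i in seq_len(nrow(sim$phas %||% tibble()))) {
    p <- sim$phas[i, ]
    per <- p$period
    plus <- tibble(part = sprintf("p%02d", seq_len(p$cycles) - 1L),
                   seq = vapply(seq_len(p$cycles) - 1L, function(j)
                     gsub_at(p$start + j * per, per), character(1)),
                   base = phased_base)
    jminus <- seq_len(p$cycles - 1L)
    minus <- tibble(part = sprintf("m%02d", jminus),
                    seq = revcomp(vapply(jminus, function(j)
                      gsub_at(p$start + j * per - 2L - (per - 1L), per),
                      character(1))),
                    base = phased_base)
    offreg <- tibble(part = c("off1", "off2", "short"),
                     seq = c(gsub_at(p$start + per + 5L, per),
                             gsub_at(p$start + 3L * per + 9L, per),
                             gsub_at(p$start + 2L * per + 1L, per - 1L)),
                     base = offreg_base)
    sp[[length(sp) + 1]] <- dplyr::bind_rows(plus, minus, offreg) |>
      dplyr::mutate(feature = p$id, feature_class = "phas", fc = p$fc)
  }
  glen <- nchar(g)
  if (n_noise > 0) {
    lens <- sample(c(20L, 21L, 22L, 24L), n_noise, replace = TRUE,
                   prob = c(0.2, 0.4, 0.2, 0.2))
    starts <- sample.int(glen - 40L, n_noise)
    strands <- sample(c("+", "-"), n_noise, replace = TRUE)
    seqs <- substr(rep(g, n_noise), starts + 1L, starts + lens)
    seqs[strands == "-"] <- revcomp(seqs[strands == "-"])
    sp[[length(sp) + 1]] <- tibble(
      feature = "noise", feature_class = "noise",
      part = sprintf("n%04d", seq_len(n_noise)),
      seq = seqs, base = noise_base, fc = 0)
  }
  out <- dplyr::bind_rows(sp)
  out$length <- nchar(out$seq)
  out$species_id <- paste(out$feature, out$part, sep = ".")
  # distinct sequences only: a duplicated noise draw collapses anyway
  out[!duplicated(out$seq), ]
}

#' Simulate the multi-tissue sRNA libraries
#'
#' Per-library counts for every planted read species are drawn from a
#' negative binomial around tissue-group means that encode the planted
#' log2 fold changes (`mu = depth_factor * base * 2^(fc/2)` in reproductive
#' libraries and `2^(-fc/2)` in vegetative ones, so the group-mean ratio is
#' `2^fc`); background noise species are uniform over the genome with no
#' fold change. Contaminant (blacklist) species are added when the
#' simulation carries them.
#'
#' @param sim a `phasnet_sim` with planted features.
#' @param manifest manifest tibble (`total_clean_reads` may be a
#'   placeholder; it is recomputed and returned).
#' @param depth_factor global abundance multiplier (default 5, about 25k
#'   reads per library at the default feature panel).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`; default 0.1).
#' @param n_noise number of background noise species.
#' @param noise_base mean copies per noise species and library.
#' @param blacklist optional tibble of contaminant source sequences; 21-nt
#'   fragments of each are spiked in at `blacklist_base` copies.
#' @param blacklist_base mean copies per contaminant species.
#' @param seed optional seed.
#' @return list with `reads` (tibble `library_id`, `seq`), `species`
#'   (the species truth table), `species_counts` (species x library), and
#'   `manifest` with recomputed `total_clean_reads` (contaminants
#'   excluded).
#' @export
simulate_libraries <- function(sim, manifest, depth_factor = 5,
                               dispersion = 0.1, n_noise = 150L,
                               noise_base = 5, blacklist = NULL,
                               blacklist_base = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  species <- planted_species(sim, n_noise = n_noise, noise_base = noise_base)
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    bl <- tibble(feature = blacklist$id, feature_class = "blacklist",
                 part = "frag",
                 seq = substr(blacklist$seq, 10L, 30L),
                 base = blacklist_base, fc = 0,
                 length = 21L,
                 species_id = paste0(blacklist$id, ".frag"))
    species <- dplyr::bind_rows(species, bl)
  }
  nsp <- nrow(species)
  counts <- matrix(0L, nsp, nrow(manifest),
                   dimnames = list(species$species_id, manifest$library_id))
  for (li in seq_len(nrow(manifest))) {
    dir <- if (manifest$group[li] == "reproductive") 1 else -1
    mu <- depth_factor * species$base * 2^(species$fc / 2 * dir)
    counts[, li] <- stats::rnbinom(nsp, mu = mu, size = 1 / dispersion)
  }
  reads <- dplyr::bind_rows(lapply(seq_len(nrow(manifest)), function(li) {
    tibble(library_id = manifest$library_id[li],
           seq = rep(species$seq, counts[, li]))
  }))
  clean <- species$feature_class != "blacklist"
  manifest$total_clean_reads <- pmax(1, colSums(counts[clean, , drop = FALSE]))
  pn_log("simulate_libraries", "%d species, %d reads over %d libraries",
         nsp, nrow(reads), nrow(manifest))
  list(reads = reads, species = species, species_counts = counts,
       manifest = manifest)
}

#' Simulate a degradome library
#'
#' 5'-end read pileups concentrated at the cleavage coordinates of the
#' planted cleavable target sites (height `peak_height`) over a sparse
#' uniform background, mimicking the 5'-monophosphate capture of true
#' slicing products.
#'
#' @param sites truth tibble of planted sites ([plant_target_site()]).
#' @param transcripts transcript tibble (post-planting).
#' @param peak_height mean reads at each cleavage position.
#' @param background_n total background reads spread uniformly.
#' @param read_len degradome read length (default 20).
#' @param seed optional seed.
#' @return tibble of reads (`id`, `seq`).
#' @export
simulate_degradome <- function(sites, transcripts, peak_height = 50,
                               background_n = 120L, read_len = 20L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reads <- vector("list", 0)
  cle <- sites[sites$cleavable, , drop = FALSE]
  for (i in seq_len(nrow(cle))) {
    tseq <- transcripts$seq[transcripts$id == cle$transcript_id[i]]
    n <- stats::rpois(1, peak_height)
    frag <- substr(tseq, cle$cleavage[i] + 1L, cle$cleavage[i] + read_len)
    if (nchar(frag) == read_len && n > 0) {
      reads[[length(reads) + 1]] <- tibble(seq = rep(frag, n))
    }
  }
  if (background_n > 0) {
    ti <- sample.int(nrow(transcripts), background_n, replace = TRUE)
    tlen <- nchar(transcripts$seq[ti])
    pos <- floor(stats::runif(background_n) * (tlen - read_len))
    reads[[length(reads) + 1]] <- tibble(
      seq = substr(transcripts$seq[ti], pos + 1L, pos + read_len))
  }
  out <- dplyr::bind_rows(reads)
  out$id <- sprintf("deg%06d", seq_len(nrow(out)))
  out[c("id", "seq")]
}

#' Simulate a complete synthetic sRNA study
#'
#' Builds the default synthetic experiment used throughout the package's
#' tests: a 50-kb genome carrying 6 MIR hairpins and 8 PHAS loci (two with
#' a 24-nt period), 12 transcripts of 600 nt, and 8 libraries (4
#' reproductive, 4 vegetative; about 200k reads in total at the default
#' depth). The planted regulatory truth comprises one Model-2 triple
#' (an up-regulated miRNA triggering an up-regulated PHAS locus and
#' repressing a CHS-like transcript, with a phasiRNA of the locus hitting
#' the same transcript), one triggered Model-1 triple (flat PHAS locus),
#' one trigger-less Model-1 pair, trigger-free decoy PHAS loci, and
#' non-differential decoy features. Planted fold changes are +/-4 for the
#' miRNA/mRNA pairs and +2 for the Model-2 PHAS locus.
#'
#' @param seed integer seed; the whole study is a deterministic function
#'   of it.
#' @param genome_length genome size (default 50 kb).
#' @param n_mir,n_phas,n_phas24 feature counts (defaults 6, 8, 2).
#' @param n_transcripts,transcript_length transcriptome size (12 x 600 nt).
#' @param depth_factor,dispersion,n_noise,noise_base library simulation
#'   parameters; see [simulate_libraries()].
#' @param peak_height,deg_background degradome parameters; see
#'   [simulate_degradome()].
#' @return list with `sim` (genome + planted truth), `manifest`, `reads`,
#'   `blacklist`, `known_mirnas`, `transcripts`, `sites`, `mrna_counts`,
#'   `mrna_manifest`, `degradome`, `species`, `species_counts`.
#' @export
simulate_srna_study <- function(seed = 1L, genome_length = 50000L,
                                n_mir = 6L, n_phas = 8L, n_phas24 = 2L,
                                n_transcripts = 12L,
                                transcript_length = 600L,
                                depth_factor = 5, dispersion = 0.1,
                                n_noise = 150L, noise_base = 5,
                                peak_height = 50, deg_background = 120L) {
  set.seed(seed)
  sim <- make_genome(genome_length, gc = 0.4)
  # planted fold changes: mir_1..3 carry the +4 reproductive programme,
  # mir_4 is a vegetative-preferred miRNA (-4) and the rest are flat
  # decoys. Planting both directions keeps library composition balanced,
  # as in real multi-tissue designs
  mir_fc <- c(4, 4, 4, -4, rep(0, max(0, n_mir - 4L)))[seq_len(n_mir)]
  for (i in seq_len(n_mir)) {
    sim <- plant_mir(sim, star_gap = sample(30:60, 1), fc = mir_fc[i],
                     id = sprintf("mir_%d", i))
  }
  # phas_1: Model-2 locus (triggered by mir_1, fc +2); phas_2: triggered
  # but flat (Model-1); phas_3 and the 24-nt loci are vegetative-preferred
  # (-2, cambium-type); the rest are trigger-free flat decoys
  phas_fc <- numeric(n_phas)
  phas_fc[1] <- 2
  if (n_phas >= 3) phas_fc[3] <- -2
  for (i in seq_len(n_phas)) {
    per <- if (i > n_phas - n_phas24) 24L else 21L
    if (per == 24L) phas_fc[i] <- -2
    trig <- if (i == 1L) "mir_1" else if (i == 2L) "mir_2" else NULL
    sim <- plant_phas(sim, period = per, cycles = 11L, trigger = trig,
                      fc = phas_fc[i], id = sprintf("phas_%d", i))
  }
  manifest <- make_manifest(
    library_id = c("ovule_1", "embryo_1", "FB_1", "MB_1",
                   "leaf_1", "leaf_2", "cambium_1", "cambium_2"),
    tissue = c("ovule", "embryo", "FB", "MB",
               "leaf", "leaf", "cambium", "cambium"),
    total_clean_reads = rep(1, 8))
  # contaminant panel: two rRNA-like sources spiked into every library
  blacklist <- tibble(
    id = c("rRNA_1", "tRNA_1"),
    seq = vapply(1:2, function(i)
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
            collapse = ""), character(1)))
  libs <- simulate_libraries(sim, manifest, depth_factor = depth_factor,
                             dispersion = dispersion, n_noise = n_noise,
                             noise_base = noise_base, blacklist = blacklist)
  # transcripts; mrna_1..3 are the -4 targets, the rest decoys
  transcripts <- tibble(
    id = sprintf("mrna_%d", seq_len(n_transcripts)),
    seq = vapply(seq_len(n_transcripts), function(i)
      paste(sample(c("A", "C", "G", "T"), transcript_length, replace = TRUE),
            collapse = ""), character(1)))
  mrna_fc <- c(-4, -4, -4, rep(0, max(0, n_transcripts - 3L)))
  sites <- vector("list", 0)
  at_mir <- as.integer(floor(transcript_length * 0.4))
  at_phasi <- as.integer(min(transcript_length - 30L,
                             floor(transcript_length * 0.75)))
  for (i in 1:3) {
    ps <- plant_target_site(transcripts, sim$mir$mature_seq[i],
                            sprintf("mrna_%d", i), at = at_mir,
                            srna_ref = sprintf("mir_%d", i))
    transcripts <- ps$transcripts
    sites[[length(sites) + 1]] <- ps$site
  }
  # one phasiRNA of the Model-2 locus also targets the CHS-like mrna_1
  p1 <- sim$phas[sim$phas$id == "phas_1", ]
  phasi_seq <- substr(sim$genome$seq[1], p1$start + 3L * p1$period + 1L,
                      p1$start + 4L * p1$period)
  ps <- plant_target_site(transcripts, phasi_seq, "mrna_1", at = at_phasi,
                          srna_ref = "phas_1.p03")
  transcripts <- ps$transcripts
  sites[[length(sites) + 1]] <- ps$site
  sites <- dplyr::bind_rows(sites)
  # mRNA raw counts with planted fold changes (equal-depth libraries)
  mrna_counts <- tibble(feature_id = transcripts$id)
  for (li in seq_len(nrow(manifest))) {
    dir <- if (manifest$group[li] == "reproductive") 1 else -1
    mu <- 200 * 2^(mrna_fc[seq_len(n_transcripts)] / 2 * dir)
    mrna_counts[[manifest$library_id[li]]] <-
      stats::rnbinom(n_transcripts, mu = mu, size = 1 / dispersion)
  }
  mrna_manifest <- libs$manifest
  mrna_manifest$total_clean_reads <- 1e6
  degradome <- simulate_degradome(sites, transcripts,
                                  peak_height = peak_height,
                                  background_n = deg_background)
  known <- tibble(id = c("gbi-miR159a", "gbi-miR390a"),
                  seq = sim$mir$mature_seq[1:2])
  list(sim = sim, manifest = libs$manifest, reads = libs$reads,
       blacklist = blacklist, known_mirnas = known,
       transcripts = transcripts, sites = sites, mrna_fc = mrna_fc,
       mrna_counts = mrna_counts, mrna_manifest = mrna_manifest,
       degradome = degradome, species = libs$species,
       species_counts = libs$species_counts, seed = seed)
}
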