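# Scaled-down synthetic study used by the seeded recovery suites: same
# planted structure as the default study, smaller genome and depth so that
# one full stage pass stays around a second.
small_study <- function(seed) {
  simulate_srna_study(seed,
                      genome_length = 20000L, n_mir = 4L, n_phas = 4L,
                      n_phas24 = 1L, n_transcripts = 6L,
                      transcript_length = 400L, depth_factor = 1,
                      n_noise = 40L, deg_background = 60L)
}

# Random DNA string.
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Abundance ratio of planted to noise reads in a simulated study.
planted_noise_ratio <- function(study) {
  cls <- study$species$feature_class
  tot <- rowSums(study$species_counts)
  sum(tot[cls %in% c("mirna", "phas")]) / sum(tot[cls == "noise"])
}
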