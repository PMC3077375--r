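# Shared fixtures built in code. The balanced tetraploid simulation is
# expensive enough to build once and reuse across test files.

sim_cache <- new.env(parent = emptyenv())

# Balanced tetraploid hybrid: 50 homozygous-different + 50 HEF-heterozygous
# sites, one per gene, equal per-copy expression, mean site depth ~80,
# substitution error 1%. Run through trim -> align -> pileup.
balanced_tetraploid_sim <- function() {
  if (!is.null(sim_cache$balanced)) return(sim_cache$balanced)
  cfg <- sim_config(
    n_genes = 100, transcript_length = 150,
    n_snps = c(HOM_HOM_DIFF = 50, HET_ONE_HEF = 50),
    coverage = 64, error_rate = 0.01, seed = 42
  )
  genomes <- simulate_donor_genomes(cfg)
  readset <- simulate_hybrid_reads(genomes, expression = NULL)
  trimmed <- trim_anchors(readset)
  alignments <- align_reads(trimmed, genomes$reference)
  pileup <- pileup_counts(alignments)
  sim_cache$balanced <- list(
    config = cfg, genomes = genomes, readset = readset,
    trimmed = trimmed, alignments = alignments, pileup = pileup
  )
  sim_cache$balanced
}

random_dna <- function(n, len) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                           collapse = ""),
         character(1))
}

# mean within 2 standard errors (SE across sites) of the expectation
expect_within_2se <- function(x, expected) {
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 2 * se)
}
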