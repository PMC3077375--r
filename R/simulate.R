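#' Simulation configuration for a fusion-hybrid transcriptome
#'
#' Bundles every knob of the synthetic-data generator: a transcript reference
#' shared by the two donor genomes, discriminating-SNP category counts, the
#' hybrid ploidy model, sequencing parameters and the run seed. Defaults
#' reflect GAII-era single-end RNA sequencing of a tetraploid (2+2) hybrid
#' with balanced per-copy expression.
#'
#' SNP categories (per donor pair, HEF and hFL):
#' \describe{
#'   \item{HOM_HOM_DIFF}{both donors homozygous, for different alleles
#'     (2:2 allele copies in a tetraploid; expected read share 50/50).}
#'   \item{HET_ONE_HEF / HET_ONE_HFL}{exactly one donor heterozygous, the
#'     other homozygous for one of its alleles (3:1 copies; expected 75/25).}
#'   \item{HET_BOTH}{both donors heterozygous — not discriminating.}
#'   \item{IDENTICAL}{donors share the genotype (differs from the reference
#'     base so it is still a SNP) — not discriminating.}
#' }
#'
#' @param n_genes Number of genes; one transcript is generated per gene.
#' @param transcript_length Transcript length in nucleotides.
#' @param n_snps Named integer vector of site counts per category; names from
#'   `HOM_HOM_DIFF`, `HET_ONE_HEF`, `HET_ONE_HFL`, `HET_BOTH`, `IDENTICAL`.
#' @param read_length Read length in nucleotides (default 36).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param coverage Mean reads per expressed transcript copy (Poisson mean at
#'   baseline expression).
#' @param ploidy `"tetraploid"` (2+2 copies) or `"octaploid"` (4+4).
#' @param expression_skew Relative expression multiplier applied to
#'   HEF-genome copies (hFL copies are the unit); 1 means balanced.
#' @param fold_changes Data frame with columns `gene` and `log2fc` naming
#'   designated differentially expressed genes (positive = up in hFL), or
#'   `NULL` for none.
#' @param anchor_contamination_rate Fraction of reads carrying a residual
#'   UP1/UP2 anchor + poly-T prefix.
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A list of class `hyb_config`.
#' @seealso [simulate_donor_genomes()], [simulate_hybrid_reads()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 6, n_snps = c(HOM_HOM_DIFF = 3, HET_ONE_HEF = 3))
sim_config <- function(n_genes = 20,
                       transcript_length = 300,
                       n_snps = c(HOM_HOM_DIFF = 5, HET_ONE_HEF = 5,
                                  HET_ONE_HFL = 5, HET_BOTH = 2, IDENTICAL = 2),
                       read_length = 36,
                       error_rate = 0.01,
                       coverage = 20,
                       ploidy = c("tetraploid", "octaploid"),
                       expression_skew = 1,
                       fold_changes = NULL,
                       anchor_contamination_rate = 0,
                       seed = 1L) {
  ploidy <- match.arg(ploidy)
  valid <- c("HOM_HOM_DIFF", "HET_ONE_HEF", "HET_ONE_HFL", "HET_BOTH", "IDENTICAL")
  full <- setNames(integer(length(valid)), valid)
  if (length(n_snps)) {
    if (is.null(names(n_snps)) || !all(names(n_snps) %in% valid)) {
      abort(paste("n_snps names must be among:", paste(valid, collapse = ", ")))
    }
    full[names(n_snps)] <- as.integer(n_snps)
  }
  if (any(full < 0)) abort("SNP category counts must be non-negative.")
  if (error_rate < 0 || error_rate >= 1) abort("error_rate must be in [0, 1).")
  if (anchor_contamination_rate < 0 || anchor_contamination_rate >= 1) {
    abort("anchor_contamination_rate must be in [0, 1).")
  }
  if (read_length > transcript_length) {
    abort("read_length must not exceed transcript_length.")
  }
  if (coverage <= 0) abort("coverage must be positive.")
  if (expression_skew < 0) abort("expression_skew must be non-negative.")
  if (!is.null(fold_changes)) {
    fold_changes <- as_tibble(fold_changes)
    if (!all(c("gene", "log2fc") %in% names(fold_changes))) {
      abort("fold_changes needs columns 'gene' and 'log2fc'.")
    }
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      transcript_length = as.integer(transcript_length),
      n_snps = full,
      read_length = as.integer(read_length),
      error_rate = error_rate,
      coverage = coverage,
      ploidy = ploidy,
      expression_skew = expression_skew,
      fold_changes = fold_changes,
      anchor_contamination_rate = anchor_contamination_rate,
      seed = as.integer(seed)
    ),
    class = "hyb_config"
  )
}

#' @export
print.hyb_config <- function(x, ...) {
  cat("<hyb_config> ", x$n_genes, " genes x ", x$transcript_length, " nt, ",
      x$ploidy, " hybrid\n", sep = "")
  cat("  SNP sites:", paste(names(x$n_snps), x$n_snps, sep = "=", collapse = " "), "\n")
  cat("  reads: ", x$read_length, " nt, error ", x$error_rate,
      ", coverage ", x$coverage, "/copy, skew ", x$expression_skew,
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate two donor genomes over a shared transcript reference
#'
#' Creates a random transcript per gene, then plants SNP sites realizing
#' exactly the category counts requested in the configuration. At every
#' non-SNP position all four (or eight) hybrid haplotype copies are identical
#' to the reference. Positions are reported 1-based in transcript
#' coordinates; the transcript identifier doubles as the chromosome label.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `hyb_genomes` with elements
#'   \describe{
#'     \item{reference}{tibble: `transcript`, `gene`, `length`, `sequence`.}
#'     \item{genotypes}{tibble: `chrom`, `pos`, `gene`, `ref`, `hef`, `hfl`,
#'       `category`, `het_donor` — the donor genotype table. Genotypes are
#'       two-letter unordered pairs (alphabetical), e.g. `"CG"`.}
#'   }
#' @export
simulate_donor_genomes <- function(config) {
  stopifnot(inherits(config, "hyb_config"))
  set.seed(stage_seed(config$seed, "genomes"))

  genes <- sprintf("GENE%03d", seq_len(config$n_genes))
  L <- config$transcript_length
  sequences <- vapply(
    genes,
    function(g) paste(sample(BASES, L, replace = TRUE), collapse = ""),
    character(1)
  )
  reference <- tibble(
    transcript = genes, gene = genes, length = L, sequence = unname(sequences)
  )

  n_sites <- sum(config$n_snps)
  # keep sites away from transcript ends so every site can be fully covered,
  # and at least one read length apart so no read spans two SNPs (each read
  # carries at most one discriminating site)
  rl <- config$read_length
  lo <- min(rl, max(1L, L %/% 4L))
  hi <- max(lo, L - rl + 1L)
  per_gene <- max(1L, (hi - lo) %/% rl + 1L)
  if (n_sites > config$n_genes * per_gene) {
    abort(sprintf(
      "requested %d SNP sites but only %d placeable positions exist (%d per gene at >= read_length spacing); increase n_genes or transcript_length.",
      n_sites, config$n_genes * per_gene, per_gene
    ))
  }
  if (n_sites == 0) {
    gt <- tibble(
      chrom = character(), pos = integer(), gene = character(),
      ref = character(), hef = character(), hfl = character(),
      category = character(), het_donor = character()
    )
    return(structure(list(reference = reference, genotypes = gt, config = config),
                     class = "hyb_genomes"))
  }
  # spread sites across genes round-robin (random gene order), then draw
  # spaced positions within each gene's placeable window
  gene_order <- sample(genes)
  site_gene <- rep(gene_order, length.out = n_sites)
  picked_pos <- integer(n_sites)
  for (g in unique(site_gene)) {
    idx <- which(site_gene == g)
    m <- length(idx)
    # jittered grid of m positions with pairwise distance >= read_length
    slack <- (hi - lo) - (m - 1L) * rl
    offs <- sort(sample.int(slack + 1L, m, replace = TRUE)) - 1L
    picked_pos[idx] <- lo + offs + (seq_len(m) - 1L) * rl
  }
  picked <- data.frame(gene = site_gene, pos = picked_pos,
                       stringsAsFactors = FALSE)
  # randomize which category lands where
  sim_cat <- sample(rep(names(config$n_snps), times = config$n_snps))

  ref_base <- substr(sequences[picked$gene], picked$pos, picked$pos)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1), character(1))
  pair <- function(a, b) {
    paste0(pmin(a, b), pmax(a, b))
  }
  hom <- function(a) paste0(a, a)

  # orient alleles randomly so both ref-carrying and ref-free donors occur
  flip <- runif(n_sites) < 0.5
  a1 <- ifelse(flip, ref_base, alt_base)   # allele of donor side one
  a2 <- ifelse(flip, alt_base, ref_base)

  hef <- character(n_sites)
  hfl <- character(n_sites)
  for (i in seq_len(n_sites)) {
    switch(sim_cat[i],
      HOM_HOM_DIFF = {
        hef[i] <- hom(a1[i]); hfl[i] <- hom(a2[i])
      },
      HET_ONE_HEF = {
        hef[i] <- pair(a1[i], a2[i]); hfl[i] <- hom(a1[i])
      },
      HET_ONE_HFL = {
        hef[i] <- hom(a1[i]); hfl[i] <- pair(a1[i], a2[i])
      },
      HET_BOTH = {
        # both heterozygous with distinct genotypes (same-genotype het sites
        # are the IDENTICAL category)
        alt2 <- sample(setdiff(BASES, c(ref_base[i], alt_base[i])), 1)
        hef[i] <- pair(ref_base[i], alt_base[i])
        hfl[i] <- pair(ref_base[i], alt2)
      },
      IDENTICAL = {
        hef[i] <- hom(alt_base[i]); hfl[i] <- hom(alt_base[i])
      }
    )
  }

  cls <- classify_genotypes(hef, hfl)
  gt <- tibble(
    chrom = picked$gene,
    pos = as.integer(picked$pos),
    gene = picked$gene,
    ref = unname(ref_base),
    hef = hef,
    hfl = hfl,
    category = cls$category,
    het_donor = cls$het_donor
  ) %>%
    arrange(.data$chrom, .data$pos)

  structure(list(reference = reference, genotypes = gt, config = config),
            class = "hyb_genomes")
}

#' @export
print.hyb_genomes <- function(x, ...) {
  cat("<hyb_genomes> ", nrow(x$reference), " transcripts, ",
      nrow(x$genotypes), " SNP sites\n", sep = "")
  print(count(x$genotypes, .data$category, .data$het_donor))
  invisible(x)
}

#' Build the individual haplotype copies carried by the hybrid
#'
#' Expands the donor genotype table into per-copy transcript sequences:
#' 2 HEF + 2 hFL copies for a tetraploid hybrid, 4 + 4 for an octaploid. For
#' a heterozygous donor the two (or two pairs of) copies carry the two
#' alleles deterministically in alphabetical order.
#'
#' @param genomes A `hyb_genomes` object.
#' @return Tibble with `copy_id`, `donor`, `copy_index`, `transcript`,
#'   `sequence`.
#' @export
donor_haplotypes <- function(genomes) {
  stopifnot(inherits(genomes, "hyb_genomes"))
  n_per <- if (genomes$config$ploidy == "octaploid") 4L else 2L
  copies <- tibble(
    donor = rep(c("HEF", "hFL"), each = n_per),
    copy_index = rep(seq_len(n_per), times = 2)
  ) %>%
    mutate(copy_id = paste0(.data$donor, "_", .data$copy_index))

  gt <- genomes$genotypes
  out <- tidyr::crossing(copies, genomes$reference["transcript"]) %>%
    left_join(genomes$reference[c("transcript", "sequence")], by = "transcript")

  if (nrow(gt)) {
    seqs <- out$sequence
    for (i in seq_len(nrow(gt))) {
      rows <- which(out$transcript == gt$chrom[i])
      for (r in rows) {
        g <- if (out$donor[r] == "HEF") gt$hef[i] else gt$hfl[i]
        # copies 1..n_per alternate over the (sorted) genotype alleles
        allele <- substr(g, ((out$copy_index[r] - 1L) %% 2L) + 1L,
                         ((out$copy_index[r] - 1L) %% 2L) + 1L)
        substr(seqs[r], gt$pos[i], gt$pos[i]) <- allele
      }
    }
    out$sequence <- seqs
  }
  out[c("copy_id", "donor", "copy_index", "transcript", "sequence")]
}

#' Generate per-cell-type expression profiles
#'
#' Draws a shared log-normal baseline per gene and applies the designated
#' log2 fold changes symmetrically, so that a gene with `log2fc = f` has
#' hFL/HEF expression ratio `2^f` (positive = over-expressed in hFL).
#' Undesignated genes receive only mild replicate noise, so an at-least
#' 4-fold differential-expression filter returns exactly the designated set.
#'
#' @param genomes A `hyb_genomes` object.
#' @param config A [sim_config()]; defaults to the one inside `genomes`.
#' @return Tibble with `gene`, `hef`, `hfl` (linear expression units) and
#'   `log2fc = log2(hfl/hef)`.
#' @export
simulate_expression <- function(genomes, config = genomes$config) {
  stopifnot(inherits(genomes, "hyb_genomes"))
  set.seed(stage_seed(config$seed, "expression"))
  genes <- genomes$reference$gene
  base <- rlnorm(length(genes), meanlog = log(100), sdlog = 0.5)
  # replicate noise well below the 4-fold detection threshold
  noise <- function(n) 2^rnorm(n, mean = 0, sd = 0.25)
  hef <- base * noise(length(genes))
  hfl <- base * noise(length(genes))
  if (!is.null(config$fold_changes) && nrow(config$fold_changes)) {
    fc <- config$fold_changes
    missing <- setdiff(fc$gene, genes)
    if (length(missing)) {
      abort(paste("fold_changes genes absent from reference:",
                  paste(missing, collapse = ", ")))
    }
    idx <- match(fc$gene, genes)
    hef[idx] <- base[idx] * 2^(-fc$log2fc / 2)
    hfl[idx] <- base[idx] * 2^(fc$log2fc / 2)
  }
  if (any(hef < 0) || any(hfl < 0)) abort("expression levels must be non-negative.")
  tibble(gene = genes, hef = hef, hfl = hfl,
         log2fc = log2(hfl / hef))
}

#' Simulate short reads from the hybrid transcriptome
#'
#' Draws single-end reads copy-proportionally from the hybrid's haplotype
#' copies. Under the `"reprogrammed"` scenario every copy expresses at the
#' hFL-like level (the hybrid follows the erythroid program), HEF copies
#' additionally scaled by `expression_skew`; under `"silent_cargo"` the HEF
#' copies are further multiplied by `silencing_factor` (0 = fully silent,
#' 1 = indistinguishable from reprogrammed). Each base is substituted with a
#' uniformly chosen different base with probability `error_rate`; a fraction
#' of reads is replaced by anchor-primer contamination (UP1/UP2 + poly-T).
#'
#' @param genomes A `hyb_genomes` object.
#' @param expression Output of [simulate_expression()]; `NULL` for a flat
#'   profile.
#' @param config A [sim_config()]; defaults to the one inside `genomes`.
#' @param scenario `"reprogrammed"` or `"silent_cargo"`.
#' @param silencing_factor Expression multiplier for HEF copies under
#'   `"silent_cargo"` (default 0).
#' @return A list of class `hyb_readset`:
#'   \describe{
#'     \item{reads}{tibble `read_id`, `sequence`, `quality`.}
#'     \item{truth}{tibble `read_id`, `origin_donor`, `origin_transcript`,
#'       `origin_copy`, `origin_offset` (0-based), `strand`, `contaminated`.}
#'   }
#' @export
simulate_hybrid_reads <- function(genomes, expression = NULL,
                                  config = genomes$config,
                                  scenario = c("reprogrammed", "silent_cargo"),
                                  silencing_factor = 0) {
  stopifnot(inherits(genomes, "hyb_genomes"))
  scenario <- match.arg(scenario)
  if (config$coverage <= 0) abort("coverage must be positive.")
  if (silencing_factor < 0) abort("silencing_factor must be non-negative.")
  set.seed(stage_seed(config$seed, "reads"))

  haps <- donor_haplotypes(genomes)
  rl <- config$read_length

  if (is.null(expression)) {
    w <- setNames(rep(1, nrow(genomes$reference)), genomes$reference$gene)
  } else {
    w <- setNames(expression$hfl / mean(expression$hfl), expression$gene)
  }
  hef_mult <- config$expression_skew *
    if (scenario == "silent_cargo") silencing_factor else 1

  haps <- haps %>%
    mutate(
      gene = .data$transcript,
      lambda = config$coverage * unname(w[.data$gene]) *
        ifelse(.data$donor == "HEF", hef_mult, 1),
      n_reads = rpois(n(), .data$lambda)
    )

  total <- sum(haps$n_reads)
  if (total == 0) {
    reads <- tibble(read_id = character(), sequence = character(),
                    quality = character())
    truth <- tibble(read_id = character(), origin_donor = character(),
                    origin_transcript = character(), origin_copy = integer(),
                    origin_offset = integer(), strand = character(),
                    contaminated = logical())
    return(structure(list(reads = reads, truth = truth, config = config,
                          scenario = scenario),
                     class = "hyb_readset"))
  }

  src <- rep(seq_len(nrow(haps)), haps$n_reads)
  tlen <- nchar(haps$sequence[src])
  offset0 <- floor(runif(total) * (tlen - rl + 1))  # 0-based start
  seqs <- substr(haps$sequence[src], offset0 + 1, offset0 + rl)
  strand <- ifelse(runif(total) < 0.5, "+", "-")
  seqs[strand == "-"] <- reverse_complement(seqs[strand == "-"])

  # substitution errors
  if (config$error_rate > 0) {
    set.seed(stage_seed(config$seed, "errors"))
    n_err <- rbinom(total, rl, config$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(rl, n_err[i])
      for (p in pos) {
        old <- substr(seqs[i], p, p)
        substr(seqs[i], p, p) <- sample(setdiff(BASES, old), 1)
      }
    }
  }

  contaminated <- rep(FALSE, total)
  if (config$anchor_contamination_rate > 0) {
    set.seed(stage_seed(config$seed, "anchors"))
    contaminated <- runif(total) < config$anchor_contamination_rate
    if (any(contaminated)) {
      spec <- anchor_specs()
      which_anchor <- sample(nrow(spec), sum(contaminated), replace = TRUE)
      seqs[contaminated] <- substr(
        paste0(spec$sequence[which_anchor], seqs[contaminated]), 1, rl
      )
    }
  }

  ids <- sprintf("r%06d", seq_len(total))
  reads <- tibble(
    read_id = ids,
    sequence = seqs,
    quality = strrep("I", rl)
  )
  truth <- tibble(
    read_id = ids,
    origin_donor = haps$donor[src],
    origin_transcript = haps$transcript[src],
    origin_copy = haps$copy_index[src],
    origin_offset = as.integer(offset0),
    strand = strand,
    contaminated = contaminated
  )
  structure(list(reads = reads, truth = truth, config = config,
                 scenario = scenario),
            class = "hyb_readset")
}

#' @export
print.hyb_readset <- function(x, ...) {
  cat("<hyb_readset> ", nrow(x$reads), " reads (", x$scenario, " scenario)\n",
      sep = "")
  print(count(x$truth, .data$origin_donor))
  invisible(x)
}
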