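test_that("donor genomes realize exactly the requested category counts", {
  cfg <- sim_config(
    n_genes = 12, transcript_length = 200,
    n_snps = c(HOM_HOM_DIFF = 4, HET_ONE_HEF = 3, HET_ONE_HFL = 2,
               HET_BOTH = 2, IDENTICAL = 1),
    seed = 5
  )
  g <- simulate_donor_genomes(cfg)
  gt <- g$genotypes
  expect_equal(nrow(gt), 12)
  expect_equal(sum(gt$category == "HOM_HOM_DIFF"), 4)
  expect_equal(sum(gt$category == "HET_ONE" & gt$het_donor == "HEF"), 3)
  expect_equal(sum(gt$category == "HET_ONE" & gt$het_donor == "hFL"), 2)
  expect_equal(sum(gt$category == "HET_BOTH"), 2)
  expect_equal(sum(gt$category == "IDENTICAL"), 1)
  # positions unique per chromosome, 1-based, inside the transcript
  expect_false(any(duplicated(gt[c("chrom", "pos")])))
  expect_true(all(gt$pos >= 1 & gt$pos <= cfg$transcript_length))
  # the reference base at each site is reported correctly
  ref <- setNames(g$reference$sequence, g$reference$transcript)
  expect_equal(unname(substr(ref[gt$chrom], gt$pos, gt$pos)), gt$ref)
})

test_that("all-zero category counts give two identical donors and no SNPs", {
  cfg <- sim_config(n_genes = 4, n_snps = integer(0), seed = 1)
  g <- simulate_donor_genomes(cfg)
  expect_equal(nrow(g$genotypes), 0)
  haps <- donor_haplotypes(g)
  # all four haplotype copies identical to the reference everywhere
  ref <- setNames(g$reference$sequence, g$reference$transcript)
  expect_true(all(haps$sequence == ref[haps$transcript]))
  expect_equal(nrow(build_list_a(g$genotypes)), 0)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 6, n_snps = c(HOM_HOM_DIFF = 3), seed = 99)
  g1 <- simulate_donor_genomes(cfg)
  g2 <- simulate_donor_genomes(cfg)
  expect_identical(g1$genotypes, g2$genotypes)
  expect_identical(g1$reference, g2$reference)
  r1 <- simulate_hybrid_reads(g1, NULL)
  r2 <- simulate_hybrid_reads(g2, NULL)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
  g3 <- simulate_donor_genomes(sim_config(n_genes = 6,
                                          n_snps = c(HOM_HOM_DIFF = 3),
                                          seed = 100))
  expect_false(identical(g1$genotypes$pos, g3$genotypes$pos))
})

test_that("oversized SNP requests raise a sizing error", {
  cfg <- sim_config(n_genes = 2, transcript_length = 80, read_length = 36,
                    n_snps = c(HOM_HOM_DIFF = 50))
  expect_error(simulate_donor_genomes(cfg), "placeable")
})

test_that("expression profiles realize designated fold changes exactly", {
  fc <- tibble::tibble(gene = c("GENE001", "GENE002"),
                       log2fc = c(2.37, -3.82))
  cfg <- sim_config(n_genes = 5, n_snps = integer(0), fold_changes = fc,
                    seed = 3)
  g <- simulate_donor_genomes(cfg)
  e <- simulate_expression(g)
  expect_equal(e$hfl[e$gene == "GENE001"] / e$hef[e$gene == "GENE001"],
               2^2.37, tolerance = 1e-12)
  expect_equal(e$hfl[e$gene == "GENE002"] / e$hef[e$gene == "GENE002"],
               2^-3.82, tolerance = 1e-12)
  expect_true(all(e$hef >= 0 & e$hfl >= 0))
  # undesignated genes never reach the 4-fold threshold
  other <- e[!e$gene %in% fc$gene, ]
  expect_true(all(abs(other$log2fc) < 2))
})

test_that("expression with no designated genes passes no DE filter", {
  cfg <- sim_config(n_genes = 30, n_snps = integer(0), seed = 8)
  e <- simulate_expression(simulate_donor_genomes(cfg))
  expect_equal(nrow(de_filter(e, min_fold_change = 4)), 0)
})

test_that("unknown fold-change genes are rejected", {
  fc <- tibble::tibble(gene = "NOSUCH", log2fc = 2)
  cfg <- sim_config(n_genes = 3, n_snps = integer(0), fold_changes = fc)
  g <- simulate_donor_genomes(cfg)
  expect_error(simulate_expression(g), "absent")
})

test_that("error-free reads are exact substrings of a haplotype copy", {
  cfg <- sim_config(n_genes = 4, n_snps = c(HOM_HOM_DIFF = 2, HET_ONE_HFL = 2),
                    coverage = 10, error_rate = 0, seed = 21)
  g <- simulate_donor_genomes(cfg)
  rs <- simulate_hybrid_reads(g, NULL)
  haps <- donor_haplotypes(g)
  key <- paste(haps$donor, haps$copy_index, haps$transcript)
  for (i in seq_len(nrow(rs$reads))) {
    tr <- rs$truth[i, ]
    hap <- haps$sequence[key == paste(tr$origin_donor, tr$origin_copy,
                                      tr$origin_transcript)]
    fragment <- substr(hap, tr$origin_offset + 1,
                       tr$origin_offset + cfg$read_length)
    seq <- rs$reads$sequence[i]
    if (tr$strand == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    expect_identical(seq, fragment)
  }
})

test_that("truth table covers every read exactly once", {
  cfg <- sim_config(n_genes = 5, n_snps = c(HOM_HOM_DIFF = 3), coverage = 15,
                    seed = 77, anchor_contamination_rate = 0.1)
  rs <- simulate_hybrid_reads(simulate_donor_genomes(cfg), NULL)
  expect_setequal(rs$reads$read_id, rs$truth$read_id)
  expect_false(any(duplicated(rs$truth$read_id)))
  expect_equal(sum(table(rs$truth$origin_donor)), nrow(rs$reads))
})

test_that("read sampling is copy-proportional at deep coverage", {
  # with no errors, the shared (3-copy) allele's read share at a one-donor-het
  # site converges to 3/4; checked with a 99.9% binomial CI on pooled reads
  cfg <- sim_config(n_genes = 5, transcript_length = 150,
                    n_snps = c(HET_ONE_HFL = 5), coverage = 600,
                    error_rate = 0, seed = 13)
  g <- simulate_donor_genomes(cfg)
  rs <- simulate_hybrid_reads(g, NULL)
  expect_gt(nrow(rs$reads), 1e4)
  haps <- donor_haplotypes(g)
  gt <- g$genotypes
  shared_n <- 0L; total_n <- 0L
  for (i in seq_len(nrow(gt))) {
    cover <- rs$truth$origin_transcript == gt$chrom[i] &
      rs$truth$origin_offset < gt$pos[i] &
      rs$truth$origin_offset + cfg$read_length >= gt$pos[i]
    cov <- rs$truth[cover, ]
    hap_allele <- vapply(seq_len(nrow(cov)), function(j) {
      hap <- haps$sequence[haps$donor == cov$origin_donor[j] &
                             haps$copy_index == cov$origin_copy[j] &
                             haps$transcript == cov$origin_transcript[j]]
      substr(hap, gt$pos[i], gt$pos[i])
    }, character(1))
    cls <- classify_genotypes(gt$hef[i], gt$hfl[i])
    shared_n <- shared_n + sum(hap_allele == cls$shared_allele)
    total_n <- total_n + length(hap_allele)
  }
  ci <- stats::binom.test(shared_n, total_n, 0.75,
                          conf.level = 0.999)$conf.int
  expect_true(ci[1] <= 0.75 && 0.75 <= ci[2])
})

test_that("octaploid hybrids keep the same expected allele ratios", {
  cfg <- sim_config(n_genes = 20, transcript_length = 150,
                    n_snps = c(HET_ONE_HEF = 20), coverage = 40,
                    error_rate = 0, ploidy = "octaploid", seed = 31)
  g <- simulate_donor_genomes(cfg)
  haps <- donor_haplotypes(g)
  expect_equal(nrow(haps), 8 * 20)  # 4 + 4 copies per transcript
  rs <- simulate_hybrid_reads(g, NULL)
  aln <- align_reads(rs$reads, g$reference)
  pu <- pileup_counts(aln)
  rec <- attribute_reads(g$genotypes, pu, mode = "allele_ratio")
  ci <- stats::binom.test(sum(rec$n_major), sum(rec$n_informative), 0.75,
                          conf.level = 0.999)$conf.int
  expect_true(ci[1] <= 0.75 && 0.75 <= ci[2])
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(error_rate = 1.2), "error_rate")
  expect_error(sim_config(read_length = 500, transcript_length = 100),
               "read_length")
  expect_error(sim_config(coverage = 0), "coverage")
  expect_error(sim_config(n_snps = c(BOGUS = 2)), "n_snps")
  cfg <- sim_config(n_genes = 2, n_snps = integer(0))
  g <- simulate_donor_genomes(cfg)
  expect_error(simulate_hybrid_reads(g, NULL, silencing_factor = -1),
               "silencing_factor")
})
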