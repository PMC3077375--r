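test_that("error-free simulated reads align uniquely at their true offsets", {
  cfg <- sim_config(n_genes = 6, n_snps = c(HOM_HOM_DIFF = 3, HET_ONE_HEF = 3),
                    coverage = 12, error_rate = 0, seed = 17)
  g <- simulate_donor_genomes(cfg)
  rs <- simulate_hybrid_reads(g, NULL)
  aln <- align_reads(rs$reads, g$reference)
  expect_equal(nrow(aln), nrow(rs$reads))
  expect_equal(attr(aln, "n_multi"), 0L)
  expect_equal(attr(aln, "n_unaligned"), 0L)
  chk <- dplyr::inner_join(aln, rs$truth, by = "read_id")
  expect_equal(chk$offset, chk$origin_offset)
  expect_equal(chk$transcript, chk$origin_transcript)
  # alignment soundness: recount mismatches post hoc
  ref <- setNames(g$reference$sequence, g$reference$transcript)
  window <- substr(ref[aln$transcript], aln$offset + 1,
                   aln$offset + nchar(aln$aligned_sequence))
  recount <- mapply(function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
                    aln$aligned_sequence, window)
  expect_equal(unname(recount), aln$mismatches)
  expect_true(all(aln$mismatches <= 2))
})

test_that("reads matching two reference entries equally are discarded", {
  set.seed(2)
  seq <- random_dna(1, 120)
  ref <- tibble::tibble(transcript = c("T1", "T1copy"), sequence = c(seq, seq))
  reads <- tibble::tibble(read_id = "r1", sequence = substr(seq, 10, 45))
  aln <- align_reads(reads, ref)
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "n_multi"), 1L)
})

test_that("reads beyond the mismatch bound stay unaligned", {
  set.seed(3)
  ref <- tibble::tibble(transcript = "T1", sequence = random_dna(1, 120))
  r <- substr(ref$sequence, 20, 55)
  for (p in c(3, 15, 27)) {  # one mismatch in each seed block
    substr(r, p, p) <- setdiff(c("A", "C", "G", "T"), substr(r, p, p))[1]
  }
  aln <- align_reads(tibble::tibble(read_id = "r1", sequence = r), ref,
                     max_mismatches = 2)
  expect_equal(nrow(aln), 0)
  expect_equal(attr(aln, "n_unaligned"), 1L)
})

test_that("reverse-complement reads align to the forward reference", {
  set.seed(4)
  ref <- tibble::tibble(transcript = "T1", sequence = random_dna(1, 100))
  fwd <- substr(ref$sequence, 31, 66)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  aln <- align_reads(tibble::tibble(read_id = "rc", sequence = rc), ref)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$offset, 30L)
  expect_equal(aln$strand, "-")
  expect_identical(aln$aligned_sequence, fwd)
})

test_that("pileups tally aligned bases site by site", {
  set.seed(6)
  ref <- tibble::tibble(transcript = "T1", sequence = random_dna(1, 60))
  reads <- tibble::tibble(
    read_id = c("a", "b"),
    sequence = c(substr(ref$sequence, 1, 16), substr(ref$sequence, 9, 24))
  )
  pu <- pileup_counts(align_reads(reads, ref, seed_length = 8))
  expect_equal(nrow(pu), 24)
  expect_true(all(pu$depth[pu$pos <= 8] == 1))
  expect_true(all(pu$depth[pu$pos >= 9 & pu$pos <= 16] == 2))
  expect_true(all(pu$depth[pu$pos >= 17] == 1))
  b10 <- substr(ref$sequence, 10, 10)
  expect_equal(pu[[b10]][pu$pos == 10], 2)
  expect_equal(pu$depth, pu$A + pu$C + pu$G + pu$T)
})

test_that("pileup counts at SNP sites match the simulation truth when error-free", {
  cfg <- sim_config(n_genes = 5, transcript_length = 150,
                    n_snps = c(HOM_HOM_DIFF = 5), coverage = 30,
                    error_rate = 0, seed = 23)
  g <- simulate_donor_genomes(cfg)
  rs <- simulate_hybrid_reads(g, NULL)
  aln <- align_reads(rs$reads, g$reference)
  pu <- pileup_counts(aln)
  gt <- g$genotypes
  cls <- classify_genotypes(gt$hef, gt$hfl)
  for (i in seq_len(nrow(gt))) {
    row <- pu[pu$chrom == gt$chrom[i] & pu$pos == gt$pos[i], ]
    cover <- rs$truth$origin_transcript == gt$chrom[i] &
      rs$truth$origin_offset < gt$pos[i] &
      rs$truth$origin_offset + cfg$read_length >= gt$pos[i]
    by_donor <- table(factor(rs$truth$origin_donor[cover],
                             levels = c("HEF", "hFL")))
    expect_equal(row[[cls$hef_allele[i]]], unname(by_donor["HEF"]))
    expect_equal(row[[cls$hfl_allele[i]]], unname(by_donor["hFL"]))
  }
})

test_that("consensus calls reproduce the worked-example frequency rows", {
  pu <- tibble::tibble(
    chrom = c("1", "1"), pos = c(25589895L, 156947511L),
    A = c(0L, 0L), C = c(53L, 12L), G = c(28L, 0L), T = c(1L, 33L)
  )
  cons <- call_consensus(pu)
  r1 <- cons[cons$pos == 25589895, ]
  expect_equal(r1$first_base, "C")
  expect_equal(r1$first_freq, "53\\82")
  expect_equal(r1$second_base, "G")
  expect_equal(r1$second_freq, "28\\82")
  expect_equal(consensus_alleles(r1$consensus), "CG")
  r2 <- cons[cons$pos == 156947511, ]
  expect_equal(r2$first_freq, "33\\45")
  expect_equal(r2$second_freq, "12\\45")
  expect_equal(consensus_alleles(r2$consensus), "CT")
})

test_that("count ties break alphabetically and heterozygote thresholds apply", {
  pu <- tibble::tibble(chrom = "t", pos = 1:3,
                       A = c(5L, 9L, 8L), C = c(0L, 1L, 2L),
                       G = c(5L, 0L, 0L), T = c(0L, 0L, 0L))
  cons <- call_consensus(pu)
  expect_equal(cons$first_base, c("A", "A", "A"))
  expect_equal(cons$consensus[1], "A/G")  # tie -> A first
  expect_equal(cons$zygosity, c("het", "hom", "het"))
})

test_that("caller matches an exhaustive oracle on every pileup of depth <= 6", {
  # independent oracle: plodding loops over base orderings and the literal
  # het rule, evaluated on all 4^d base sequences tabulated to count tables
  oracle_call <- function(counts) {
    bases <- c("A", "C", "G", "T")
    best <- ""; best_n <- -1
    for (b in bases) {
      if (counts[[b]] > best_n) { best <- b; best_n <- counts[[b]] }
    }
    second <- ""; second_n <- -1
    for (b in bases) {
      if (b == best) next
      if (counts[[b]] > second_n) { second <- b; second_n <- counts[[b]] }
    }
    depth <- sum(unlist(counts))
    if (second_n >= max(2, 0.2 * depth)) {
      list(first = best, consensus = sort(c(best, second)))
    } else {
      list(first = best, consensus = c(best, best))
    }
  }
  tables <- list()
  for (d in 1:6) {
    for (a in 0:d) for (c in 0:(d - a)) for (g in 0:(d - a - c)) {
      tables[[length(tables) + 1]] <-
        list(A = a, C = c, G = g, T = d - a - c - g)
    }
  }
  pu <- tibble::tibble(
    chrom = "x", pos = seq_along(tables),
    A = vapply(tables, function(t) t$A, integer(1)),
    C = vapply(tables, function(t) t$C, integer(1)),
    G = vapply(tables, function(t) t$G, integer(1)),
    T = vapply(tables, function(t) t$T, integer(1))
  )
  cons <- call_consensus(pu)
  for (i in seq_along(tables)) {
    exp <- oracle_call(tables[[i]])
    expect_identical(cons$first_base[i], exp$first)
    expect_identical(consensus_alleles(cons$consensus[i]),
                     paste(exp$consensus, collapse = ""))
  }
})

test_that("deep error-free consensus recovers the union of haplotype alleles", {
  cfg <- sim_config(n_genes = 6, transcript_length = 150,
                    n_snps = c(HOM_HOM_DIFF = 3, HET_ONE_HFL = 3),
                    coverage = 60, error_rate = 0, seed = 29)
  g <- simulate_donor_genomes(cfg)
  rs <- simulate_hybrid_reads(g, NULL)
  cons <- call_consensus(pileup_counts(align_reads(rs$reads, g$reference)))
  gt <- g$genotypes
  pu <- pileup_counts(align_reads(rs$reads, g$reference))
  joined <- dplyr::inner_join(gt, cons, by = c("chrom", "pos")) |>
    dplyr::inner_join(pu, by = c("chrom", "pos"))
  expect_equal(nrow(joined), nrow(gt))
  for (i in seq_len(nrow(joined))) {
    present <- sort(unique(c(
      strsplit(joined$hef[i], "")[[1]], strsplit(joined$hfl[i], "")[[1]]
    )))
    # alleles whose observed support clears the heterozygote threshold;
    # a minor allele can dip below it by sampling, in which case the call
    # is legitimately homozygous for the major allele
    obs <- unlist(joined[i, c("A", "C", "G", "T")])
    thr <- max(2, 0.2 * sum(obs))
    supported <- sort(names(obs)[obs >= thr])
    called <- sort(unique(strsplit(consensus_alleles(joined$consensus[i]),
                                   "")[[1]]))
    expect_identical(called, supported)
    expect_true(all(called %in% present))  # error-free: nothing spurious
  }
})
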