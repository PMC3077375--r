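#' Align reads to a transcript reference (unique, ungapped)
#'
#' A seed-and-extend short-read aligner for transcript references: exact
#' k-mer seeds anchor candidate locations, full-length ungapped verification
#' bounds the mismatch count, and both strands are searched. A read is
#' reported only when exactly one reference location matches within
#' `max_mismatches`; ambiguous (multi-hit) and unaligned reads are discarded
#' and counted. With `seed_length` 12 and 36-nt reads the three disjoint
#' seeds guarantee, by pigeonhole, that every location with at most two
#' mismatches is found.
#'
#' @param reads Tibble with `read_id` and `sequence`, or a `hyb_readset`.
#' @param reference Tibble with `transcript` and `sequence` columns (as in
#'   `hyb_genomes$reference`), or a named character vector of sequences.
#' @param max_mismatches Maximum mismatches for a reported alignment
#'   (default 2).
#' @param seed_length Exact-seed length k (default 12).
#' @return Tibble of class `hyb_alignments`: `read_id`, `transcript`,
#'   `offset` (0-based), `strand`, `mismatches`, and `aligned_sequence` (the
#'   read in reference orientation). Attributes `n_unaligned` and `n_multi`
#'   count discarded reads.
#' @export
align_reads <- function(reads, reference, max_mismatches = 2, seed_length = 12) {
  if (inherits(reads, "hyb_readset")) reads <- reads$reads
  reads <- as_tibble(reads)
  ref <- as_reference_vector(reference)
  if (length(ref) == 0 || all(nchar(ref) == 0)) abort("empty reference.")

  empty <- tibble(
    read_id = character(), transcript = character(), offset = integer(),
    strand = character(), mismatches = integer(), aligned_sequence = character()
  )
  if (nrow(reads) == 0) {
    return(structure(empty, n_unaligned = 0L, n_multi = 0L,
                     class = c("hyb_alignments", class(empty))))
  }

  k <- as.integer(seed_length)
  tlen <- nchar(ref)
  index <- purrr::map_dfr(seq_along(ref), function(i) {
    n <- tlen[i] - k + 1L
    if (n < 1L) return(NULL)
    tibble(kmer = substring(ref[i], 1:n, k:tlen[i]),
           transcript = names(ref)[i],
           kpos = 1:n)
  })

  # queries: each read in both orientations, reported in ref orientation
  queries <- bind_rows(
    tibble(read_id = reads$read_id, qseq = reads$sequence, strand = "+"),
    tibble(read_id = reads$read_id, qseq = reverse_complement(reads$sequence),
           strand = "-")
  ) %>%
    mutate(qidx = row_number(), qlen = nchar(.data$qseq)) %>%
    filter(.data$qlen >= k)

  hits <- NULL
  if (nrow(queries) > 0 && nrow(index) > 0) {
    # one seed table per unique read length keeps substring() calls vectorized
    seeds <- purrr::map_dfr(unique(queries$qlen), function(L) {
      offs <- unique(c(seq(0L, L - k, by = k), L - k))
      q <- queries[queries$qlen == L, ]
      purrr::map_dfr(offs, function(o) {
        tibble(qidx = q$qidx,
               offset_in_read = o,
               kmer = substr(q$qseq, o + 1L, o + k))
      })
    })
    cand <- inner_join(seeds, index, by = "kmer",
                       relationship = "many-to-many") %>%
      mutate(start = .data$kpos - .data$offset_in_read) %>%
      distinct(.data$qidx, .data$transcript, .data$start)
    cand <- cand %>%
      left_join(queries[c("qidx", "qlen")], by = "qidx") %>%
      filter(.data$start >= 1L,
             .data$start + .data$qlen - 1L <= tlen[.data$transcript])
    if (nrow(cand) > 0) {
      window <- substr(ref[cand$transcript], cand$start,
                       cand$start + cand$qlen - 1L)
      mm <- hamming_pairs(queries$qseq[match(cand$qidx, queries$qidx)], window)
      hits <- cand[mm <= max_mismatches, ]
      hits$mismatches <- mm[mm <= max_mismatches]
    }
  }

  if (is.null(hits) || nrow(hits) == 0) {
    out <- empty
    return(structure(out, n_unaligned = nrow(reads), n_multi = 0L,
                     class = c("hyb_alignments", class(out))))
  }

  hits <- hits %>%
    left_join(queries[c("qidx", "read_id", "qseq", "strand")], by = "qidx")
  n_locs <- hits %>%
    distinct(.data$read_id, .data$transcript, .data$start, .data$strand) %>%
    count(.data$read_id, name = "n_loc")
  uniq_ids <- n_locs$read_id[n_locs$n_loc == 1L]
  n_multi <- sum(n_locs$n_loc > 1L)
  n_unaligned <- nrow(reads) - nrow(n_locs)

  out <- hits %>%
    filter(.data$read_id %in% uniq_ids) %>%
    distinct(.data$read_id, .keep_all = TRUE) %>%
    mutate(offset = .data$start - 1L) %>%
    select("read_id", "transcript", "offset", "strand",
           "mismatches", aligned_sequence = "qseq") %>%
    arrange(.data$transcript, .data$offset, .data$read_id)

  structure(out, n_unaligned = n_unaligned, n_multi = as.integer(n_multi),
            class = c("hyb_alignments", class(out)))
}

as_reference_vector <- function(reference) {
  if (inherits(reference, "hyb_genomes")) reference <- reference$reference
  if (is.data.frame(reference)) {
    stopifnot(all(c("transcript", "sequence") %in% names(reference)))
    setNames(reference$sequence, reference$transcript)
  } else if (is.character(reference)) {
    if (is.null(names(reference))) abort("character reference must be named.")
    reference
  } else {
    abort("reference must be a data frame with transcript/sequence or a named character vector.")
  }
}

#' Per-site base counts from unique alignments
#'
#' Tallies, for every covered reference site, the bases of the uniquely
#' aligned reads (in reference orientation). `N` bases are excluded from
#' counts and depth.
#'
#' @param alignments Output of [align_reads()].
#' @param reads Unused when alignments carry `aligned_sequence` (the
#'   default); otherwise a tibble with `read_id`, `sequence`.
#' @param reference Reference, used only to label positions; optional.
#' @return Tibble with `chrom`, `pos` (1-based), `A`, `C`, `G`, `T`, `depth`.
#' @export
pileup_counts <- function(alignments, reads = NULL, reference = NULL) {
  aln <- as_tibble(alignments)
  if (!"aligned_sequence" %in% names(aln)) {
    if (is.null(reads)) abort("alignments lack aligned_sequence; supply reads.")
    if (inherits(reads, "hyb_readset")) reads <- reads$reads
    aln <- aln %>% left_join(
      tibble(read_id = reads$read_id, aligned_sequence = reads$sequence),
      by = "read_id"
    )
  }
  if (nrow(aln) == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  A = integer(), C = integer(), G = integer(), T = integer(),
                  depth = integer()))
  }
  w <- nchar(aln$aligned_sequence)
  obs <- tibble(
    chrom = rep.int(aln$transcript, w),
    pos = rep.int(aln$offset, w) + sequence(w),
    base = unlist(strsplit(aln$aligned_sequence, "", fixed = TRUE),
                  use.names = FALSE)
  ) %>%
    filter(.data$base %in% BASES)
  obs %>%
    count(.data$chrom, .data$pos, .data$base) %>%
    tidyr::pivot_wider(names_from = "base", values_from = "n",
                       values_fill = 0L) %>%
    { for (b in setdiff(BASES, names(.))) .[[b]] <- 0L; . } %>%
    mutate(depth = .data$A + .data$C + .data$G + .data$T) %>%
    select("chrom", "pos", dplyr::all_of(BASES), "depth") %>%
    arrange(.data$chrom, .data$pos)
}

#' Call consensus genotypes from per-site base counts
#'
#' For every site with non-zero depth, reports the first- and second-best
#' bases with their supporting read counts (rendered `"count\\depth"`, the
#' frequency of the base among uniquely aligned reads at the site), and the
#' consensus genotype: heterozygous (a base pair) when the second-best base
#' is supported by at least `max(min_minor_reads, minor_fraction * depth)`
#' reads, otherwise homozygous for the best base. Count ties are broken
#' alphabetically.
#'
#' @param pileup Output of [pileup_counts()].
#' @param min_minor_reads Minimum reads on the minor base to call a
#'   heterozygote (default 2).
#' @param minor_fraction Minimum fraction of depth on the minor base
#'   (default 0.2).
#' @return Tibble with `chrom`, `pos`, `depth`, `first_base`, `first_count`,
#'   `first_freq`, `second_base`, `second_count`, `second_freq`, `consensus`
#'   (e.g. `"C/G"`, best-supported first, or a single base), `zygosity`.
#' @export
call_consensus <- function(pileup, min_minor_reads = 2, minor_fraction = 0.2) {
  pu <- as_tibble(pileup)
  stopifnot(all(c("chrom", "pos", BASES) %in% names(pu)))
  pu <- pu %>% mutate(depth = .data$A + .data$C + .data$G + .data$T) %>%
    filter(.data$depth >= 1)
  if (nrow(pu) == 0) {
    return(tibble(chrom = character(), pos = integer(), depth = integer(),
                  first_base = character(), first_count = integer(),
                  first_freq = character(), second_base = character(),
                  second_count = integer(), second_freq = character(),
                  consensus = character(), zygosity = character()))
  }
  counts <- as.matrix(pu[BASES])
  # stable order: descending count, alphabetical base on ties
  ord1 <- max.col(counts, ties.method = "first")
  first_count <- counts[cbind(seq_len(nrow(counts)), ord1)]
  counts2 <- counts
  counts2[cbind(seq_len(nrow(counts)), ord1)] <- -1L
  ord2 <- max.col(counts2, ties.method = "first")
  second_count <- counts[cbind(seq_len(nrow(counts)), ord2)]

  first_base <- BASES[ord1]
  second_base <- BASES[ord2]
  het <- second_count >= pmax(min_minor_reads, minor_fraction * pu$depth)
  consensus <- ifelse(het, paste0(first_base, "/", second_base), first_base)

  tibble(
    chrom = pu$chrom,
    pos = pu$pos,
    depth = pu$depth,
    first_base = first_base,
    first_count = as.integer(first_count),
    first_freq = paste0(first_count, "\\", pu$depth),
    second_base = ifelse(second_count > 0, second_base, NA_character_),
    second_count = as.integer(second_count),
    second_freq = ifelse(second_count > 0,
                         paste0(second_count, "\\", pu$depth), NA_character_),
    consensus = consensus,
    zygosity = ifelse(het, "het", "hom")
  )
}

#' Parse a consensus genotype into an unordered allele set
#'
#' @param consensus Character vector like `"C/G"` or `"T"`.
#' @return Character vector of alphabetically sorted allele pairs
#'   (homozygous calls are doubled), e.g. `"CG"`, `"TT"` — comparable with
#'   donor genotypes from [classify_genotypes()].
#' @export
consensus_alleles <- function(consensus) {
  parts <- strsplit(consensus, "/", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) == 1) p <- c(p, p)
    paste(sort(p[1:2]), collapse = "")
  }, character(1))
}
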