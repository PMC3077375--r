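#' Build List A: array-genotype-derived discriminating SNPs
#'
#' Applies the ordered filter cascade to a donor genotype table: keep exonic
#' sites, keep discriminating sites (donor genotypes differ and are either
#' both homozygous or heterozygous in exactly one donor; missing genotypes
#' excluded), and — when an expression table and `min_fold_change` are given
#' — keep sites in genes differentially expressed at least that many fold.
#'
#' @param genotypes Tibble with `chrom`, `pos`, `gene`, `hef`, `hfl` (donor
#'   genotype pairs, `"N/A"` for missing).
#' @param exons Optional exon annotation tibble with `chrom`, `start`, `end`
#'   (1-based closed intervals, as from [read_exons_bed()]); `NULL` keeps all
#'   sites.
#' @param expression Optional tibble with `gene` and `log2fc`.
#' @param min_fold_change Linear-scale fold-change threshold for the
#'   differential-expression filter (default 4, i.e. `|log2fc| >= 2`);
#'   `NULL` (or no `expression`) disables the filter.
#' @return Tibble of informative SNPs with `category` (`HOM_HOM_DIFF` or
#'   `HET_ONE`), `het_donor` and discriminating alleles, plus a
#'   `filter_counts` attribute logging row counts per cascade stage.
#' @export
build_list_a <- function(genotypes, exons = NULL, expression = NULL,
                         min_fold_change = 4) {
  gt <- as_tibble(genotypes)
  stopifnot(all(c("chrom", "pos", "gene", "hef", "hfl") %in% names(gt)))
  log <- c(input = nrow(gt))

  if (!is.null(exons)) {
    gt <- filter_exonic(gt, exons)
  }
  log <- c(log, exonic = nrow(gt))

  cls <- classify_genotypes(gt$hef, gt$hfl)
  gt <- bind_cols(gt[setdiff(names(gt), names(cls))], cls) %>%
    filter(.data$category %in% c("HOM_HOM_DIFF", "HET_ONE"))
  log <- c(log, discriminating = nrow(gt))

  if (!is.null(expression) && !is.null(min_fold_change)) {
    expression <- as_tibble(expression)
    stopifnot(all(c("gene", "log2fc") %in% names(expression)))
    missing <- setdiff(unique(gt$gene), expression$gene)
    if (length(missing)) {
      warn(paste("genes without expression values excluded:",
                 paste(missing, collapse = ", ")))
    }
    gt <- gt %>%
      inner_join(expression[c("gene", "log2fc")], by = "gene",
                 relationship = "many-to-one") %>%
      filter(abs(.data$log2fc) >= log2(min_fold_change))
  }
  log <- c(log, final = nrow(gt))
  attr(gt, "filter_counts") <- log
  gt
}

#' Build List B: SNPs called from the hybrid transcriptome
#'
#' Sites whose consensus call differs from the homozygous reference base,
#' optionally restricted to exons. Depth and base frequencies are retained.
#'
#' @param consensus Output of [call_consensus()].
#' @param reference Reference (tibble/named vector/`hyb_genomes`) supplying
#'   the base at each site.
#' @param exons Optional exon annotation (1-based closed intervals).
#' @return Tibble: the consensus rows at variant sites, with a `ref` column.
#' @export
build_list_b <- function(consensus, reference, exons = NULL) {
  cons <- as_tibble(consensus)
  ref <- as_reference_vector(reference)
  bad <- setdiff(unique(cons$chrom), names(ref))
  if (length(bad)) {
    abort(paste("consensus chrom(s) absent from reference:",
                paste(bad, collapse = ", ")))
  }
  cons <- cons %>%
    mutate(ref = unname(substr(ref[.data$chrom], .data$pos, .data$pos))) %>%
    filter(consensus_alleles(.data$consensus) != paste0(.data$ref, .data$ref))
  if (!is.null(exons)) cons <- filter_exonic(cons, exons)
  cons %>% select("chrom", "pos", "ref", dplyr::everything())
}

#' Cross List A with List B
#'
#' Intersects the array-derived discriminating SNPs with the
#' transcriptome-called SNPs on `(chrom, pos)` and applies the robustness
#' filter: sites with read depth of at most `min_read_count` are removed
#' (strictly greater-than rule). The result carries both the donor genotypes
#' and the transcriptome counts.
#'
#' @param list_a Output of [build_list_a()].
#' @param list_b Output of [build_list_b()] (or any tibble with `chrom`,
#'   `pos`, `depth`).
#' @param min_read_count Depth threshold; sites kept only when
#'   `depth > min_read_count` (default 5).
#' @return Tibble of verified SNPs.
#' @export
cross_lists <- function(list_a, list_b, min_read_count = 5) {
  a <- as_tibble(list_a)
  b <- as_tibble(list_b)
  for (x in list(a, b)) {
    if (anyDuplicated(x[c("chrom", "pos")])) {
      abort("duplicate (chrom, pos) keys; coordinate systems inconsistent.")
    }
  }
  stopifnot("depth" %in% names(b))
  b_cols <- unique(c("chrom", "pos", setdiff(names(b), names(a))))
  a %>%
    inner_join(b[b_cols], by = c("chrom", "pos")) %>%
    filter(.data$depth > min_read_count)
}

#' Differential-expression filter with up/down split
#'
#' Retains SNPs whose gene changes at least `min_fold_change`-fold between
#' the two cell types and splits them by direction (positive `log2fc` = up
#' in hFL/hybrid).
#'
#' @param snps Tibble with `gene` and `log2fc` columns (e.g. the Table-1
#'   style fixture from [table1_snps()], or [cross_lists()] output joined
#'   with expression).
#' @param min_fold_change Linear fold-change threshold (default 4).
#' @return The retained rows with a `direction` column (`"up"`/`"down"`);
#'   attribute `de_summary` tabulates SNPs and genes per direction.
#' @export
de_filter <- function(snps, min_fold_change = 4) {
  x <- as_tibble(snps)
  stopifnot(all(c("gene", "log2fc") %in% names(x)))
  out <- x %>%
    filter(abs(.data$log2fc) >= log2(min_fold_change)) %>%
    mutate(direction = ifelse(.data$log2fc > 0, "up", "down"))
  summary <- out %>%
    group_by(.data$direction) %>%
    summarise(n_snps = n(), n_genes = dplyr::n_distinct(.data$gene),
              .groups = "drop")
  attr(out, "de_summary") <- summary
  out
}

#' Summary of a [de_filter()] result
#' @param x Output of [de_filter()].
#' @return Tibble with `direction`, `n_snps`, `n_genes`.
#' @export
de_summary <- function(x) {
  s <- attr(x, "de_summary")
  if (is.null(s)) abort("no de_summary attribute; was this produced by de_filter()?")
  s
}

# Keep rows whose (chrom, pos) falls in a 1-based closed exon interval.
filter_exonic <- function(x, exons) {
  ex <- as_tibble(exons)
  stopifnot(all(c("chrom", "start", "end") %in% names(ex)))
  hit <- purrr::map_lgl(seq_len(nrow(x)), function(i) {
    any(ex$chrom == x$chrom[i] & ex$start <= x$pos[i] & ex$end >= x$pos[i])
  })
  x[hit, , drop = FALSE]
}
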