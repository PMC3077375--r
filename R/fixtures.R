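#' The 12-SNP worked-example genotype/consensus table
#'
#' A packaged fixture of twelve exonic SNPs in eight genes that
#' discriminate the HEF19 and hFL24 donor genomes in a differentiated
#' hybrid colony, with the hybrid transcriptome consensus call, the
#' first/second best base read counts (`"count\\depth"` strings), the donor
#' array genotypes (one missing call, ATP1B2, is `N/A`), and the log2
#' expression difference between the differentiated hFL and HEF cells.
#'
#' @param parsed If `TRUE` (default) returns an analysis-ready tibble with
#'   internal column names, integer `first_count`/`second_count`/`depth`
#'   parsed out of the frequency strings, and `NA` for missing genotypes;
#'   if `FALSE`, the file verbatim.
#' @return A tibble with 12 rows.
#' @export
#' @examples
#' table1_snps()
table1_snps <- function(parsed = TRUE) {
  path <- system.file("extdata", "table1_snps.tsv", package = "hybridase",
                      mustWork = TRUE)
  raw <- read_genotype_table(path)
  if (!parsed) {
    return(readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           na = character()))
  }
  parse_freq <- function(x) {
    parts <- stringr::str_split_fixed(x, stringr::fixed("\\"), 2)
    list(count = as.integer(parts[, 1]), depth = as.integer(parts[, 2]))
  }
  f1 <- parse_freq(raw[["1st Best Freq."]])
  f2 <- parse_freq(raw[["2nd Best Freq."]])
  stopifnot(all(f1$depth == f2$depth))
  tibble(
    chrom = raw$chrom,
    pos = raw$pos,
    gene = raw$gene,
    ref = raw$ref,
    consensus = raw[["Consensus Genome"]],
    first_base = raw[["1st Best Base"]],
    first_count = f1$count,
    second_base = raw[["2nd Best Base"]],
    second_count = f2$count,
    depth = f1$depth,
    hef = raw$hef,
    hfl = raw$hfl,
    log2fc = raw$log2fc
  )
}

#' Write the packaged fixture set to a directory
#'
#' Materializes the demo inputs used throughout the documentation: the
#' 12-SNP worked-example table, a toy exon annotation covering its sites
#' (BED), the two anchor primer sequences (FASTA), and a demo simulation
#' config (YAML if available, otherwise JSON-free R dput).
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  t1 <- system.file("extdata", "table1_snps.tsv", package = "hybridase",
                    mustWork = TRUE)
  dest <- file.path(dir, "table1_snps.tsv")
  file.copy(t1, dest, overwrite = TRUE)
  files <- c(files, dest)

  # toy exon annotation: one 201-nt exon centred on each fixture SNP
  snps <- table1_snps()
  exons <- snps %>%
    mutate(start = pmax(1L, .data$pos - 100L), end = .data$pos + 100L,
           name = .data$gene) %>%
    select("chrom", "start", "end", "name")
  bed <- file.path(dir, "toy_exons.bed")
  write_exons_bed(exons, bed)
  files <- c(files, bed)

  fa <- file.path(dir, "anchors.fasta")
  a <- anchor_specs()
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(a$sequence, a$name)), fa
  )
  files <- c(files, fa)

  cfg <- sim_config()
  cfg_path <- file.path(dir, "demo_config.yaml")
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(
      c(unclass(cfg)[setdiff(names(cfg), c("fold_changes", "n_snps"))],
        list(n_snps = as.list(cfg$n_snps))),
      cfg_path
    )
    files <- c(files, cfg_path)
  }
  invisible(files)
}
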