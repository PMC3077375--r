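#' Read and write sequencing/annotation files
#'
#' Thin wrappers around Biostrings and readr that move between the
#' package's tibble representations and the standard on-disk formats:
#' FASTA transcript references, FASTQ read sets (Sanger qualities), donor
#' genotype tables in the classic array-report dialect, and BED exon
#' annotation (0-based half-open on disk, 1-based closed in memory).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param reference Tibble with `transcript`, `sequence` (and optionally
#'   `gene`, `length`), or a named character vector.
#' @param genotypes Tibble with `chrom`, `pos`, `gene`, `ref`, `hef`, `hfl`.
#' @param exons Tibble with `chrom`, `start`, `end` (1-based closed).
#' @param path File path.
#' @name hyb_io
NULL

#' @rdname hyb_io
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "hyb_readset")) reads <- reads$reads
  q <- if ("quality" %in% names(reads)) reads$quality else strrep("I", nchar(reads$sequence))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
    Biostrings::PhredQuality(q)
  )
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' @rdname hyb_io
#' @export
read_reads_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(Biostrings::quality(x)))
  )
}

#' @rdname hyb_io
#' @export
write_reference_fasta <- function(reference, path) {
  ref <- as_reference_vector(reference)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' @rdname hyb_io
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(
    transcript = sub("\\s.*$", "", names(x)),
    gene = sub("\\s.*$", "", names(x)),
    length = Biostrings::width(x),
    sequence = unname(as.character(x))
  )
}

# classic array-report column dialect <-> internal names
GENOTYPE_DIALECT <- c(
  chrom = "Chromosome", pos = "Position", gene = "Gene", ref = "Ref. Gen.",
  hef = "HEF19 Genome", hfl = "hFL24 Genome",
  log2fc = "Expression dhFL24-HEF19"
)

#' @rdname hyb_io
#' @export
write_genotype_table <- function(genotypes, path) {
  g <- as_tibble(genotypes)
  keep <- names(GENOTYPE_DIALECT)[names(GENOTYPE_DIALECT) %in% names(g)]
  out <- g[keep]
  names(out) <- GENOTYPE_DIALECT[keep]
  out[is.na(out)] <- "N/A"
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname hyb_io
#' @export
read_genotype_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  nm <- names(raw)
  back <- setNames(names(GENOTYPE_DIALECT), GENOTYPE_DIALECT)
  names(raw) <- ifelse(nm %in% names(back), back[nm], nm)
  raw <- raw %>%
    mutate(
      chrom = as.character(.data$chrom),
      pos = as.integer(.data$pos)
    )
  if ("log2fc" %in% names(raw)) {
    raw$log2fc <- as.numeric(gsub("−", "-", raw$log2fc))
  }
  for (col in intersect(c("hef", "hfl"), names(raw))) {
    raw[[col]][raw[[col]] %in% c("N/A", "NA", "")] <- NA_character_
  }
  raw
}

#' @rdname hyb_io
#' @export
read_exons_bed <- function(path) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name"),
    col_types = "ciic", na = character(), comment = "#"
  )
  # BED is 0-based half-open; internally 1-based closed
  bed %>% mutate(start = .data$start + 1L, end = as.integer(.data$end))
}

#' @rdname hyb_io
#' @export
write_exons_bed <- function(exons, path) {
  ex <- as_tibble(exons)
  out <- tibble(
    chrom = ex$chrom,
    start = ex$start - 1L,
    end = ex$end,
    name = if ("name" %in% names(ex)) ex$name else
      paste0(ex$chrom, ":", ex$start, "-", ex$end)
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
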