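#' Classify a pair of donor genotypes
#'
#' Assigns each site to the category that decides whether reads at that site
#' can identify their genome of origin. A site is discriminating when the two
#' donor genotypes differ and are either both homozygous (`HOM_HOM_DIFF`) or
#' heterozygous in exactly one donor (`HET_ONE`). Both-heterozygous and
#' identical genotypes carry no origin information; a missing genotype
#' (`"N/A"` or `NA`) makes the site unusable.
#'
#' @param hef,hfl Character vectors of unordered genotype pairs, e.g. `"CG"`
#'   or `"GG"`; allele order does not matter. `"N/A"`, `"NA"`, `""` or `NA`
#'   mark a missing call.
#' @return Tibble with columns `category` (one of `HOM_HOM_DIFF`, `HET_ONE`,
#'   `HET_BOTH`, `IDENTICAL`, `MISSING`), `het_donor` (`"HEF"`/`"hFL"` for
#'   `HET_ONE`, otherwise `NA`), `shared_allele` and `unique_allele` (the
#'   discriminating alleles of a `HET_ONE` site: the allele carried by three
#'   of four tetraploid copies, and the allele unique to the heterozygous
#'   donor), and `hef_allele`/`hfl_allele` (per-donor alleles at
#'   `HOM_HOM_DIFF` sites).
#' @export
#' @examples
#' classify_genotypes(c("CG", "AA", "CT"), c("GG", "TT", "CT"))
classify_genotypes <- function(hef, hfl) {
  stopifnot(length(hef) == length(hfl))
  norm <- function(g) {
    g <- toupper(trimws(as.character(g)))
    g[is.na(g) | g %in% c("N/A", "NA", "")] <- NA_character_
    ok <- !is.na(g)
    a <- substr(g[ok], 1, 1)
    b <- substr(g[ok], 2, 2)
    bad <- nchar(g[ok]) != 2 | !(a %in% BASES) | !(b %in% BASES)
    if (any(bad)) {
      abort(paste("malformed genotype(s):", paste(unique(g[ok][bad]), collapse = ", ")))
    }
    g[ok] <- paste0(pmin(a, b), pmax(a, b))
    g
  }
  g1 <- norm(hef)
  g2 <- norm(hfl)
  alleles <- function(g) list(substr(g, 1, 1), substr(g, 2, 2))
  a1 <- alleles(g1); a2 <- alleles(g2)
  het1 <- !is.na(g1) & a1[[1]] != a1[[2]]
  het2 <- !is.na(g2) & a2[[1]] != a2[[2]]

  category <- case_when(
    is.na(g1) | is.na(g2) ~ "MISSING",
    g1 == g2 ~ "IDENTICAL",
    het1 & het2 ~ "HET_BOTH",
    !het1 & !het2 ~ "HOM_HOM_DIFF",
    TRUE ~ "HET_ONE"
  )
  het_donor <- ifelse(category == "HET_ONE", ifelse(het1, "HEF", "hFL"),
                      NA_character_)

  # discriminating alleles at HET_ONE sites: the homozygous donor's allele is
  # carried by 3 of 4 tetraploid copies when shared, 2 of 4 when disjoint;
  # an allele of the het pair absent from the hom genotype is donor-unique.
  hom_allele <- ifelse(het1, a2[[1]], a1[[1]])
  het_first <- ifelse(het1, a1[[1]], a2[[1]])
  het_second <- ifelse(het1, a1[[2]], a2[[2]])
  shared <- ifelse(category == "HET_ONE" &
                     (het_first == hom_allele | het_second == hom_allele),
                   hom_allele, NA_character_)
  uniq <- ifelse(category == "HET_ONE",
                 ifelse(het_first == hom_allele, het_second,
                        ifelse(het_second == hom_allele, het_first,
                               NA_character_)),
                 NA_character_)

  tibble(
    category = category,
    het_donor = het_donor,
    shared_allele = shared,
    unique_allele = uniq,
    hef_allele = ifelse(category == "HOM_HOM_DIFF", a1[[1]], NA_character_),
    hfl_allele = ifelse(category == "HOM_HOM_DIFF", a2[[1]], NA_character_)
  )
}

#' Fusion/amplification efficiency
#'
#' Percentage of input cells that gave rise to a hybrid colony, assuming each
#' colony is the progeny of a single hybrid cell.
#'
#' @param colonies Number of colonies observed.
#' @param input_cells Number of input cells used for fusion.
#' @param digits Decimal places for rounding (default 3, the precision at
#'   which such efficiencies are conventionally reported).
#' @return Efficiency as a percentage.
#' @export
#' @examples
#' fusion_efficiency(363, 2e6)  # 0.018
fusion_efficiency <- function(colonies, input_cells, digits = 3) {
  if (input_cells <= 0) abort("input_cells must be positive.")
  round(100 * colonies / input_cells, digits)
}
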