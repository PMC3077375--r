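#' Attribute reads at discriminating SNPs to their donor genome
#'
#' The core origin-attribution statistic. At each discriminating SNP the
#' uniquely aligned read bases are partitioned between the two donor
#' genomes:
#'
#' * `HOM_HOM_DIFF` sites (each donor homozygous for a different allele,
#'   2:2 copies in a tetraploid): every read of an allele is attributed
#'   wholly (coefficient 1) to the donor carrying it, in every mode.
#' * `HET_ONE` sites (one donor heterozygous `SU`, the other homozygous
#'   `SS`; the shared allele S sits on 3 of 4 copies):
#'   - `"allele_ratio"` — report only the majority(3-copy)/minority(1-copy)
#'     allele fractions; no donor split.
#'   - `"copy_proportional"` — shared-allele reads are split between donors
#'     by copy share (`major_share` to the homozygous donor, `minor_share`
#'     to the heterozygous donor); unique-allele reads go wholly to the
#'     heterozygous donor.
#'   - `"unique_allele"` — shared-allele reads wholly to the homozygous
#'     donor, unique-allele reads wholly to the heterozygous donor (the
#'     convention behind the 25%/75% theoretical expectation).
#'
#' Reads carrying a base found in neither donor genotype are treated as
#' sequencing error and excluded; if they exceed `error_budget` of the site
#' depth a warning is raised.
#'
#' The reported `majority_fraction` is defined structurally by copy number:
#' at `HET_ONE` sites it is the shared (3-copy) allele's share; at
#' `HOM_HOM_DIFF` sites the copies tie 2:2 and, by convention, the
#' hFL-genome allele's share is reported (theoretical expectation 50%
#' either way).
#'
#' @param snps Informative-SNP tibble (e.g. from [build_list_a()] or
#'   [cross_lists()]): `chrom`, `pos`, `gene`, `category`, `het_donor`,
#'   `shared_allele`, `unique_allele`, `hef_allele`, `hfl_allele`.
#' @param pileup Per-site base counts from [pileup_counts()].
#' @param mode Attribution convention, see above.
#' @param coefficients Length-2 numeric `c(major_share, minor_share)` for
#'   `"copy_proportional"`; defaults to exact thirds `c(2/3, 1/3)`. The
#'   string `"literal"` selects `c(0.66, 0.33)`, which reproduces
#'   legacy-style weighted counts at the cost of not conserving reads
#'   (0.66 + 0.33 < 1).
#' @param error_budget Tolerated fraction of off-genotype (error) reads
#'   before warning (default 0.05).
#' @return Tibble of class `hyb_attribution`, one row per covered SNP:
#'   allele counts (`n_major`, `n_minor`, `n_error`), `majority_fraction`,
#'   raw per-donor counts under the unique-allele reading (`hef_count`,
#'   `hfl_count`), weighted per-donor counts and fractions (`hef_weighted`,
#'   `hfl_weighted`, `hef_fraction`, `hfl_fraction`; `NA` for `HET_ONE`
#'   rows in `"allele_ratio"` mode), and `p_hef_expected`, the HEF-derived
#'   read fraction expected under full reprogramming with balanced
#'   expression. The `mode` is stored as an attribute.
#' @export
attribute_reads <- function(snps, pileup,
                            mode = c("allele_ratio", "copy_proportional",
                                     "unique_allele"),
                            coefficients = c(2 / 3, 1 / 3),
                            error_budget = 0.05) {
  mode <- match.arg(mode)
  if (identical(coefficients, "literal")) coefficients <- c(0.66, 0.33)
  if (identical(coefficients, "thirds")) coefficients <- c(2 / 3, 1 / 3)
  stopifnot(is.numeric(coefficients), length(coefficients) == 2)
  if (sum(coefficients) > 1 + 1e-9) {
    abort("major_share + minor_share must not exceed 1.")
  }
  major_share <- coefficients[1]
  minor_share <- coefficients[2]

  s <- as_tibble(snps)
  need <- c("chrom", "pos", "category", "het_donor",
            "shared_allele", "unique_allele", "hef_allele", "hfl_allele")
  if (!all(need %in% names(s))) {
    cls <- classify_genotypes(s$hef, s$hfl)
    s <- bind_cols(s[setdiff(names(s), names(cls))], cls)
  }
  s <- s %>% filter(.data$category %in% c("HOM_HOM_DIFF", "HET_ONE"))
  bad <- s$category == "HET_ONE" & (is.na(s$shared_allele) | is.na(s$unique_allele))
  if (any(bad)) {
    warn(sprintf("%d HET_ONE site(s) without a shared allele dropped.", sum(bad)))
    s <- s[!bad, , drop = FALSE]
  }

  pu <- as_tibble(pileup)
  s <- s %>% inner_join(pu[c("chrom", "pos", BASES)], by = c("chrom", "pos"))
  if (nrow(s) == 0) {
    out <- tibble()
    attr(out, "mode") <- mode
    class(out) <- c("hyb_attribution", class(out))
    return(out)
  }

  counts <- as.matrix(s[BASES])
  take <- function(allele) {
    n <- integer(nrow(s))
    ok <- !is.na(allele)
    n[ok] <- counts[cbind(which(ok), match(allele[ok], BASES))]
    n
  }

  is_hom <- s$category == "HOM_HOM_DIFF"
  major_allele <- ifelse(is_hom, s$hfl_allele, s$shared_allele)
  minor_allele <- ifelse(is_hom, s$hef_allele, s$unique_allele)
  n_major <- take(major_allele)
  n_minor <- take(minor_allele)
  depth <- rowSums(counts)
  n_error <- as.integer(depth - n_major - n_minor)
  over <- n_error > error_budget * depth
  if (any(over)) {
    warn(sprintf(
      "%d site(s) exceed the %.0f%% off-genotype error budget; error reads excluded.",
      sum(over), 100 * error_budget))
  }

  n_inf <- n_major + n_minor
  het_is_hef <- s$het_donor == "HEF"

  # raw per-donor counts under the unique-allele reading
  hef_count <- ifelse(is_hom, n_minor,
                      ifelse(het_is_hef, n_minor, n_major))
  hfl_count <- n_inf - hef_count

  # weighted donor counts
  if (mode == "copy_proportional") {
    het_w <- n_minor + minor_share * n_major        # heterozygous donor
    hom_w <- major_share * n_major                  # homozygous donor
    hef_weighted <- ifelse(is_hom, n_minor, ifelse(het_is_hef, het_w, hom_w))
    hfl_weighted <- ifelse(is_hom, n_major, ifelse(het_is_hef, hom_w, het_w))
  } else if (mode == "unique_allele") {
    hef_weighted <- as.numeric(hef_count)
    hfl_weighted <- as.numeric(hfl_count)
  } else {
    hef_weighted <- ifelse(is_hom, as.numeric(hef_count), NA_real_)
    hfl_weighted <- ifelse(is_hom, as.numeric(hfl_count), NA_real_)
  }
  w_total <- hef_weighted + hfl_weighted

  p_hef_expected <- ifelse(is_hom, 0.5,
    ifelse(het_is_hef,
           switch(mode, unique_allele = 0.25, copy_proportional = 0.5, NA_real_),
           switch(mode, unique_allele = 0.75, copy_proportional = 0.5, NA_real_)))

  keep_cols <- intersect(c("chrom", "pos", "gene", "category", "het_donor"),
                         names(s))
  out <- bind_cols(
    s[keep_cols],
    tibble(
      majority_allele = major_allele,
      minority_allele = minor_allele,
      n_major = as.integer(n_major),
      n_minor = as.integer(n_minor),
      n_error = n_error,
      n_informative = as.integer(n_inf),
      majority_fraction = ifelse(n_inf > 0, n_major / n_inf, NA_real_),
      hef_count = as.integer(hef_count),
      hfl_count = as.integer(hfl_count),
      hef_weighted = hef_weighted,
      hfl_weighted = hfl_weighted,
      hef_fraction = ifelse(!is.na(hef_weighted) & w_total > 0,
                            hef_weighted / w_total, NA_real_),
      hfl_fraction = ifelse(!is.na(hfl_weighted) & w_total > 0,
                            hfl_weighted / w_total, NA_real_),
      p_hef_expected = p_hef_expected
    )
  )
  attr(out, "mode") <- mode
  class(out) <- c("hyb_attribution", class(out))
  out
}

# population SD (denominator n), matching dispersion-across-SNPs reporting
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Summarize attribution records per SNP category
#'
#' Mean and standard deviation (across SNPs, population SD) of the
#' per-site majority-allele fraction and the HEF-derived fraction, grouped
#' by category and heterozygous donor, with the theoretical expectation for
#' a balanced hybrid attached: 1/2 at `HOM_HOM_DIFF` sites, 3/4 for the
#' majority allele at `HET_ONE` sites, and 1/4 (or 3/4) for the
#' heterozygous-donor-derived fraction under the unique-allele convention.
#'
#' @param records A `hyb_attribution` tibble from [attribute_reads()].
#' @return Tibble of class `hyb_attribution_summary`: one row per
#'   `(category, het_donor)` with `n_snps`, `mean_majority`, `sd_majority`,
#'   `theoretical_majority`, `mean_hef`, `sd_hef`, `theoretical_hef`, and a
#'   human-readable `label` in percent.
#' @export
summarize_attribution <- function(records) {
  stopifnot(inherits(records, "hyb_attribution"))
  if (nrow(records) == 0) {
    warn("no attribution records; empty summary.")
    return(structure(tibble(), class = c("hyb_attribution_summary", class(tibble()))))
  }
  out <- records %>%
    group_by(.data$category, .data$het_donor) %>%
    summarise(
      n_snps = n(),
      mean_majority = mean(.data$majority_fraction, na.rm = TRUE),
      sd_majority = pop_sd(.data$majority_fraction),
      theoretical_majority = ifelse(.data$category[1] == "HOM_HOM_DIFF", 0.5, 0.75),
      mean_hef = mean(.data$hef_fraction, na.rm = TRUE),
      sd_hef = pop_sd(.data$hef_fraction),
      theoretical_hef = .data$p_hef_expected[1],
      .groups = "drop"
    ) %>%
    mutate(label = sprintf(
      "%.1f±%.1f%%/%.1f±%.1f%% (theoretical %.0f%%/%.0f%%)",
      100 * .data$mean_majority, 100 * .data$sd_majority,
      100 * (1 - .data$mean_majority), 100 * .data$sd_majority,
      100 * .data$theoretical_majority, 100 * (1 - .data$theoretical_majority)
    ))
  attr(out, "mode") <- attr(records, "mode")
  class(out) <- c("hyb_attribution_summary", class(out))
  out
}

#' @export
print.hyb_attribution_summary <- function(x, ...) {
  cat("<attribution summary> mode:", attr(x, "mode") %||% "?", "\n")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
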