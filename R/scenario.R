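#' Decide between a reprogrammed genome and silent cargo
#'
#' Tests whether the HEF-derived read fractions at discriminating SNPs match
#' the copy-proportional expectations of a fully reprogrammed genome (1/2 at
#' `HOM_HOM_DIFF` sites, 1/4 or 3/4 at `HET_ONE` sites depending on which
#' donor is heterozygous) or are depleted toward zero, as they would be if
#' the HEF genome were carried as transcriptionally silent cargo. Each SNP
#' gets a two-sided exact binomial test of its HEF-derived count against the
#' reprogrammed expectation; p-values are Bonferroni-corrected.
#'
#' Verdict rule: let R be the pooled HEF-derived read count divided by its
#' copy-proportional expectation (R = 1 under full reprogramming, R = 0
#' under fully silent cargo). With fewer than `min_snps` covered SNPs the
#' test is `"inconclusive"`; when at most half the SNPs reject the
#' reprogrammed expectation and R >= 3/4 the verdict is `"reprogrammed"`;
#' when R < 1/4 it is `"cargo"`; anything between is `"intermediate"`
#' (partial silencing).
#'
#' @param records A `hyb_attribution` tibble from [attribute_reads()]
#'   (any mode; the raw unique-allele counts are used).
#' @param alpha Family-wise significance level after Bonferroni correction
#'   (default 0.05).
#' @param min_snps Minimum covered SNPs for a verdict (default 3).
#' @return A list of class `hyb_scenario`: `verdict`, `n_snps`,
#'   `frac_rejecting`, `pooled_hef_fraction`, `expected_hef_fraction`,
#'   `alpha`, and `tests` (per-SNP tibble with counts, expectation, p_value
#'   and `p_adj`). Use [tidy()] / [glance()] for tidy access.
#' @export
scenario_test <- function(records, alpha = 0.05, min_snps = 3) {
  stopifnot(inherits(records, "hyb_attribution"))
  # only HOM_HOM_DIFF and HET_ONE(HEF-het) sites carry an HEF-unique allele
  # whose depletion separates the two regimes; at HET_ONE(hFL-het) sites the
  # shared allele is expressed by both genomes either way
  r <- as_tibble(records) %>%
    filter(.data$n_informative > 0,
           .data$category == "HOM_HOM_DIFF" |
             (!is.na(.data$het_donor) & .data$het_donor == "HEF"))
  p0 <- ifelse(r$category == "HOM_HOM_DIFF", 0.5, 0.25)
  tests <- r %>%
    mutate(
      p_reprogrammed = p0,
      p_value = purrr::map_dbl(seq_len(n()), function(i) {
        binom.test(r$hef_count[i], r$n_informative[i], p0[i])$p.value
      }),
      p_adj = pmin(1, .data$p_value * n()),
      hef_fraction_raw = .data$hef_count / .data$n_informative
    ) %>%
    select("chrom", "pos", "category", "het_donor", "hef_count",
           "n_informative", "hef_fraction_raw", "p_reprogrammed",
           "p_value", "p_adj")

  n_snps <- nrow(tests)
  pooled <- if (n_snps) sum(tests$hef_count) / sum(tests$n_informative) else NA_real_
  expected <- if (n_snps) {
    sum(tests$p_reprogrammed * tests$n_informative) / sum(tests$n_informative)
  } else NA_real_
  frac_rej <- if (n_snps) mean(tests$p_adj < alpha) else NA_real_
  hef_ratio <- pooled / expected

  verdict <- if (n_snps < min_snps) {
    "inconclusive"
  } else if (frac_rej <= 0.5 && hef_ratio >= 0.75) {
    "reprogrammed"
  } else if (hef_ratio < 0.25) {
    "cargo"
  } else {
    "intermediate"
  }

  structure(
    list(verdict = verdict, n_snps = n_snps, frac_rejecting = frac_rej,
         pooled_hef_fraction = pooled, expected_hef_fraction = expected,
         hef_ratio = hef_ratio, alpha = alpha, tests = tests),
    class = "hyb_scenario"
  )
}

#' @export
print.hyb_scenario <- function(x, ...) {
  cat("<scenario test> verdict:", x$verdict, "\n")
  cat(sprintf("  %d SNPs; pooled HEF-derived fraction %.3f (expected %.3f if reprogrammed)\n",
              x$n_snps, x$pooled_hef_fraction, x$expected_hef_fraction))
  cat(sprintf("  %.0f%% of SNPs reject the reprogrammed expectation at Bonferroni alpha %.2g\n",
              100 * x$frac_rejecting, x$alpha))
  invisible(x)
}

#' Tidy the per-SNP tests of a scenario decision
#' @param x A `hyb_scenario` object.
#' @param ... Unused.
#' @return The per-SNP test tibble.
#' @export
tidy.hyb_scenario <- function(x, ...) x$tests

#' One-row summary of a scenario decision
#' @param x A `hyb_scenario` object.
#' @param ... Unused.
#' @return One-row tibble with verdict and pooled statistics.
#' @export
glance.hyb_scenario <- function(x, ...) {
  tibble(
    verdict = x$verdict,
    n_snps = x$n_snps,
    frac_rejecting = x$frac_rejecting,
    pooled_hef_fraction = x$pooled_hef_fraction,
    expected_hef_fraction = x$expected_hef_fraction,
    hef_ratio = x$hef_ratio,
    alpha = x$alpha
  )
}

#' Tidy an attribution summary
#' @param x A `hyb_attribution_summary`.
#' @param ... Unused.
#' @return The summary as a plain tibble.
#' @export
tidy.hyb_attribution_summary <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "mode") <- NULL
  out
}
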