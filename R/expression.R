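#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the identical value distribution: each
#' sample's sorted values are replaced by the across-sample means of the
#' sorted values, with ties within a sample resolved by averaging over the
#' tied ranks. Idempotent; after normalization all columns share the same
#' sorted vector.
#'
#' @param x Numeric matrix or data frame (genes in rows, samples in
#'   columns); a `gene` character column is carried through unchanged.
#' @return Same shape as the input, normalized.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantile_normalize <- function(x) {
  gene_col <- NULL
  was_df <- is.data.frame(x)
  if (was_df) {
    if ("gene" %in% names(x)) {
      gene_col <- x$gene
      x <- x[setdiff(names(x), "gene")]
    }
    x <- as.matrix(x)
  }
  if (!is.numeric(x)) abort("expression values must be numeric.")
  if (anyNA(x)) abort("expression matrix contains missing values.")
  if (ncol(x) < 2) abort("quantile normalization needs at least 2 samples.")

  n <- nrow(x)
  sorted <- apply(x, 2, sort)
  target <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # average the target over tied (possibly fractional) ranks
    lo <- floor(r); hi <- ceiling(r)
    out[, j] <- (target[lo] + target[hi]) / 2
  }
  if (was_df) {
    res <- as_tibble(out)
    if (!is.null(gene_col)) res <- bind_cols(tibble(gene = gene_col), res)
    return(res)
  }
  out
}

#' Pearson product-moment correlation via standard scores
#'
#' Computes r as the mean product of the two profiles' standard scores,
#' `sum(z_x * z_y) / (n - 1)` with `z = (x - mean(x)) / sd(x)` — the form
#' used to compare genome-wide expression profiles between cell types.
#'
#' @param x,y Equal-length numeric vectors of length at least 2.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' pmcc(1:10, (1:10)^2)
pmcc <- function(x, y) {
  if (length(x) != length(y)) abort("profiles must have equal length.")
  n <- length(x)
  if (n < 2) abort("need at least 2 observations.")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) abort("correlation undefined for zero-variance profile.")
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy
  sum(zx * zy) / (n - 1)
}

#' Pairwise PMCC table for an expression matrix
#'
#' @param x Numeric matrix or data frame (samples in columns; optional
#'   `gene` column ignored).
#' @return Tibble with `sample_x`, `sample_y`, `pmcc` for every unordered
#'   pair.
#' @export
pmcc_pairs <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[setdiff(names(x), "gene")])
  cols <- colnames(x) %||% paste0("S", seq_len(ncol(x)))
  pairs <- utils::combn(seq_len(ncol(x)), 2)
  tibble(
    sample_x = cols[pairs[1, ]],
    sample_y = cols[pairs[2, ]],
    pmcc = purrr::map2_dbl(pairs[1, ], pairs[2, ],
                           function(i, j) pmcc(x[, i], x[, j]))
  )
}

#' Per-gene log2 fold change
#'
#' `log2((a + pseudocount) / (b + pseudocount))` on linear-scale inputs;
#' antisymmetric under swapping the two profiles.
#'
#' @param expr_a,expr_b Non-negative numeric vectors (linear scale).
#' @param pseudocount Added to both before the ratio (default 1).
#' @return Numeric vector of log2 differences (positive = higher in
#'   `expr_a`).
#' @export
log2_fold_change <- function(expr_a, expr_b, pseudocount = 1) {
  if (any(expr_a < 0) || any(expr_b < 0)) abort("expression must be non-negative.")
  log2((expr_a + pseudocount) / (expr_b + pseudocount))
}
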