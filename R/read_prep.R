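#' Anchor primer specifications
#'
#' The two anchor primers used for reverse transcription and second-strand
#' synthesis of the single-colony cDNA library. Each primer carries a unique
#' sequence (UP1 or UP2), a rare-cutter BstUI recognition site (CGCG) and a
#' poly-T tail, so that BstUI digestion releases the anchors from the cDNA
#' before sequencing.
#'
#' @return Tibble with `name`, `sequence` (full primer) and
#'   `restriction_site` (`"CGCG"`).
#' @export
anchor_specs <- function() {
  polyt <- strrep("T", 24)
  tibble(
    name = c("UP1", "UP2"),
    sequence = c(
      paste0("ATATGGATCCGGCGCGCCGTCGACCGCG", polyt),
      paste0("ATATCTCGAGGGCGCGCCGGATCCCGCG", polyt)
    ),
    restriction_site = "CGCG"
  )
}

#' In-silico BstUI digestion
#'
#' Cuts a DNA sequence at every CG^CG site (blunt cut between the two CG
#' dinucleotides). Overlapping recognition sites are resolved left to right,
#' as a processive enzyme scanning the molecule would: once a site is cut,
#' the scan resumes after it.
#'
#' @param sequence A single DNA string over `{A,C,G,T,N}`.
#' @return Character vector of fragments, in order; their concatenation
#'   reproduces the input. An empty sequence yields one empty fragment.
#' @export
#' @examples
#' digest_bstu1("ACGCGA")  # "ACG" "CGA"
digest_bstu1 <- function(sequence) {
  stopifnot(length(sequence) == 1)
  if (!grepl("^[ACGTN]*$", sequence)) {
    abort("sequence must be over {A,C,G,T,N}.")
  }
  m <- gregexpr("CGCG", sequence, fixed = TRUE)[[1]]
  if (m[1] == -1) return(sequence)
  # gregexpr already returns non-overlapping matches left-to-right
  cuts <- as.integer(m) + 1L          # cut after position m+1 (CG | CG)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(sequence))
  substring(sequence, starts, ends)
}

#' Trim anchor and poly-T prefixes from reads
#'
#' Removes residual library-construction anchors: any read whose prefix
#' matches an anchor primer within `max_mismatches` (over the shorter of the
#' two lengths) loses the matched prefix plus any immediately following
#' poly-T run of at least `polyt_min` bases. Reads shorter than `min_length`
#' after trimming are dropped and counted. The operation is idempotent.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `quality`
#'   (trimmed in step), or a `hyb_readset` (its `$reads` is used).
#' @param anchors Anchor table as from [anchor_specs()].
#' @param max_mismatches Mismatches tolerated in the anchor prefix match
#'   (default 1).
#' @param min_length Minimum read length kept after trimming (default 20).
#' @param polyt_min Minimum run of consecutive T counted as primer-derived
#'   poly-T (default 10).
#' @return The surviving reads as a tibble, with a `trim_report` attribute
#'   (tibble: `n_input`, `n_trimmed`, `n_dropped`, `n_out`); retrieve it with
#'   [trim_report()].
#' @export
trim_anchors <- function(reads, anchors = anchor_specs(), max_mismatches = 1,
                         min_length = 20, polyt_min = 10) {
  if (inherits(reads, "hyb_readset")) reads <- reads$reads
  reads <- as_tibble(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  n_input <- nrow(reads)
  has_qual <- "quality" %in% names(reads)

  seqs <- reads$sequence
  cut_at <- rep(0L, length(seqs))  # number of leading bases to remove

  for (i in seq_len(nrow(anchors))) {
    anchor <- anchors$sequence[i]
    alen <- nchar(anchor)
    k <- pmin(nchar(seqs), alen)
    todo <- which(cut_at == 0L & k > 0L)
    if (!length(todo)) next
    # pad so hamming_pairs sees equal-width groups; compare per unique width
    for (w in unique(k[todo])) {
      idx <- todo[k[todo] == w]
      mm <- hamming_pairs(substr(seqs[idx], 1, w), rep(substr(anchor, 1, w), length(idx)))
      hit <- idx[mm <= max_mismatches]
      cut_at[hit] <- w
    }
  }

  # strip the poly-T run following a removed anchor
  trimmed <- cut_at > 0L
  out_seq <- seqs
  if (any(trimmed)) {
    rest <- substr(seqs[trimmed], cut_at[trimmed] + 1L, nchar(seqs[trimmed]))
    tlen <- attr(regexpr("^T+", rest), "match.length")
    tlen[tlen < polyt_min] <- 0L
    tlen[tlen < 0L] <- 0L
    out_seq[trimmed] <- substr(rest, tlen + 1L, nchar(rest))
  }

  out <- reads
  out$sequence <- out_seq
  if (has_qual) {
    off <- nchar(seqs) - nchar(out_seq)
    out$quality <- substr(reads$quality, off + 1L, nchar(reads$quality))
  }
  keep <- nchar(out$sequence) >= min_length
  report <- tibble(
    n_input = n_input,
    n_trimmed = sum(trimmed),
    n_dropped = sum(!keep),
    n_out = sum(keep)
  )
  out <- out[keep, , drop = FALSE]
  attr(out, "trim_report") <- report
  out
}

#' Retrieve the trimming report of [trim_anchors()]
#'
#' @param x Output of [trim_anchors()].
#' @return Tibble with `n_input`, `n_trimmed`, `n_dropped`, `n_out`.
#' @export
trim_report <- function(x) {
  r <- attr(x, "trim_report")
  if (is.null(r)) abort("no trim_report attribute found; was this produced by trim_anchors()?")
  r
}
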