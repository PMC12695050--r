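# Per-base scanning SNV caller: every reference base is interrogated by
# substituting each alternate at the 3'-most position of its anchoring
# k-mer and querying the overlapping k-mers covering it (start offsets
# stepping by j) against the sample's k-mer index.

default_min_queried <- function(k, j) {
  max(3L, as.integer(floor(k / (2 * j))))
}

#' Call single-nucleotide variants against a reference
#'
#' Scans every reference position 5' to 3'. At each position the set of
#' k-mers covering it -- anchored at the k-mer whose 3'-most base is the
#' position, with start offsets stepping by `j`, truncated at contig ends
#' -- is queried in the sample index with each of the four bases
#' substituted at the position. An SNV is emitted for every alternate
#' base whose support fraction (hits / k-mers queried) meets or exceeds
#' the threshold `Y`; the same statistic for the reference base is
#' recorded for information. Positions whose ref base is not A/C/G/T, or
#' with fewer than `min_queried` queryable k-mers (contig ends, N runs),
#' are skipped and tallied.
#'
#' @param reference Reference genome: FASTA path, `DNAStringSet`, or named
#'   character vector of contigs.
#' @param index A `bloom_filter` or `kmer_exact_set` built from the
#'   sample's reads or assembly; its `k` is used.
#' @param j Query stride in bases (default 3), `1 <= j <= k`.
#' @param Y Support-fraction threshold in (0, 1] (default 0.55).
#' @param min_queried Minimum queryable k-mers at a position; default
#'   `max(3, floor(k / (2 j)))`.
#' @return A tibble with one row per call: `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `ksf` (alternate support fraction), `rsf` (reference
#'   support fraction), `nq` (k-mers queried), sorted by contig order,
#'   position, then alternate base. The number of skipped positions is
#'   attached as attribute `n_skipped`.
#' @export
call_snvs <- function(reference, index, j = 3L, Y = 0.55, min_queried = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- as_seq_vector(reference, "reference")
  k <- index$k
  j <- as.integer(j)
  if (is.na(j) || j < 1 || j > k) stop("j must be in [1, k]", call. = FALSE)
  if (!is.numeric(Y) || Y <= 0 || Y > 1) stop("Y must be in (0, 1]", call. = FALSE)
  if (is.null(min_queried)) min_queried <- default_min_queried(k, j)
  res <- cpp_call_snvs(unname(seqs), contig_names(seqs), index$ptr, j, Y,
                       as.integer(min_queried))
  calls <- tibble::tibble(
    chrom = as.character(res$chrom), pos = res$pos,
    ref = as.character(res$ref), alt = as.character(res$alt),
    ksf = res$ksf, rsf = res$rsf, nq = res$nq
  )
  # contig order, then position, then alternate base
  ord <- order(match(calls$chrom, contig_names(seqs)), calls$pos, calls$alt)
  calls <- calls[ord, ]
  attr(calls, "n_skipped") <- res$n_skipped
  calls
}

#' Support fraction for one base at one position
#'
#' The single-position primitive behind [call_snvs()]: substitutes `base`
#' at 1-based position `pos` of contig `chrom` and queries the covering
#' k-mers (start offsets stepping by `j`, anchored at the k-mer ending at
#' `pos`, truncated at contig ends).
#'
#' @inheritParams call_snvs
#' @param chrom Contig name.
#' @param pos 1-based position within the contig.
#' @param base The base (A/C/G/T) to substitute at `pos`.
#' @return A list with `fraction` (hits / n_queried; `NA` when fewer than
#'   `min_queried` k-mers were queryable -- a skip signal, not an error)
#'   and `n_queried`.
#' @export
evaluate_base <- function(reference, chrom, pos, base, index, j = 3L,
                          min_queried = NULL) {
  stopifnot(inherits(index, "kmer_index"))
  seqs <- as_seq_vector(reference, "reference")
  i <- match(chrom, contig_names(seqs))
  if (is.na(i)) stop("contig '", chrom, "' not found in reference", call. = FALSE)
  if (pos < 1 || pos > nchar(seqs[[i]])) stop("position out of contig bounds", call. = FALSE)
  if (is.null(min_queried)) min_queried <- default_min_queried(index$k, j)
  res <- cpp_evaluate_base(seqs[[i]], as.numeric(pos), base, index$ptr, as.integer(j))
  fraction <- if (res$n_queried < min_queried) NA_real_ else res$hits / res$n_queried
  list(fraction = fraction, n_queried = res$n_queried)
}
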