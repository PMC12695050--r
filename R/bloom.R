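# Bloom filters of canonical k-mers, built from reads (with solid-k-mer
# error filtering) or from assemblies / other 1x genome representations.

#' Bloom filter size for a target false-positive rate
#'
#' Returns the smallest bit length `m`, rounded up to a whole byte, such
#' that the theoretical Bloom false-positive rate
#' \eqn{(1 - e^{-hn/m})^h} is at most `target_fpr` for `n_expected`
#' distinct keys and `num_hashes` hash functions.
#'
#' @param n_expected Expected number of distinct k-mers to insert.
#' @param target_fpr Target false-positive probability, in (0, 1).
#' @param num_hashes Number of hash functions `h` (default 3).
#' @return Bit length `m` (a double; may exceed `.Machine$integer.max`).
#' @export
#' @examples
#' bloom_size_for_fpr(1000, 0.0174, num_hashes = 3)
bloom_size_for_fpr <- function(n_expected, target_fpr, num_hashes = 3L) {
  if (!is.numeric(n_expected) || length(n_expected) != 1 || n_expected <= 0) {
    stop("n_expected must be a positive number", call. = FALSE)
  }
  if (!is.numeric(target_fpr) || length(target_fpr) != 1 ||
      target_fpr <= 0 || target_fpr >= 1) {
    stop("target_fpr must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(num_hashes) || length(num_hashes) != 1 || num_hashes < 1) {
    stop("num_hashes must be a positive integer", call. = FALSE)
  }
  h <- as.integer(num_hashes)
  # (1 - exp(-hn/m))^h <= f  <=>  m >= h n / (-log(1 - f^(1/h)))
  m_min <- h * n_expected / (-log1p(-target_fpr^(1 / h)))
  max(8, 8 * ceiling(m_min / 8))
}

#' Theoretical Bloom filter false-positive rate
#'
#' @param bf A `bloom_filter` object.
#' @return \eqn{(1 - e^{-hn/m})^h} computed from the filter's fields.
#' @export
bloom_fpr <- function(bf) {
  info <- kmer_index_info(bf)
  (1 - exp(-info$h * info$n_inserted / info$m))^info$h
}

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographic minimum of a k-mer and its
#' reverse complement, which makes all k-mer queries strand-agnostic.
#' Lowercase bases are accepted; k-mers containing any non-ACGT base
#' yield `NA` (the caller discards them).
#'
#' @param kmers Character vector of k-mers (each of length at most 64).
#' @return Character vector of canonical k-mers, `NA` where invalid.
#' @export
#' @examples
#' canonical_kmer(c("AAAT", "TTTT", "ACGT"))
canonical_kmer <- function(kmers) {
  stopifnot(is.character(kmers))
  cpp_canonical(kmers)
}

new_kmer_index <- function(ptr, subclass, extra = list()) {
  info <- cpp_index_info(ptr)
  structure(c(list(ptr = ptr, k = info$k), extra),
            class = c(subclass, "kmer_index"))
}

# Shared build path: exact counting pre-pass, then membership structure.
build_index <- function(seqs, k, min_count, target_fpr, num_hashes, exact = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 2 || k > 64) {
    stop("k must be an integer between 2 and 64 (recommended >= 16)", call. = FALSE)
  }
  if (all(nchar(seqs) < k)) {
    stop("all input sequences are shorter than k = ", k, call. = FALSE)
  }
  counts <- cpp_kmer_count(seqs, k)
  auto <- is.null(min_count) || is.na(min_count)
  min_count <- if (auto) solid_threshold(counts) else as.integer(min_count)
  if (min_count < 1) stop("min_count must be >= 1", call. = FALSE)
  n_solid <- cpp_count_solid(counts, min_count)
  if (n_solid < 1) {
    stop("no k-mers occur at least min_count = ", min_count, " times", call. = FALSE)
  }
  if (exact) {
    ptr <- cpp_exact_from_counts(counts, min_count)
    return(new_kmer_index(ptr, "kmer_exact_set", list(min_count = min_count)))
  }
  m <- bloom_size_for_fpr(n_solid, target_fpr, num_hashes)
  ptr <- cpp_bf_from_counts(counts, min_count, m, as.integer(num_hashes))
  new_kmer_index(ptr, "bloom_filter",
                 list(min_count = min_count, target_fpr = target_fpr,
                      auto_threshold = auto))
}

# The k-mer multiplicity histogram of error-bearing reads is bimodal: a
# decaying sequencing-error cluster at low counts and a solid cluster
# around the k-mer coverage. The valley floor itself is still dominated
# by the error cluster's tail (its Poisson ratio accounts for the whole
# bin at typical error rates), so the solidity threshold is set one above
# the first upturn of the histogram.
solid_threshold <- function(counts, max_bin = 64L) {
  hist <- cpp_count_histogram(counts, max_bin)
  for (c in 2:(max_bin - 1)) {
    if (hist[c] < hist[c + 1]) return(c + 1L)
  }
  2L
}

#' Build a Bloom filter of solid k-mers from sequencing reads
#'
#' Canonical k-mers are counted exactly, k-mers occurring fewer than
#' `min_count` times are discarded as likely sequencing errors, and the
#' survivors are inserted into a Bloom filter sized for `target_fpr`.
#' With `min_count = NULL` the solidity threshold is chosen automatically
#' as the first valley of the k-mer multiplicity histogram, which tracks
#' the boundary between the error cluster and the coverage peak.
#'
#' @param reads FASTA/FASTQ path(s) (optionally gzipped), a
#'   `DNAStringSet`, or a character vector of read sequences.
#' @param k K-mer length (2--64; 16 or more recommended, default 55).
#' @param min_count Solidity threshold; `NULL` for automatic selection.
#' @param target_fpr Target Bloom false-positive rate (default 0.001).
#' @param num_hashes Number of hash functions (default 3).
#' @return A `bloom_filter` object.
#' @export
bloom_from_reads <- function(reads, k = 55L, min_count = NULL,
                             target_fpr = 0.001, num_hashes = 3L) {
  seqs <- as_seq_vector(reads, "reads")
  build_index(seqs, k, min_count, target_fpr, num_hashes)
}

#' Build a Bloom filter from a genome assembly
#'
#' Every canonical k-mer of every sequence is inserted (solidity threshold
#' 1): an assembly or any other 1x representation of a genome carries no
#' k-mer redundancy to filter on.
#'
#' @inheritParams bloom_from_reads
#' @param assembly FASTA path, `DNAStringSet`, or character vector of
#'   contig/haplotype sequences.
#' @return A `bloom_filter` object.
#' @export
bloom_from_assembly <- function(assembly, k = 55L, target_fpr = 0.001,
                                num_hashes = 3L) {
  seqs <- as_seq_vector(assembly, "assembly")
  build_index(seqs, k, min_count = 1L, target_fpr, num_hashes)
}

#' Exact canonical k-mer set
#'
#' Same construction and interface as the Bloom filter builders but with
#' exact membership (no false positives). Used as the reference oracle
#' when validating Bloom-backed calls, and usable anywhere a
#' `bloom_filter` is.
#'
#' @inheritParams bloom_from_reads
#' @param x Sequences (path, `DNAStringSet`, or character vector).
#' @return A `kmer_exact_set` object.
#' @export
exact_kmer_set <- function(x, k = 55L, min_count = 1L) {
  seqs <- as_seq_vector(x, "sequences")
  build_index(seqs, k, min_count, target_fpr = NA, num_hashes = NA, exact = TRUE)
}

#' Query k-mers against a k-mer index
#'
#' @param index A `bloom_filter` or `kmer_exact_set`.
#' @param kmers Character vector of k-mers of the index's `k`. Queries are
#'   strand-agnostic (canonicalized internally); k-mers containing
#'   non-ACGT characters return `NA`.
#' @return Logical vector of membership results.
#' @export
kmer_contains <- function(index, kmers) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_contains(index$ptr, kmers)
}

#' Fields of a k-mer index
#'
#' @param index A `bloom_filter` or `kmer_exact_set`.
#' @return A list with `type`, `k`, `m` (bits; `NA` for exact sets), `h`
#'   (`NA` for exact sets), and `n_inserted` (distinct k-mers inserted).
#' @export
kmer_index_info <- function(index) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_index_info(index$ptr)
}

#' Serialize a Bloom filter to a file
#'
#' Writes a small binary header (magic, k, number of hashes, bit length,
#' insert count) followed by the raw bit array, so a filter built once can
#' be reloaded by the SNV caller.
#'
#' @param bf A `bloom_filter`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
bloom_save <- function(bf, path) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bf_save(bf$ptr, path)
  invisible(path)
}

#' @rdname bloom_save
#' @export
bloom_load <- function(path) {
  if (!file.exists(path)) stop("Bloom filter file not found: '", path, "'", call. = FALSE)
  new_kmer_index(cpp_bf_load(path), "bloom_filter")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- kmer_index_info(x)
  if (info$type == "bloom") {
    cat(sprintf("<bloom_filter> k=%d, m=%s bits, h=%d, n_inserted=%s, theoretical FPR=%.3g\n",
                info$k, format(info$m, big.mark = ","), info$h,
                format(info$n_inserted, big.mark = ","), bloom_fpr(x)))
  } else {
    cat(sprintf("<kmer_exact_set> k=%d, n_inserted=%s\n",
                info$k, format(info$n_inserted, big.mark = ",")))
  }
  invisible(x)
}
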