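# Pure-R oracles, independent of the package's C++ k-mer machinery.

# reverse complement of an ACGT string
rc_r <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

canonical_r <- function(kmer) {
  r <- rc_r(kmer)
  if (kmer <= r) kmer else r
}

# brute-force enumeration of all canonical k-mers of a sequence
# (k-mers touching a non-ACGT character are dropped)
enumerate_kmers_r <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  vapply(kmers, canonical_r, "", USE.NAMES = FALSE)
}

# exact canonical k-mer counter over a set of sequences
count_kmers_r <- function(seqs, k) {
  table(unlist(lapply(seqs, enumerate_kmers_r, k = k)))
}

# brute-force support-fraction evaluator: enumerates the covering k-mers
# of a position from an exact canonical k-mer set (an R character vector)
evaluate_base_r <- function(seq, pos, base, kmer_set, k, j) {
  L <- nchar(seq)
  starts <- seq.int(pos - k + 1, pos, by = j)
  starts <- starts[starts >= 1 & starts + k - 1 <= L]
  hits <- 0L
  n <- 0L
  for (s in starts) {
    w <- substring(seq, s, s + k - 1)
    if (grepl("[^ACGT]", w)) next
    substr(w, pos - s + 1, pos - s + 1) <- base
    n <- n + 1L
    if (canonical_r(w) %in% kmer_set) hits <- hits + 1L
  }
  list(fraction = if (n > 0) hits / n else NA_real_, n_queried = n)
}

random_genome <- function(len, seed, name = "chr1") {
  rootstock::simulate_reference(stats::setNames(len, name), seed = seed)
}

# plant homozygous substitutions at given positions; returns donor + truth
plant_snvs <- function(ref, positions, seed) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- names(ref)[1]
  s <- ref[[1]]
  refb <- substring(s, positions, positions)
  altb <- vapply(refb, function(r) sample(setdiff(bases, r), 1), "",
                 USE.NAMES = FALSE)
  for (i in seq_along(positions)) {
    substr(s, positions[i], positions[i]) <- altb[i]
  }
  donor <- stats::setNames(s, paste0(chrom, "_donor"))
  list(donor = donor,
       truth = tibble::tibble(chrom = chrom, pos = as.numeric(positions),
                              ref = refb, alt = altb))
}

call_key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
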