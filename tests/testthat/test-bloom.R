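test_that("bloom_size_for_fpr returns the smallest byte-rounded size meeting the target", {
  fpr <- function(m, n, h) (1 - exp(-h * n / m))^h

  # closed-form check case: (1 - e^(-0.3))^3 ~ 0.0174, so m = 10000 suffices
  expect_equal(fpr(10000, 1000, 3), 0.01741059, tolerance = 1e-6)
  m <- bloom_size_for_fpr(1000, fpr(10000, 1000, 3), num_hashes = 3)
  expect_equal(m, 10000)
  expect_lte(fpr(m, 1000, 3), fpr(10000, 1000, 3))
  expect_gt(fpr(m - 8, 1000, 3), fpr(10000, 1000, 3))  # minimality

  # degenerate lower bound: one byte
  expect_equal(bloom_size_for_fpr(1, 0.999, num_hashes = 1), 8)

  # large case verified by direct substitution, plus minimality
  m <- bloom_size_for_fpr(1e6, 1e-4, num_hashes = 3)
  expect_lte(fpr(m, 1e6, 3), 1e-4)
  expect_gt(fpr(m - 8, 1e6, 3), 1e-4)

  expect_error(bloom_size_for_fpr(0, 0.01), "positive")
  expect_error(bloom_size_for_fpr(10, 1), "between 0 and 1")
})

test_that("canonical_kmer is the lexicographic min of a k-mer and its reverse complement", {
  expect_equal(canonical_kmer(c("AAAT", "TTTT", "ACGT")),
               c("AAAT", "AAAA", "ACGT"))
  expect_equal(canonical_kmer("acgt"), "ACGT")  # lowercase accepted
  expect_true(is.na(canonical_kmer("ACNT")))    # skip signal

  # idempotence and agreement with the pure-R oracle on random k-mers
  set.seed(42)
  for (k in c(5, 16, 31, 55, 64)) {
    kmers <- vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
    }, "")
    canon <- canonical_kmer(kmers)
    expect_equal(canon, vapply(kmers, canonical_r, "", USE.NAMES = FALSE))
    expect_equal(canonical_kmer(canon), canon)
  }
})

test_that("reads-mode construction keeps exactly the k-mers at or above min_count", {
  # one read: all 4 canonical 5-mers present
  bf <- bloom_from_reads("ACGTACGT", k = 5, min_count = 1)
  kmers <- substring("ACGTACGT", 1:4, 5:8)
  expect_true(all(kmer_contains(bf, kmers)))
  expect_equal(kmer_index_info(bf)$n_inserted, length(unique(canonical_kmer(kmers))))

  # threshold semantics: a singleton error k-mer is excluded at min_count = 2
  reads <- c("ACGTACGT", "ACGTACGT", "ACGAACGT")  # third has T->A error
  bf2 <- bloom_from_reads(reads, k = 5, min_count = 2)
  expect_true(all(kmer_contains(bf2, kmers)))
  expect_equal(kmer_index_info(bf2)$n_inserted,
               length(unique(canonical_kmer(kmers))))
  expect_false(kmer_contains(bf2, "ACGAA"))  # the singleton error k-mer

  expect_error(bloom_from_reads(character(0), k = 5), "empty")
  expect_error(bloom_from_reads(c("ACG", "GT"), k = 5), "shorter than k")
})

test_that("solid k-mer set from noisy reads matches a brute-force counter", {
  ref <- random_genome(5000, seed = 101)
  donor <- c(hap1 = unname(ref), hap2 = unname(ref))
  reads <- simulate_reads(donor, coverage = 30, read_length = 80,
                          error_rate = 0.005, seed = 102)
  k <- 21
  counts <- count_kmers_r(reads$seq, k)
  solid <- names(counts)[counts >= 2]
  bf <- bloom_from_reads(reads$seq, k = k, min_count = 2, target_fpr = 1e-8)
  # every solid k-mer is present (no false negatives) ...
  expect_true(all(kmer_contains(bf, solid)))
  # ... and the filter holds exactly as many distinct k-mers
  expect_equal(kmer_index_info(bf)$n_inserted, length(solid))
  # non-solid (singleton) k-mers are absent at this FPR
  singles <- names(counts)[counts == 1]
  expect_false(any(kmer_contains(bf, head(singles, 500))))
})

test_that("assembly-mode construction inserts every k-mer, skipping N windows", {
  # a sequence of length k holds exactly one k-mer
  bf <- bloom_from_assembly("ACGTTGCA", k = 8)
  expect_equal(kmer_index_info(bf)$n_inserted, 1)
  expect_true(kmer_contains(bf, "ACGTTGCA"))

  # windows overlapping an N are skipped; count equals brute force
  s <- "ACGTTANCCGGTTA"
  k <- 4
  bf2 <- bloom_from_assembly(s, k = k)
  oracle <- unique(enumerate_kmers_r(s, k))
  expect_equal(kmer_index_info(bf2)$n_inserted, length(oracle))
  expect_true(all(kmer_contains(bf2, oracle)))

  # diploid input: union of both haplotypes' k-mers
  ref <- random_genome(300, seed = 7)
  hap2 <- ref
  substr(hap2[[1]], 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                         substring(ref[[1]], 150, 150))[1]
  bf3 <- bloom_from_assembly(c(h1 = unname(ref), h2 = unname(hap2)), k = 21)
  oracle3 <- unique(c(enumerate_kmers_r(ref[[1]], 21),
                      enumerate_kmers_r(hap2[[1]], 21)))
  expect_equal(kmer_index_info(bf3)$n_inserted, length(oracle3))
  expect_true(all(kmer_contains(bf3, oracle3)))

  expect_error(bloom_from_assembly(character(0), k = 5), "empty")
})

test_that("no false negatives and strand-invariant queries (property)", {
  for (seed in 1:5) {
    ref <- random_genome(2000, seed = seed)
    k <- 17
    bf <- bloom_from_assembly(ref, k = k, target_fpr = 0.01)
    kmers <- unique(enumerate_kmers_r(ref[[1]], k))
    expect_true(all(kmer_contains(bf, kmers)))
    # reverse-complement queries answer identically
    rcs <- vapply(sample(kmers, 50), rc_r, "", USE.NAMES = FALSE)
    expect_equal(kmer_contains(bf, rcs),
                 kmer_contains(bf, vapply(rcs, rc_r, "", USE.NAMES = FALSE)))
  }
})

test_that("measured FPR stays within 3x the theoretical rate", {
  ref <- random_genome(20000, seed = 31)
  k <- 21
  bf <- bloom_from_assembly(ref, k = k, target_fpr = 0.01)
  exact <- exact_kmer_set(ref, k = k)
  set.seed(32)
  probes <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, "")
  never_inserted <- !kmer_contains(exact, probes)
  measured <- mean(kmer_contains(bf, probes[never_inserted]))
  expect_lte(measured, 3 * bloom_fpr(bf))
})

test_that("reads-mode BF with min_count 1 on error-free 1x reads equals assembly mode", {
  ref <- random_genome(4000, seed = 55)
  k <- 19
  # tile the genome into non-overlapping, overlapping-by-(k-1) "reads" so
  # every genome k-mer is present exactly once
  L <- nchar(ref[[1]])
  starts <- unique(c(seq(1, L - 100 + 1, by = 100 - k + 1), L - 100 + 1))
  reads <- substring(ref[[1]], starts, starts + 99)
  bf_reads <- bloom_from_reads(reads, k = k, min_count = 1, target_fpr = 1e-4)
  bf_asm <- bloom_from_assembly(ref, k = k, target_fpr = 1e-4)
  genome_kmers <- unique(enumerate_kmers_r(ref[[1]], k))
  expect_equal(kmer_contains(bf_reads, genome_kmers),
               kmer_contains(bf_asm, genome_kmers))
  expect_true(all(kmer_contains(bf_reads, genome_kmers)))
})

test_that("Bloom filters round-trip through serialization", {
  ref <- random_genome(1500, seed = 77)
  bf <- bloom_from_assembly(ref, k = 21, target_fpr = 0.001)
  path <- withr::local_tempfile(fileext = ".bf")
  bloom_save(bf, path)
  bf2 <- bloom_load(path)
  expect_equal(kmer_index_info(bf2), kmer_index_info(bf))
  kmers <- unique(enumerate_kmers_r(ref[[1]], 21))
  expect_equal(kmer_contains(bf2, kmers), kmer_contains(bf, kmers))
  expect_error(bloom_load(withr::local_tempfile()), "not found")
})

test_that("the automatic solidity threshold lands above the error cluster", {
  ref <- random_genome(4000, seed = 91)
  donor <- c(hap1 = unname(ref), hap2 = unname(ref))
  reads <- simulate_reads(donor, coverage = 40, read_length = 80,
                          error_rate = 0.01, seed = 92)
  bf <- bloom_from_reads(reads$seq, k = 21)  # min_count = NULL -> auto
  expect_gte(bf$min_count, 2)
  # genome k-mers at 40x survive the threshold
  genome_kmers <- unique(enumerate_kmers_r(ref[[1]], 21))
  expect_gt(mean(kmer_contains(bf, genome_kmers)), 0.99)
})
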