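labels <- super_populations()

# build a records tibble from a matrix of per-label AFs
records_from_af <- function(af, chrom = "chr1", pos = NULL) {
  d <- tibble::tibble(chrom = chrom,
                      pos = if (is.null(pos)) seq_len(nrow(af)) * 100 else pos,
                      ref = "A", alt = "C")
  for (i in seq_along(labels)) d[[labels[i]]] <- af[, i]
  d
}

test_that("tile_genome partitions contigs without spanning them", {
  t1 <- tile_genome(c(chr1 = 12e6), tile_size = 5e6)
  expect_equal(t1$length, c(5e6, 5e6, 2e6))
  expect_equal(t1$start, c(0, 5e6, 10e6))

  t2 <- tile_genome(c(chr1 = 4e6), tile_size = 5e6)
  expect_equal(nrow(t2), 1)
  expect_equal(t2$length, 4e6)

  t3 <- tile_genome(c(a = 6e6, b = 6e6), tile_size = 5e6)
  expect_equal(nrow(t3), 4)
  expect_equal(t3$length, c(5e6, 1e6, 5e6, 1e6))
  expect_equal(t3$chrom, c("a", "a", "b", "b"))

  expect_error(tile_genome(c(chr1 = 100), tile_size = 0), "at least 1")
})

test_that("accumulate_af tallies AF sums, counts and non-zero counts per scope", {
  tiles <- tile_genome(c(chr1 = 1000), tile_size = 500)

  empty <- accumulate_af(records_from_af(matrix(0, 0, 5)), tiles)
  expect_true(all(empty$global$sum_af == 0) && all(empty$global$n == 0))
  expect_equal(nrow(empty$tile), 10)  # 2 tiles x 5 labels

  one <- accumulate_af(records_from_af(matrix(c(0.5, 0, 0, 0, 0), 1), pos = 100), tiles)
  g <- one$global
  expect_equal(g$sum_af[g$label == "EAS"], 0.5)
  expect_equal(g$nz_count[g$label == "EAS"], 1L)
  expect_equal(g$n, rep(1L, 5))
  expect_equal(g$total_nz, rep(1L, 5))

  # record outside every tile errors (reference/panel mismatch)
  bad <- records_from_af(matrix(0.5, 1, 5), pos = 2000)
  expect_error(accumulate_af(bad, tiles), "outside every tile")
})

test_that("tile accumulators match a brute-force re-summation and sum to the global", {
  set.seed(401)
  n <- 10000
  af <- matrix(runif(n * 5), n, 5) * rbinom(n * 5, 1, 0.6)
  pos <- sample.int(30000, n, replace = TRUE)
  recs <- records_from_af(af, pos = pos)
  tiles <- tile_genome(c(chr1 = 30000), tile_size = 10000)
  acc <- accumulate_af(recs, tiles)

  # brute-force per-record re-summation, one tile and label at a time
  for (tid in 1:3) {
    in_tile <- pos > (tid - 1) * 10000 & pos <= tid * 10000
    for (i in seq_along(labels)) {
      row <- acc$tile[acc$tile$tile_id == tid & acc$tile$label == labels[i], ]
      expect_equal(row$sum_af, sum(af[in_tile, i]))
      expect_equal(row$n, sum(in_tile))
      expect_equal(row$nz_count, sum(af[in_tile, i] > 0))
    }
    tile_rows <- acc$tile[acc$tile$tile_id == tid, ]
    expect_equal(tile_rows$total_nz[1], sum(rowSums(af[in_tile, ]) > 0))
  }

  # conservation: global equals the element-wise sum over tiles
  by_label <- dplyr::summarize(dplyr::group_by(acc$tile, label),
                               sum_af = sum(sum_af), n = sum(n),
                               nz_count = sum(nz_count),
                               total_nz = sum(total_nz))
  expect_equal(by_label$sum_af, acc$global$sum_af)
  expect_equal(by_label$n, acc$global$n)
  expect_equal(by_label$nz_count, acc$global$nz_count)
  expect_equal(by_label$total_nz, acc$global$total_nz)

  # record order changes nothing
  acc2 <- accumulate_af(recs[sample.int(n), ], tiles)
  expect_equal(acc2$tile, acc$tile)
  expect_equal(acc2$global, acc$global)
})

test_that("score_labels reproduces the hand-computed four-SNV example", {
  # 4 SNVs; EUR AFs (0.5, 0, 0.3, 0.2); AFR AFs (0.1, 0.2, 0, 0); others 0.
  # Every SNV is non-zero somewhere, so total_nz = 4.
  # EUR: mean 1.0/4 = 0.25, r_nz 3/4, s = 0.1875
  # AFR: mean 0.3/4 = 0.075, r_nz 2/4, s = 0.0375
  af <- cbind(EAS = 0, AFR = c(0.1, 0.2, 0, 0), EUR = c(0.5, 0, 0.3, 0.2),
              SAS = 0, AMR = 0)
  tiles <- tile_genome(c(chr1 = 1000), tile_size = 1000)
  scored <- score_labels(accumulate_af(records_from_af(af), tiles)$global)
  expect_equal(scored$af_mean[scored$label == "EUR"], 0.25)
  expect_equal(scored$r_nz[scored$label == "EUR"], 0.75)
  expect_equal(scored$s[scored$label == "EUR"], 0.1875)
  expect_equal(scored$af_mean[scored$label == "AFR"], 0.075)
  expect_equal(scored$r_nz[scored$label == "AFR"], 0.5)
  expect_equal(scored$s[scored$label == "AFR"], 0.0375)
  expect_equal(scored$s[scored$label %in% c("EAS", "SAS", "AMR")], rep(0, 3))

  # single dominant label: r_nz = 1 and s = af_mean; empty scope: all 0
  af1 <- cbind(EAS = c(0.4, 0.6), AFR = 0, EUR = 0, SAS = 0, AMR = 0)
  s1 <- score_labels(accumulate_af(records_from_af(af1), tiles)$global)
  expect_equal(s1$r_nz[s1$label == "EAS"], 1)
  expect_equal(s1$s[s1$label == "EAS"], s1$af_mean[s1$label == "EAS"])
  s0 <- score_labels(accumulate_af(records_from_af(af1[0, , drop = FALSE]), tiles)$global)
  expect_equal(s0$s, rep(0, 5))
})

test_that("scores stay in [0,1] under randomized accumulators (fuzz)", {
  set.seed(402)
  for (i in 1:1000) {
    n_rec <- sample.int(50, 1)
    af <- matrix(runif(n_rec * 5), n_rec, 5) *
      rbinom(n_rec * 5, 1, runif(1))
    acc <- tibble::tibble(
      label = factor(labels, levels = labels),
      sum_af = colSums(af),
      n = rep(n_rec, 5L),
      nz_count = as.integer(colSums(af > 0)),
      total_nz = as.integer(sum(rowSums(af) > 0))
    )
    s <- score_labels(acc)
    expect_true(all(s$s >= 0 & s$s <= 1))
    expect_true(all(s$af_mean >= 0 & s$af_mean <= 1))
    expect_true(all(s$r_nz >= 0 & s$r_nz <= 1))
  }
})

test_that("tile labels follow argmax with r_nz then label-order tie-breaks", {
  base <- tibble::tibble(tile_id = 1L, label = factor(labels, levels = labels),
                         sum_af = 0, n = 0L, nz_count = 0L, total_nz = 0L)
  sc <- function(s, r_nz = rep(0, 5)) {
    d <- base
    d$af_mean <- 0
    d$r_nz <- r_nz
    d$s <- s
    d
  }
  expect_equal(assign_tile_labels(sc(c(0.1, 0.2, 0.05, 0, 0)))$label, "AFR")
  a0 <- assign_tile_labels(sc(rep(0, 5)))
  expect_true(is.na(a0$label))
  # exact tie EAS = EUR, EUR has higher r_nz -> EUR, flagged ambiguous
  tie <- assign_tile_labels(sc(c(0.2, 0, 0.2, 0, 0), r_nz = c(0.4, 0, 0.6, 0, 0)))
  expect_equal(tie$label, "EUR")
  expect_true(tie$ambiguous)
  # full tie falls back to fixed label order
  tie2 <- assign_tile_labels(sc(c(0.2, 0, 0.2, 0, 0), r_nz = c(0.5, 0, 0.5, 0, 0)))
  expect_equal(tie2$label, "EAS")
  expect_true(tie2$ambiguous)
})

test_that("LAI fractions are length-weighted and sum to one", {
  tiles <- tile_genome(c(chr1 = 12e6), tile_size = 5e6)
  asg <- tibble::tibble(tile_id = 1:3, label = c("EUR", "EUR", "EAS"),
                        s = 0.1, ambiguous = FALSE)
  fr <- lai_fractions(asg, tiles)
  expect_equal(fr$lai_fraction[fr$label == "EUR"], 10 / 12)
  expect_equal(fr$lai_fraction[fr$label == "EAS"], 2 / 12)
  expect_equal(sum(fr$lai_fraction), 1, tolerance = 1e-9)

  asg$label <- "SAS"
  expect_equal(max(lai_fractions(asg, tiles)$lai_fraction), 1)

  # equal-length tiles split 50/50
  tiles2 <- tile_genome(c(chr1 = 10e6), tile_size = 5e6)
  asg2 <- tibble::tibble(tile_id = 1:2, label = c("AMR", "AFR"),
                         s = 0.1, ambiguous = FALSE)
  fr2 <- lai_fractions(asg2, tiles2)
  expect_equal(sort(fr2$lai_fraction[fr2$lai_fraction > 0]), c(0.5, 0.5))

  asg2$label <- NA_character_
  expect_error(lai_fractions(asg2, tiles2), "no tile")
})

test_that("Poisson multi-SNP probability matches the closed form", {
  # density 1/1000: ~4e-4 in 30 bp, ~2e-3 in 70 bp windows
  expect_equal(prob_multi_snp(1 / 1000, 30), 1 - exp(-0.03) * 1.03)
  expect_equal(signif(prob_multi_snp(1 / 1000, 30), 1), 4e-4)
  expect_equal(signif(prob_multi_snp(1 / 1000, 70), 1), 2e-3)
  expect_equal(prob_multi_snp(1 / 1000, 0), 0)
  expect_error(prob_multi_snp(-1, 10), "non-negative")
})

test_that("infer_ancestry reports are internally consistent and written as TSV", {
  set.seed(403)
  n <- 2000
  af <- matrix(runif(n * 5)^2, n, 5)
  af[, 3] <- af[, 3] + 0.2  # EUR-shifted
  recs <- records_from_af(af, pos = sample.int(12e6, n))
  rep <- infer_ancestry(recs, c(chr1 = 12e6), tile_size = 5e6)
  expect_s3_class(rep, "ancestry_report")
  expect_equal(rep$gai_label, "EUR")
  expect_equal(as.character(rep$global$label[rep$global$rank == 1]), "EUR")
  expect_equal(sum(rep$lai$lai_fraction), 1, tolerance = 1e-9)

  prefix <- file.path(withr::local_tempdir(), "donor")
  files <- write_ancestry_reports(rep, prefix)
  expect_equal(basename(files),
               c("donor_ancestry-predictions_tile5000000.tsv",
                 "donor_ancestry-predictions-tile-resolution_tile5000000.tsv"))
  f1 <- readr::read_tsv(files[1], show_col_types = FALSE)
  f2 <- readr::read_tsv(files[2], show_col_types = FALSE)
  expect_equal(nrow(f1), 5)   # one row per label
  expect_equal(nrow(f2), 3)   # 12 Mb / 5 Mb tiles
  # recomputing the length-weighted fractions from the tile file
  # reproduces the genome file's LAI_fraction column
  for (l in labels) {
    got <- f1$LAI_fraction[f1$label == l]
    want <- sum((f2$end - f2$start)[f2$assigned_label == l]) /
      sum((f2$end - f2$start)[f2$assigned_label != "unassigned"])
    expect_equal(got, want)
  }

  # tidy/glance/autoplot accessors
  expect_equal(nrow(tidy(rep)), 3)
  expect_equal(glance(rep)$gai_label, "EUR")
  expect_s3_class(autoplot(rep), "ggplot")
})
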