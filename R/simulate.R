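# Synthetic data: random references, Balding-Nichols differentiated
# allele-frequency panels, tile-mosaic admixed diploid donors, and
# error-bearing reads. Every generator takes an explicit seed and records
# the planted truth so recovery can be scored.

# Run code under a fixed seed without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Simulate a random reference genome
#'
#' Uniform-random A/C/G/T sequences, deterministic under `seed`.
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences.
#' @export
simulate_reference <- function(contig_lengths, seed = 1L) {
  stopifnot(is.numeric(contig_lengths), all(contig_lengths >= 1),
            !is.null(names(contig_lengths)))
  bases <- charToRaw("ACGT")
  local_seed(seed, {
    vapply(contig_lengths, function(len) {
      rawToChar(bases[sample.int(4L, len, replace = TRUE)])
    }, character(1))
  })
}

#' Simulate a population-differentiated allele-frequency panel
#'
#' Variant positions arise per base with probability `snv_density`; each
#' variant gets an ancestral frequency `p ~ Uniform(0.05, 0.95)` and one
#' allele frequency per super-population label drawn from the
#' Balding-Nichols model: `Beta(p (1-F)/F, (1-p)(1-F)/F)`, i.e. mean `p`
#' and variance `p (1-p) F`, where `F = fst` controls differentiation.
#' The alternate base is uniform over the three non-reference bases.
#' Variants below `af_threshold` in every label are dropped (counted in
#' attribute `n_dropped`), mirroring the panel admission rule.
#'
#' @param reference Named character vector (or `DNAStringSet`/path) of
#'   contigs.
#' @param snv_density Per-base variant probability (default 1/1000).
#' @param fst Differentiation parameter in (0, 1); 0 is accepted and
#'   makes all labels equal to the ancestral frequency.
#' @param af_threshold Panel admission threshold (default 0.01).
#' @param seed Integer seed.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, one AF column per
#'   label, and `p_ancestral`.
#' @export
simulate_panel <- function(reference, snv_density = 1 / 1000, fst = 0.15,
                           af_threshold = 0.01, seed = 1L) {
  stopifnot(snv_density > 0, snv_density <= 1, fst >= 0, fst < 1)
  seqs <- as_seq_vector(reference, "reference")
  labels <- super_populations()
  bases <- c("A", "C", "G", "T")
  local_seed(seed, {
    per_contig <- lapply(contig_names(seqs), function(chrom) {
      s <- seqs[[match(chrom, contig_names(seqs))]]
      len <- nchar(s)
      pos <- which(rbinom(len, 1L, snv_density) == 1L)
      if (length(pos) == 0) return(NULL)
      ref <- substring(s, pos, pos)
      ok <- ref %in% bases
      pos <- pos[ok]
      ref <- ref[ok]
      alt_choice <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                           character(1), USE.NAMES = FALSE)
      tibble::tibble(chrom = chrom, pos = as.numeric(pos), ref = ref,
                     alt = alt_choice)
    })
    panel <- dplyr::bind_rows(per_contig)
    n <- nrow(panel)
    p <- runif(n, 0.05, 0.95)
    for (l in labels) {
      panel[[l]] <- if (fst < 1e-12) p else
        rbeta(n, p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
    }
    panel$p_ancestral <- p
    keep <- do.call(pmax, panel[labels]) >= af_threshold
    out <- panel[keep, , drop = FALSE]
    attr(out, "n_dropped") <- sum(!keep)
    out
  })
}

#' Build a tile mosaic of source labels
#'
#' Assigns one super-population source label to each genomic tile, the
#' map used by [simulate_individual()] to emulate an admixed donor.
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param tile_size Tile size in bases.
#' @param labels Either a character vector with one label per tile, or a
#'   named numeric vector of proportions (e.g. `c(EUR = 0.7, EAS = 0.3)`)
#'   converted to contiguous blocks of tiles in genome order.
#' @return The tile tibble of [tile_genome()] with a `label` column.
#' @export
tile_mosaic <- function(contig_lengths, tile_size, labels) {
  tiles <- tile_genome(contig_lengths, tile_size)
  n <- nrow(tiles)
  if (!is.null(names(labels)) && is.numeric(labels)) {
    stopifnot(all(names(labels) %in% super_populations()), all(labels >= 0))
    counts <- round(labels / sum(labels) * n)
    # rounding drift goes to the largest block
    counts[which.max(counts)] <- counts[which.max(counts)] + (n - sum(counts))
    lab <- rep(names(labels), times = counts)
  } else {
    stopifnot(is.character(labels), length(labels) %in% c(1L, n),
              all(labels %in% super_populations()))
    lab <- rep(labels, length.out = n)
  }
  tiles$label <- lab
  tiles
}

#' Simulate an admixed diploid donor
#'
#' For each panel variant falling in a tile with source label `L`, the
#' donor genotype is two Bernoulli(`AF_L`) draws (one per haplotype);
#' alternate alleles are substituted into the two haplotype copies of the
#' reference. The planted truth (every non-reference genotype) and the
#' mosaic are returned with the sequences.
#'
#' @param reference Named character vector (or `DNAStringSet`/path).
#' @param panel Panel tibble from [simulate_panel()] or [load_panel()].
#' @param mosaic Tile tibble with a `label` column, from [tile_mosaic()].
#' @param seed Integer seed.
#' @return A list with `haplotypes` (named character vector,
#'   `<chrom>_hap1` / `<chrom>_hap2`), `truth` (tibble `chrom`, `pos`,
#'   `ref`, `alt`, `genotype` in `het`/`hom`), and `mosaic`.
#' @export
simulate_individual <- function(reference, panel, mosaic, seed = 1L) {
  seqs <- as_seq_vector(reference, "reference")
  labels <- super_populations()
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(mosaic)),
            all(mosaic$label %in% labels),
            all(c("chrom", "pos", "ref", "alt", labels) %in% names(panel)))
  if (!"tile_id" %in% names(mosaic)) mosaic$tile_id <- seq_len(nrow(mosaic))

  p <- panel
  p$.tile <- assign_tiles(p, mosaic)
  p$.src <- mosaic$label[match(p$.tile, mosaic$tile_id)]
  p$.af <- as.matrix(p[labels])[cbind(seq_len(nrow(p)), match(p$.src, labels))]

  local_seed(seed, {
    g1 <- rbinom(nrow(p), 1L, p$.af)
    g2 <- rbinom(nrow(p), 1L, p$.af)
    haps <- list()
    for (chrom in contig_names(seqs)) {
      s <- Biostrings::DNAString(seqs[[match(chrom, contig_names(seqs))]])
      for (h in 1:2) {
        g <- if (h == 1) g1 else g2
        rows <- which(p$chrom == chrom & g == 1L)
        hap <- if (length(rows) > 0) {
          Biostrings::replaceLetterAt(s, at = as.integer(p$pos[rows]),
                                      letter = paste(p$alt[rows], collapse = ""))
        } else s
        haps[[paste0(chrom, "_hap", h)]] <- as.character(hap)
      }
    }
    truth <- tibble::tibble(
      chrom = p$chrom, pos = p$pos, ref = p$ref, alt = p$alt,
      genotype = c(NA, "het", "hom")[g1 + g2 + 1L]
    )
    truth <- truth[!is.na(truth$genotype), , drop = FALSE]
    list(haplotypes = unlist(haps), truth = truth, mosaic = mosaic)
  })
}

#' Simulate whole-genome sequencing reads
#'
#' Reads of fixed length start uniformly over both haplotypes (weighted
#' by usable length) until the total base count reaches
#' `coverage x haploid genome length`; each base is substituted
#' independently at `error_rate` with a uniform choice among the three
#' other bases. No indels, quality trends, or GC bias are modelled.
#'
#' @param haplotypes Named character vector of haplotype sequences (two
#'   per contig for a diploid donor).
#' @param coverage Haploid-genome fold coverage (default 30).
#' @param read_length Read length in bases (default 100).
#' @param error_rate Per-base substitution error probability
#'   (default 0.005).
#' @param seed Integer seed.
#' @return A tibble with `read_id`, `hap` (source haplotype name),
#'   `start` (1-based start on the haplotype) and `seq`.
#' @export
simulate_reads <- function(haplotypes, coverage = 30, read_length = 100L,
                           error_rate = 0.005, seed = 1L) {
  haps <- as_seq_vector(haplotypes, "haplotypes")
  read_length <- as.integer(read_length)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  hap_len <- nchar(haps)
  if (any(hap_len < read_length)) {
    stop("read_length exceeds a haplotype length", call. = FALSE)
  }
  haploid_len <- sum(hap_len) / 2
  n_reads <- max(1L, as.integer(round(coverage * haploid_len / read_length)))
  usable <- hap_len - read_length + 1
  bases <- c("A", "C", "G", "T")

  local_seed(seed, {
    hi <- sample.int(length(haps), n_reads, replace = TRUE,
                     prob = usable / sum(usable))
    start <- floor(runif(n_reads, min = 1, max = usable[hi] + 1))
    reads <- substring(unname(haps)[hi], start, start + read_length - 1L)

    n_err <- rbinom(n_reads, read_length, error_rate)
    if (any(n_err > 0)) {
      err_read <- rep(which(n_err > 0), n_err[n_err > 0])
      err_pos <- floor(runif(length(err_read), min = 1, max = read_length + 1))
      # several errors in one read are applied in successive rounds so the
      # vectorized substr<- never writes one string twice in a round
      df <- data.frame(read = err_read, pos = err_pos)
      df$round <- stats::ave(df$read, df$read, FUN = seq_along)
      for (r in seq_len(max(df$round))) {
        d <- df[df$round == r, ]
        cur <- substr(reads[d$read], d$pos, d$pos)
        shift <- sample.int(3L, nrow(d), replace = TRUE)
        newb <- bases[(match(cur, bases) - 1L + shift) %% 4L + 1L]
        substr(reads[d$read], d$pos, d$pos) <- newb
      }
    }
    tibble::tibble(
      read_id = sprintf("read%07d", seq_len(n_reads)),
      hap = names(haps)[hi],
      start = start,
      seq = reads
    )
  })
}
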