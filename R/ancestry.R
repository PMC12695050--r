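# Ancestry scoring: per-label mean allele frequency, non-zero rate, and
# their product S, computed genome-wide and per genomic tile; tile label
# assignment and length-weighted local-ancestry fractions.

#' Partition contigs into fixed-size tiles
#'
#' Tiles never span contigs; the last tile of each contig takes the
#' remainder, so tile lengths are used (not assumed) downstream.
#'
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param tile_size Tile size in bases (default 5,000,000).
#' @return A tibble with `tile_id`, `chrom`, `start` (0-based), `end`
#'   (exclusive) and `length`.
#' @export
#' @examples
#' tile_genome(c(chr1 = 12e6), tile_size = 5e6)
tile_genome <- function(contig_lengths, tile_size = 5e6) {
  if (!is.numeric(tile_size) || length(tile_size) != 1 || tile_size < 1) {
    stop("tile_size must be at least 1", call. = FALSE)
  }
  stopifnot(is.numeric(contig_lengths), !is.null(names(contig_lengths)),
            all(contig_lengths >= 1))
  per_contig <- lapply(names(contig_lengths), function(chrom) {
    len <- contig_lengths[[chrom]]
    starts <- seq(0, len - 1, by = tile_size)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + tile_size, len))
  })
  tiles <- dplyr::bind_rows(per_contig)
  tiles$tile_id <- seq_len(nrow(tiles))
  tiles$length <- tiles$end - tiles$start
  tiles[, c("tile_id", "chrom", "start", "end", "length")]
}

# Map each record to the tile containing it; errors on records outside
# every tile (a reference/panel contig mismatch).
assign_tiles <- function(records, tiles) {
  tile_id <- rep(NA_integer_, nrow(records))
  for (chrom in unique(records$chrom)) {
    ri <- which(records$chrom == chrom)
    tt <- tiles[tiles$chrom == chrom, ]
    if (nrow(tt) == 0) next
    # records are 1-based; tiles are 0-based half-open
    ti <- findInterval(records$pos[ri] - 1, tt$start)
    ok <- ti >= 1 & records$pos[ri] <= tt$end[pmax(ti, 1)]
    tile_id[ri[ok]] <- tt$tile_id[ti[ok]]
  }
  if (anyNA(tile_id)) {
    bad <- records[which(is.na(tile_id))[1], ]
    stop("cross-referenced SNV at ", bad$chrom, ":", bad$pos,
         " falls outside every tile; reference and panel likely disagree",
         call. = FALSE)
  }
  tile_id
}

#' Accumulate per-label allele-frequency tallies
#'
#' For each cross-referenced SNV, its full five-label allele-frequency
#' vector contributes to the accumulator of the tile containing it and to
#' the global accumulator: the running AF sum and count per label, the
#' per-label count of SNVs with non-zero AF, and the scope-level count of
#' SNVs with non-zero AF in at least one label (`total_nz`).
#'
#' @param records Cross-referenced SNVs from [cross_reference()].
#' @param tiles Tile tibble from [tile_genome()].
#' @return A list with `global` (one row per label: `label`, `sum_af`,
#'   `n`, `nz_count`, `total_nz`) and `tile` (the same per tile, all
#'   tiles represented, zero rows filled in).
#' @export
accumulate_af <- function(records, tiles) {
  labels <- super_populations()
  stopifnot(all(labels %in% names(records)) || nrow(records) == 0)

  empty <- tibble::tibble(label = factor(labels, levels = labels),
                          sum_af = 0, n = 0L, nz_count = 0L, total_nz = 0L)
  if (nrow(records) == 0) {
    tile_acc <- tidyr::crossing(tiles["tile_id"], empty)
    return(list(global = empty, tile = tile_acc))
  }

  records$tile_id <- assign_tiles(records, tiles)
  records$.nz_any <- rowSums(as.matrix(records[labels]) > 0) > 0

  long <- tidyr::pivot_longer(
    records[, c("tile_id", ".nz_any", labels)],
    cols = dplyr::all_of(labels), names_to = "label", values_to = "af"
  )
  long$label <- factor(long$label, levels = labels)

  # Grouping the long form by label puts each record exactly once in each
  # group, so per-group tallies are per-scope record tallies.
  summarize_scope <- function(d, ...) {
    dplyr::summarize(dplyr::group_by(d, ..., .data$label),
                     sum_af = sum(.data$af),
                     n = dplyr::n(),
                     nz_count = as.integer(sum(.data$af > 0)),
                     total_nz = as.integer(sum(.data$.nz_any)),
                     .groups = "drop")
  }
  global <- summarize_scope(long)
  tile_acc <- summarize_scope(long, .data$tile_id)
  tile_acc <- tidyr::complete(tile_acc, tile_id = tiles$tile_id,
                              label = factor(labels, levels = labels),
                              fill = list(sum_af = 0, n = 0L, nz_count = 0L,
                                          total_nz = 0L))
  list(global = global, tile = dplyr::arrange(tile_acc, .data$tile_id, .data$label))
}

#' Score super-population labels from an accumulator
#'
#' Adds, per label and scope: the mean allele frequency over all SNVs in
#' scope (`af_mean`, 0 when the scope is empty), the non-zero rate
#' (`r_nz` = non-zero AF SNV count for the label / count of SNVs with
#' non-zero AF in any label, 0 when the denominator is 0), and the
#' combined score `s = af_mean * r_nz`. All three lie in \[0, 1\].
#'
#' @param acc An accumulator tibble (`global` or `tile` element of
#'   [accumulate_af()]).
#' @return The input with `af_mean`, `r_nz` and `s` columns appended.
#' @export
score_labels <- function(acc) {
  stopifnot(all(c("label", "sum_af", "n", "nz_count", "total_nz") %in% names(acc)))
  dplyr::mutate(acc,
                af_mean = ifelse(.data$n > 0, .data$sum_af / .data$n, 0),
                r_nz = ifelse(.data$total_nz > 0,
                              .data$nz_count / .data$total_nz, 0),
                s = .data$af_mean * .data$r_nz)
}

#' Assign a super-population label to each tile
#'
#' The label with the highest score `s` wins; ties are broken by higher
#' `r_nz`, then by the fixed label order of [super_populations()], and
#' tied tiles are flagged ambiguous. Tiles whose scores are all zero are
#' left unassigned (`NA`).
#'
#' @param tile_scores Scored tile accumulator from [score_labels()].
#' @return A tibble with one row per tile: `tile_id`, `label` (character
#'   or `NA`), `s`, `ambiguous`.
#' @export
assign_tile_labels <- function(tile_scores) {
  labels <- super_populations()
  picked <- tile_scores |>
    dplyr::mutate(.ord = match(as.character(.data$label), labels)) |>
    dplyr::group_by(.data$tile_id) |>
    dplyr::arrange(dplyr::desc(.data$s), dplyr::desc(.data$r_nz), .data$.ord,
                   .by_group = TRUE) |>
    dplyr::summarize(
      label = ifelse(max(.data$s) == 0, NA_character_,
                     as.character(.data$label[1])),
      ambiguous = max(.data$s) > 0 & sum(.data$s == max(.data$s)) > 1,
      s = .data$s[1],
      .groups = "drop"
    )
  picked
}

#' Length-weighted local-ancestry fractions
#'
#' The fraction for a label is the total length of tiles assigned that
#' label divided by the total length of all assigned tiles, so fractions
#' account for actual tile lengths and sum to 1 over labels. Unassigned
#' tiles are excluded from numerator and denominator.
#'
#' @param tile_labels Assignment tibble from [assign_tile_labels()].
#' @param tiles Tile tibble from [tile_genome()] (for tile lengths).
#' @return A tibble with one row per label: `label`, `length`,
#'   `lai_fraction`.
#' @export
lai_fractions <- function(tile_labels, tiles) {
  labels <- super_populations()
  d <- dplyr::inner_join(tile_labels, tiles[, c("tile_id", "length")],
                         by = "tile_id")
  d <- d[!is.na(d$label), ]
  if (nrow(d) == 0) stop("no tile received a label; cannot compute ancestry fractions",
                         call. = FALSE)
  out <- d |>
    dplyr::group_by(label = factor(.data$label, levels = labels)) |>
    dplyr::summarize(length = sum(.data$length), .groups = "drop") |>
    tidyr::complete(label = factor(labels, levels = labels),
                    fill = list(length = 0))
  out$lai_fraction <- out$length / sum(out$length)
  out
}

#' Probability of two or more SNPs in a window
#'
#' Under a Poisson model for SNP occurrence at the given per-base
#' density, returns \eqn{P(X \ge 2)} for \eqn{X \sim
#' Poisson(\lambda = density \times window)}, i.e.
#' \eqn{1 - e^{-\lambda}(1 + \lambda)}. Because the caller substitutes
#' one base at a time at the 3' end of each k-mer, two or more true SNPs
#' within the same k-base window can be missed; at the human SNP density
#' of about 1 per 1000 bases this stays small for the window sizes the
#' caller uses.
#'
#' @param density Expected SNPs per base (e.g. `1/1000`).
#' @param window Window width in bases (e.g. the k-mer length).
#' @return The probability of two or more SNPs in the window.
#' @export
#' @examples
#' prob_multi_snp(1 / 1000, 30)
#' prob_multi_snp(1 / 1000, 70)
prob_multi_snp <- function(density, window) {
  if (!is.numeric(density) || any(density < 0)) {
    stop("density must be non-negative", call. = FALSE)
  }
  if (!is.numeric(window) || any(window < 0)) {
    stop("window must be non-negative", call. = FALSE)
  }
  stats::ppois(1, lambda = density * window, lower.tail = FALSE)
}
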