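# The ancestry_report object: global + per-tile label scores, tile label
# assignments, local-ancestry fractions, and the TSV report writers.

#' Infer global and local ancestry from cross-referenced SNVs
#'
#' Runs the full scoring stage: tiles the genome, accumulates per-label
#' allele-frequency tallies globally and per tile, scores every label
#' (`s = af_mean * r_nz`), assigns each tile its top-scoring label, and
#' computes length-weighted local-ancestry fractions. The global ancestry
#' call (GAI) is the top-ranked label of the genome-wide score; the
#' majority local label is reported alongside for comparison.
#'
#' @param records Cross-referenced SNVs from [cross_reference()].
#' @param contig_lengths Named numeric vector of reference contig lengths.
#' @param tile_size Tile size in bases (default 5,000,000).
#' @return An `ancestry_report` object: a list with
#'   \describe{
#'     \item{global}{per-label genome-wide tibble with `af_mean`, `r_nz`,
#'       `s`, `rank` and `lai_fraction`,}
#'     \item{tiles}{per-tile tibble (coordinates, assigned `label`,
#'       `ambiguous`, and the five per-label scores `s_EAS` ... `s_AMR`),}
#'     \item{tile_scores}{the long per-tile scored accumulator,}
#'     \item{lai}{per-label length-weighted fractions,}
#'     \item{gai_label, lai_majority_label}{the two headline labels,}
#'     \item{n_records, n_tiles, n_unassigned, tile_size}{bookkeeping.}
#'   }
#' @export
infer_ancestry <- function(records, contig_lengths, tile_size = 5e6) {
  tiles <- tile_genome(contig_lengths, tile_size)
  acc <- accumulate_af(records, tiles)
  global <- score_labels(acc$global)
  tile_scores <- score_labels(acc$tile)
  assignment <- assign_tile_labels(tile_scores)
  lai <- lai_fractions(assignment, tiles)

  global <- global |>
    dplyr::arrange(dplyr::desc(.data$s), dplyr::desc(.data$r_nz)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::left_join(lai[, c("label", "lai_fraction")], by = "label") |>
    dplyr::arrange(.data$rank)

  wide_scores <- tile_scores |>
    dplyr::select("tile_id", "label", "s") |>
    tidyr::pivot_wider(names_from = "label", values_from = "s",
                       names_prefix = "s_")
  tiles_out <- tiles |>
    dplyr::left_join(assignment[, c("tile_id", "label", "ambiguous")],
                     by = "tile_id") |>
    dplyr::left_join(wide_scores, by = "tile_id")

  majority <- as.character(lai$label[which.max(lai$lai_fraction)])
  structure(list(
    global = global,
    tiles = tiles_out,
    tile_scores = tile_scores,
    lai = lai,
    gai_label = as.character(global$label[global$rank == 1]),
    lai_majority_label = majority,
    n_records = nrow(records),
    n_tiles = nrow(tiles),
    n_unassigned = sum(is.na(tiles_out$label)),
    tile_size = tile_size
  ), class = "ancestry_report")
}

#' @export
print.ancestry_report <- function(x, ...) {
  cat(sprintf("<ancestry_report> %d cross-referenced SNVs, %d tiles (%d unassigned), tile size %s bp\n",
              x$n_records, x$n_tiles, x$n_unassigned,
              format(x$tile_size, big.mark = ",", scientific = FALSE)))
  cat(sprintf("Global ancestry (GAI): %s; majority local label: %s\n",
              x$gai_label, x$lai_majority_label))
  print(x$global, ...)
  invisible(x)
}

#' Tidy a fitted ancestry report
#'
#' @param x An `ancestry_report`.
#' @param ... Unused.
#' @return One row per tile: coordinates, assigned label, ambiguity flag
#'   and the five per-label scores.
#' @export
tidy.ancestry_report <- function(x, ...) {
  x$tiles
}

#' One-row summary of an ancestry report
#'
#' @param x An `ancestry_report`.
#' @param ... Unused.
#' @return A one-row tibble: GAI label and score, majority local label,
#'   its fraction, and counts.
#' @export
glance.ancestry_report <- function(x, ...) {
  top <- x$global[x$global$rank == 1, ]
  tibble::tibble(
    gai_label = x$gai_label,
    gai_s = top$s,
    gai_af_mean = top$af_mean,
    gai_r_nz = top$r_nz,
    lai_majority_label = x$lai_majority_label,
    lai_majority_fraction = max(x$lai$lai_fraction),
    n_records = x$n_records,
    n_tiles = x$n_tiles,
    n_unassigned = x$n_unassigned
  )
}

#' Plot local ancestry assignments along the genome
#'
#' One horizontal track per contig, tiles coloured by their assigned
#' super-population label (grey when unassigned).
#'
#' @param object An `ancestry_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ancestry_report <- function(object, ...) {
  d <- object$tiles
  d$label <- factor(ifelse(is.na(d$label), "unassigned", d$label),
                    levels = c(super_populations(), "unassigned"))
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                  ymin = 0, ymax = 1, fill = .data$label)) +
    ggplot2::geom_rect(colour = "white", linewidth = 0.1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom), switch = "y") +
    ggplot2::scale_fill_manual(
      values = c(EAS = "#d62728", AFR = "#ff7f0e", EUR = "#2ca02c",
                 SAS = "#1f77b4", AMR = "#2c2c2c", unassigned = "grey85"),
      drop = FALSE, name = "label") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Local ancestry assignments") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ancestry_report
#' @param report An `ancestry_report`.
#' @export
plot_lai <- function(report) {
  autoplot.ancestry_report(report)
}

#' Write ancestry TSV reports
#'
#' Writes the genome-level report
#' `<prefix>_ancestry-predictions_tile<tile size>.tsv` (one row per
#' label: global score, mean AF, non-zero rate, local-ancestry fraction,
#' rank) and, when `lai = TRUE`, the per-tile report
#' `<prefix>_ancestry-predictions-tile-resolution_tile<tile size>.tsv`
#' (one row per tile: coordinates, assigned label, ambiguity flag, and
#' the five per-label scores).
#'
#' @param report An `ancestry_report` from [infer_ancestry()].
#' @param prefix Output path prefix.
#' @param lai Also write the tile-resolution report? Default `TRUE`.
#' @return Character vector of the file(s) written, invisibly.
#' @export
write_ancestry_reports <- function(report, prefix, lai = TRUE) {
  stopifnot(inherits(report, "ancestry_report"))
  tile_tag <- format(report$tile_size, scientific = FALSE, trim = TRUE)
  f1 <- paste0(prefix, "_ancestry-predictions_tile", tile_tag, ".tsv")
  g <- report$global
  readr::write_tsv(tibble::tibble(
    label = as.character(g$label),
    global_S = g$s,
    global_AF_mean = g$af_mean,
    global_Rnz = g$r_nz,
    LAI_fraction = ifelse(is.na(g$lai_fraction), 0, g$lai_fraction),
    rank = g$rank
  ), f1)
  written <- f1
  if (lai) {
    f2 <- paste0(prefix, "_ancestry-predictions-tile-resolution_tile",
                 tile_tag, ".tsv")
    t <- report$tiles
    readr::write_tsv(tibble::tibble(
      chrom = t$chrom,
      start = t$start,
      end = t$end,
      assigned_label = ifelse(is.na(t$label), "unassigned", t$label),
      ambiguous = ifelse(is.na(t$ambiguous), FALSE, t$ambiguous),
      t[, paste0("s_", super_populations())]
    ), f2)
    written <- c(written, f2)
  }
  invisible(written)
}
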