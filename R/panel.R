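# Loading a super-population allele-frequency panel and cross-referencing
# SNV calls against it.

#' Load a super-population allele-frequency panel from VCF
#'
#' Reads a 1000-Genomes-style integrated-variant-call VCF whose INFO
#' field carries one allele-frequency key per super-population label,
#' splits multi-allelic records per ALT, drops non-SNV alternates, and
#' keeps only variants with an allele frequency of at least
#' `af_threshold` (default 1%) in at least one super-population. Missing
#' AF values (`"."`) are treated as 0. Duplicate (chrom, pos, ref, alt)
#' lines keep the last occurrence, with a warning.
#'
#' @param vcf Path to the panel VCF (plain or gzipped).
#' @param af_threshold Minimum allele frequency in at least one label for
#'   a variant to be admitted (default 0.01).
#' @param af_keys Named character vector mapping each label in
#'   [super_populations()] to its INFO key. Defaults to the 1kGP
#'   convention (`EAS_AF`, `AFR_AF`, `EUR_AF`, `SAS_AF`, `AMR_AF`);
#'   override for gnomAD-style panels.
#' @param chrom_style Chromosome-name normalization: `"asis"` keeps names
#'   unchanged, `"strip"` removes a leading `"chr"`, `"add"` prepends
#'   `"chr"` where absent. Use to match the reference naming.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt` and one AF column
#'   per label, named by the label. Attribute `af_threshold` records the
#'   admission threshold.
#' @export
load_panel <- function(vcf, af_threshold = 0.01,
                       af_keys = NULL,
                       chrom_style = c("asis", "strip", "add")) {
  chrom_style <- match.arg(chrom_style)
  labels <- super_populations()
  if (is.null(af_keys)) af_keys <- setNames(paste0(labels, "_AF"), labels)
  stopifnot(all(labels %in% names(af_keys)))
  if (!file.exists(vcf)) stop("panel VCF not found: '", vcf, "'", call. = FALSE)
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  for (key in af_keys[labels]) {
    if (!any(grepl(paste0("ID=", key, ","), v@meta, fixed = TRUE))) {
      stop("panel VCF lacks required INFO key '", key, "'", call. = FALSE)
    }
  }
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(v@fix) == 0) {
    out <- tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character())
    for (l in labels) out[[l]] <- numeric()
    attr(out, "af_threshold") <- af_threshold
    return(out)
  }

  # Number=A keys: one comma-separated value per ALT allele.
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_rank <- sequence(n_alt)

  af_slice <- function(key) {
    raw <- vcfR::extract.info(v, element = key)
    parts <- strsplit(ifelse(is.na(raw), "", raw), ",", fixed = TRUE)
    vals <- suppressWarnings(as.numeric(unlist(lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      length(p) <- n_alt[i]  # pad short slices with NA
      p
    }))))
    vals[is.na(vals)] <- 0  # "." and absent slices count as frequency 0
    vals
  }

  out <- tibble::tibble(
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_list)
  )
  for (l in labels) out[[l]] <- af_slice(af_keys[[l]])

  out$chrom <- normalize_chrom(out$chrom, chrom_style)
  out <- dplyr::filter(out, .data$ref %in% c("A", "C", "G", "T"),
                       .data$alt %in% c("A", "C", "G", "T"))
  keep <- do.call(pmax, c(out[labels], na.rm = TRUE)) >= af_threshold
  out <- out[keep, , drop = FALSE]

  key <- paste(out$chrom, out$pos, out$ref, out$alt)
  if (anyDuplicated(key)) {
    warning("panel has duplicate (chrom, pos, ref, alt) entries; keeping the last",
            call. = FALSE)
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  attr(out, "af_threshold") <- af_threshold
  out
}

normalize_chrom <- function(chrom, style) {
  switch(style,
         asis = chrom,
         strip = sub("^chr", "", chrom),
         add = ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom)))
}

#' Cross-reference SNV calls against a panel
#'
#' A call matches a panel variant when chromosome, position, reference
#' allele and alternate allele all agree; matching rows gain the panel's
#' five per-label allele frequencies. Unmatched calls are excluded from
#' scoring but counted (attributes `n_calls`, `n_matched`,
#' `n_unmatched`). Call order is preserved.
#'
#' @param calls Tibble of calls (from [call_snvs()] or [read_snv_vcf()]).
#' @param panel Panel tibble from [load_panel()] or [simulate_panel()].
#' @return Tibble of matched calls with the label AF columns appended.
#' @export
cross_reference <- function(calls, panel) {
  labels <- super_populations()
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(calls)),
            all(c("chrom", "pos", "ref", "alt", labels) %in% names(panel)))
  records <- dplyr::inner_join(
    calls, panel[, c("chrom", "pos", "ref", "alt", labels)],
    by = c("chrom", "pos", "ref", "alt")
  )
  attr(records, "n_calls") <- nrow(calls)
  attr(records, "n_matched") <- nrow(records)
  attr(records, "n_unmatched") <- nrow(calls) - nrow(records)
  records
}
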