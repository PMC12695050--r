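# VCF output for SNV calls and panel simulation, plus a reader for
# re-ingesting caller (or third-party) VCFs. Reading goes through vcfR;
# writing is plain VCFv4.2 line formatting.

vcf_header_lines <- function(contig_lengths, info_lines, source = "rootstock") {
  c("##fileformat=VCFv4.2",
    paste0("##source=", source),
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    info_lines,
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
}

#' Write SNV calls to a VCF file
#'
#' Emits VCFv4.2 with contig header lines and one record per call. The
#' INFO field carries `KSF` (alternate-base support fraction), `RSF`
#' (reference-base support fraction) and `NQ` (number of k-mers queried);
#' calls flagged in `panel_flag` additionally carry the `PANEL` flag,
#' marking concordance with the allele-frequency panel.
#'
#' @param calls A tibble of calls as returned by [call_snvs()].
#' @param contig_lengths Named vector of contig lengths (header lines).
#' @param path Output path.
#' @param panel_flag Optional logical vector along `calls`: `TRUE` rows
#'   are annotated with the `PANEL` INFO flag.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(calls, contig_lengths, path, panel_flag = NULL) {
  stopifnot(is.data.frame(calls))
  info_lines <- c(
    '##INFO=<ID=KSF,Number=1,Type=Float,Description="Alternate-base k-mer support fraction">',
    '##INFO=<ID=RSF,Number=1,Type=Float,Description="Reference-base k-mer support fraction">',
    '##INFO=<ID=NQ,Number=1,Type=Integer,Description="Number of k-mers queried">',
    '##INFO=<ID=PANEL,Number=0,Type=Flag,Description="Concordant with the allele-frequency panel">'
  )
  header <- vcf_header_lines(contig_lengths, info_lines)
  body <- character(0)
  if (nrow(calls) > 0) {
    info <- sprintf("KSF=%.6g;RSF=%.6g;NQ=%d", calls$ksf, calls$rsf, calls$nq)
    if (!is.null(panel_flag)) {
      stopifnot(length(panel_flag) == nrow(calls))
      info <- ifelse(panel_flag, paste0(info, ";PANEL"), info)
    }
    body <- paste(calls$chrom, format(calls$pos, scientific = FALSE, trim = TRUE),
                  ".", calls$ref, calls$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SNVs from a VCF file
#'
#' Reads a caller output VCF (or any third-party single-sample VCF) back
#' into the tibble shape used by the scoring stages. Multi-allelic
#' records are split per ALT; non-SNV ALTs are dropped. The caller's
#' `KSF`/`RSF`/`NQ` INFO keys are recovered when present, `NA` otherwise.
#'
#' @param path VCF path (plain or gzipped).
#' @return A tibble with `chrom`, `pos`, `ref`, `alt` and, when present,
#'   `ksf`, `rsf`, `nq`.
#' @export
read_snv_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: '", path, "'", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)) || nrow(vcf@fix) == 0) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          ref = character(), alt = character(),
                          ksf = numeric(), rsf = numeric(), nq = integer()))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  has_info <- function(key) any(grepl(paste0("ID=", key, ","), vcf@meta, fixed = TRUE))
  get_info <- function(key, as) {
    if (!has_info(key)) return(rep(NA, nrow(fix)))
    suppressWarnings(vcfR::extract.info(vcf, element = key, as.numeric = as))
  }
  ksf <- as.numeric(get_info("KSF", TRUE))
  rsf <- as.numeric(get_info("RSF", TRUE))
  nq <- as.integer(get_info("NQ", TRUE))
  alt_list <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- tibble::tibble(
    chrom = fix$CHROM[idx],
    pos = as.numeric(fix$POS[idx]),
    ref = fix$REF[idx],
    alt = unlist(alt_list),
    ksf = ksf[idx], rsf = rsf[idx], nq = nq[idx]
  )
  dplyr::filter(out, .data$ref %in% c("A", "C", "G", "T"),
                .data$alt %in% c("A", "C", "G", "T"))
}

#' Write an allele-frequency panel to VCF
#'
#' Writes a panel tibble (one row per SNV with the five per-label allele
#' frequencies) as a VCF whose INFO field carries one `<label>_AF` key
#' per super-population, following the 1000 Genomes integrated-call
#' convention.
#'
#' @param panel Tibble with `chrom`, `pos`, `ref`, `alt` and one column
#'   per label in [super_populations()].
#' @param contig_lengths Named vector of contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, contig_lengths, path) {
  labels <- super_populations()
  stopifnot(all(c("chrom", "pos", "ref", "alt", labels) %in% names(panel)))
  info_lines <- sprintf(
    '##INFO=<ID=%s_AF,Number=A,Type=Float,Description="Allele frequency in the %s super-population">',
    labels, labels)
  header <- vcf_header_lines(contig_lengths, info_lines)
  body <- character(0)
  if (nrow(panel) > 0) {
    info <- do.call(paste, c(lapply(labels, function(l) {
      sprintf("%s_AF=%.6g", l, panel[[l]])
    }), sep = ";"))
    body <- paste(panel$chrom, format(panel$pos, scientific = FALSE, trim = TRUE),
                  ".", panel$ref, panel$alt, ".", "PASS", info, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
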