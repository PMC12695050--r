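# In-process pipeline driver: build k-mer index -> call SNVs ->
# cross-reference against the panel -> score ancestry -> write outputs.

#' Run the full ancestry-inference pipeline
#'
#' Replicates the end-to-end flow in one process. In `"reads"` mode a
#' Bloom filter of solid read k-mers is built first; in `"genome"` mode
#' every assembly k-mer is inserted; in `"vcf"` mode SNV calling is
#' skipped and a pre-computed VCF of SNVs is scored directly. Writes the
#' calls VCF (not in `"vcf"` mode), a panel-annotated VCF, and the
#' ancestry TSV report(s).
#'
#' @param reference Reference genome (FASTA path, `DNAStringSet`, or
#'   named character vector).
#' @param input Sample input: reads (FASTQ/FASTA path(s) or sequences) in
#'   `"reads"` mode, an assembly in `"genome"` mode, or a VCF path in
#'   `"vcf"` mode.
#' @param mode One of `"genome"`, `"reads"`, `"vcf"`.
#' @param panel Panel VCF path or a panel tibble.
#' @param out_prefix Output path prefix for all artifact files.
#' @param k K-mer length (default 55).
#' @param j Query stride (default 3).
#' @param Y Support-fraction threshold (default 0.55).
#' @param tile_size Tile size in bases (default 5,000,000).
#' @param min_count Reads-mode solidity threshold (`NULL` = automatic).
#' @param target_fpr Bloom filter false-positive rate (default 0.001).
#' @param num_hashes Bloom hash count (default 3).
#' @param min_queried Minimum queryable k-mers per position (`NULL` =
#'   `max(3, floor(k / (2 j)))`).
#' @param lai Write the tile-resolution report (default `TRUE`).
#' @param af_threshold Panel admission threshold when `panel` is a path.
#' @param af_keys,chrom_style Passed to [load_panel()] when `panel` is a
#'   path.
#' @param quiet Suppress per-stage messages.
#' @return The `ancestry_report`, invisibly, with attribute `files`
#'   naming everything written.
#' @export
run_ancestry_pipeline <- function(reference, input,
                                  mode = c("genome", "reads", "vcf"),
                                  panel, out_prefix,
                                  k = 55L, j = 3L, Y = 0.55,
                                  tile_size = 5e6,
                                  min_count = NULL, target_fpr = 0.001,
                                  num_hashes = 3L, min_queried = NULL,
                                  lai = TRUE,
                                  af_threshold = 0.01, af_keys = NULL,
                                  chrom_style = "asis", quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (!quiet) message("[", ..., "]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ref <- stage("reference", as_seq_vector(reference, "reference"))
  contig_lengths <- setNames(nchar(ref), contig_names(ref))

  pan <- stage("panel", {
    if (is.character(panel)) {
      load_panel(panel, af_threshold = af_threshold, af_keys = af_keys,
                 chrom_style = chrom_style)
    } else {
      stopifnot(is.data.frame(panel))
      panel
    }
  })
  say("panel: ", nrow(pan), " variants loaded")

  files <- character(0)
  if (mode == "vcf") {
    calls <- stage("calls", {
      stopifnot(is.character(input), length(input) == 1)
      read_snv_vcf(input)
    })
    say("calls: ", nrow(calls), " SNVs read from VCF")
  } else {
    index <- stage("kmer index", {
      if (mode == "reads") {
        bloom_from_reads(input, k = k, min_count = min_count,
                         target_fpr = target_fpr, num_hashes = num_hashes)
      } else {
        bloom_from_assembly(input, k = k, target_fpr = target_fpr,
                            num_hashes = num_hashes)
      }
    })
    info <- kmer_index_info(index)
    say("kmer index: ", format(info$n_inserted, big.mark = ","),
        " k-mers inserted (k=", info$k,
        if (mode == "reads") paste0(", min_count=", index$min_count) else "",
        ")")
    calls <- stage("snv caller", {
      call_snvs(ref, index, j = j, Y = Y, min_queried = min_queried)
    })
    say("snv caller: ", nrow(calls), " SNVs called, ",
        format(attr(calls, "n_skipped"), big.mark = ","), " positions skipped")
    calls_vcf <- paste0(out_prefix, "_snvs.vcf")
    stage("calls vcf", write_snv_vcf(calls, contig_lengths, calls_vcf))
    files <- c(files, calls_vcf)
  }

  records <- stage("cross-reference", cross_reference(calls, pan))
  say("cross-reference: ", nrow(records), " of ", nrow(calls),
      " SNVs matched the panel")

  annotated_vcf <- paste0(out_prefix, "_snvs-annotated.vcf")
  stage("annotated vcf", {
    key <- paste(records$chrom, records$pos, records$ref, records$alt)
    flag <- paste(calls$chrom, calls$pos, calls$ref, calls$alt) %in% key
    if (!all(c("ksf", "rsf", "nq") %in% names(calls))) {
      calls$ksf <- calls$rsf <- NA_real_
      calls$nq <- NA_integer_
    }
    write_snv_vcf(calls, contig_lengths, annotated_vcf, panel_flag = flag)
  })
  files <- c(files, annotated_vcf)

  report <- stage("ancestry", infer_ancestry(records, contig_lengths, tile_size))
  say("ancestry: GAI=", report$gai_label,
      ", majority local label=", report$lai_majority_label,
      ", ", report$n_unassigned, "/", report$n_tiles, " tiles unassigned")
  files <- c(files, stage("reports", write_ancestry_reports(report, out_prefix,
                                                            lai = lai)))
  attr(report, "files") <- files
  invisible(report)
}
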