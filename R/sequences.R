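# Sequence input coercion and FASTA/FASTQ I/O (thin wrappers over Biostrings).

#' Read sequences from a FASTA or FASTQ file
#'
#' Accepts plain or gzipped files; the format is sniffed from the first
#' non-empty character (`>` for FASTA, `@` for FASTQ). Quality strings are
#' ignored throughout the package.
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @return A named character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  stopifnot(is.character(path), length(path) >= 1)
  out <- lapply(path, function(p) {
    if (!file.exists(p)) {
      stop("sequence file not found: '", p, "'", call. = FALSE)
    }
    con <- gzfile(p, "rt")
    on.exit(close(con))
    first <- ""
    while (!nzchar(first)) {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) stop("'", p, "' is empty", call. = FALSE)
      first <- trimws(line)
    }
    fmt <- if (startsWith(first, ">")) "fasta" else if (startsWith(first, "@")) "fastq" else
      stop("'", p, "' is neither FASTA nor FASTQ", call. = FALSE)
    x <- Biostrings::readDNAStringSet(p, format = fmt)
    stats::setNames(toupper(as.character(x)), names(x))
  })
  do.call(c, out)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs A named character vector or `DNAStringSet`.
#' @param path Output path. A `.gz` suffix triggers gzip compression.
#' @param format `"fasta"` or `"fastq"`. FASTQ qualities are written as a
#'   constant high quality since the package never uses them.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- as_dna_stringset(seqs)
  if (format == "fastq") {
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                compress = grepl("\\.gz$", path))
  } else {
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  }
  invisible(path)
}

as_dna_stringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(x))
  }
  stop("expected a DNAStringSet or character vector of sequences", call. = FALSE)
}

# Coerce reference/reads input (file path(s), DNAStringSet, or character
# vector of sequences) to a named uppercase character vector.
as_seq_vector <- function(x, what = "sequence input") {
  if (is.character(x) && length(x) == 0) stop(what, " is empty", call. = FALSE)
  if (methods::is(x, "DNAStringSet")) {
    x <- stats::setNames(toupper(as.character(x)), names(x))
  } else if (is.character(x)) {
    looks_like_path <- length(x) <= 32 && all(nchar(x) < 4096) &&
      all(file.exists(x)) && !any(grepl("^[ACGTNacgtn]+$", x) & nchar(x) >= 16)
    if (looks_like_path) {
      x <- read_sequences(x)
    } else {
      if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
      x <- toupper(x)
    }
  } else {
    stop(what, " must be a file path, DNAStringSet, or character vector",
         call. = FALSE)
  }
  if (length(x) == 0) stop(what, " is empty", call. = FALSE)
  if (anyDuplicated(names(x))) stop(what, " has duplicated sequence names", call. = FALSE)
  x
}

# First whitespace-delimited token of FASTA headers, as contig names.
contig_names <- function(seqs) {
  sub("\\s.*$", "", names(seqs))
}
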