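#' Read a FASTQ file into a data frame of reads
#'
#' Reads a Phred+33 FASTQ file and returns one row per read with its
#' identifier, base sequence and quality string.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`
#'   (quality in Phred+33 encoding, same length as the sequence).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open; intervals are returned in that convention
#' (columns `start0`, `end0`). The BED name field, when present, is kept
#' as the `name` column (used here to tag peaks by source study).
#'
#' @param path Path to a BED file (BED3 or BED4+).
#' @return Data frame with columns `chrom`, `start0`, `end0`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (!is.null(gr$name)) as.character(gr$name) else
    rep(NA_character_, length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             name = nm, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write intervals to a BED file
#'
#' @param x Data frame with `chrom`, `start0`, `end0` (0-based half-open)
#'   and optionally `name`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path) {
  gr <- GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(start = x$start0 + 1L, end = x$end0))
  if (!is.null(x$name)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path Path to a GMT file.
#' @return Named list of character vectors (category -> genes).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions
#'   (second GMT column); defaults to the set names.
#' @return The path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
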