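#' Clean raw small-RNA reads and report per-class filter counts
#'
#' Applies the standard small-RNA cleaning cascade in a fixed order; each
#' read is charged to the first class it fails:
#' \enumerate{
#'   \item \code{low_quality}: mean Phred < `quality_threshold` or >10% N;
#'   \item \code{adapter5_contaminant}: read begins with the first 8 bases
#'     of the 5' adapter;
#'   \item \code{no_adapter3}: no exact 8-base 3'-adapter prefix anywhere
#'     \emph{and} the read is longer than the maximum insert length (a
#'     shorter adapter-free read is treated as an already-trimmed insert,
#'     which makes cleaning idempotent);
#'   \item \code{no_insert}: zero-length insert after adapter trimming;
#'   \item \code{polyA}: trimmed insert with >= 80% adenine;
#'   \item \code{length_out_of_bounds}: insert length outside
#'     `length_bounds`.
#' }
#' Survivors are adapter-trimmed inserts within the length bounds.
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` ([read_fastq()]
#'   output). Sequence and quality must have equal lengths per read.
#' @param adapter5,adapter3 Adapter sequences (non-empty).
#' @param quality_threshold Minimum mean Phred score (default 20).
#' @param length_bounds Inclusive insert length bounds in nt
#'   (default `c(18, 30)`).
#' @return List with `clean` (data frame of trimmed inserts: `id`, `seq`,
#'   `qual`) and `report` (named integer vector of class counts, a
#'   `filter_report`: raw, low_quality, adapter5_contaminant, no_adapter3,
#'   no_insert, polyA, length_out_of_bounds, clean).
#' @export
clean_reads <- function(reads, adapter5 = DEFAULT_ADAPTER5,
                        adapter3 = DEFAULT_ADAPTER3,
                        quality_threshold = 20,
                        length_bounds = c(18L, 30L)) {
  stopifnot(nzchar(adapter5), nzchar(adapter3),
            length_bounds[1] <= length_bounds[2])
  bad <- which(nchar(reads$seq) != nchar(reads$qual) | !nzchar(reads$seq))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1],
         ": sequence/quality length mismatch or empty sequence")
  n <- nrow(reads)
  cls <- rep("clean", n)

  meanq <- mean_phred(reads$qual)
  nfrac <- char_fraction(reads$seq, "N")
  cls[meanq < quality_threshold | nfrac > 0.10] <- "low_quality"

  a5_8 <- substr(adapter5, 1L, 8L)
  open <- cls == "clean"
  cls[open & startsWith(reads$seq, a5_8)] <- "adapter5_contaminant"

  a8 <- substr(adapter3, 1L, 8L)
  pos <- regexpr(a8, reads$seq, fixed = TRUE)
  ins_len <- ifelse(pos > 0L, pos - 1L, nchar(reads$seq))
  open <- cls == "clean"
  cls[open & pos < 0L & nchar(reads$seq) > length_bounds[2]] <- "no_adapter3"

  open <- cls == "clean"
  cls[open & ins_len == 0L] <- "no_insert"

  insert <- substr(reads$seq, 1L, ins_len)
  open <- cls == "clean"
  cls[open & char_fraction(insert, "A") >= 0.8] <- "polyA"

  open <- cls == "clean"
  cls[open & (ins_len < length_bounds[1] | ins_len > length_bounds[2])] <-
    "length_out_of_bounds"

  keep <- cls == "clean"
  clean <- data.frame(id = reads$id[keep], seq = insert[keep],
                      qual = substr(reads$qual, 1L, ins_len)[keep],
                      stringsAsFactors = FALSE)
  levels <- c("low_quality", "adapter5_contaminant", "no_adapter3",
              "no_insert", "polyA", "length_out_of_bounds", "clean")
  report <- c(raw = n, stats::setNames(
    as.integer(tabulate(factor(cls, levels = levels), length(levels))),
    levels))
  class(report) <- c("filter_report", class(report))
  list(clean = clean, report = report)
}

#' Length distribution of clean reads
#'
#' @param reads Data frame of clean reads (or character vector of
#'   sequences).
#' @return Named numeric vector mapping read length (nt) to the fraction
#'   of reads; fractions sum to 1.
#' @export
length_distribution <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) stop("no reads: length distribution undefined")
  tab <- table(nchar(seqs))
  stats::setNames(as.numeric(tab) / length(seqs), names(tab))
}

#' Positional nucleotide composition of miRNA-assigned reads
#'
#' Computes, for each position (1-based from the 5' end), the fraction of
#' reads carrying each base among the reads long enough to cover that
#' position. Thymine is reported as uracil.
#'
#' @param reads Data frame of reads or character vector of sequences.
#' @return Numeric matrix, positions x c("A","U","C","G"); each covered
#'   row sums to 1.
#' @export
nucleotide_bias <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  if (length(seqs) == 0L) stop("no reads: nucleotide bias undefined")
  maxlen <- max(nchar(seqs))
  bases <- c("A", "U", "C", "G")
  mat <- matrix(0, nrow = maxlen, ncol = 4,
                dimnames = list(seq_len(maxlen), bases))
  chars <- strsplit(chartr("T", "U", seqs), "")
  for (p in seq_len(maxlen)) {
    at <- vapply(chars, function(x) if (length(x) >= p) x[p] else NA_character_,
                 character(1))
    at <- at[!is.na(at)]
    tab <- table(factor(at, levels = bases))
    mat[p, ] <- as.numeric(tab) / length(at)
  }
  mat
}

#' Map reads to reference sequences allowing up to one mismatch
#'
#' Substitution-only matching of each read (and its reverse complement for
#' the minus strand) against every reference sequence, reporting all
#' alignments with at most `max_mismatch` mismatches. Coordinates are
#' 0-based half-open on the forward strand.
#'
#' @param reads Data frame of clean reads or character vector (optionally
#'   named with read ids).
#' @param reference Named character vector of reference sequences (e.g. a
#'   toy genome) or a `DNAStringSet`.
#' @param max_mismatch Maximum substitutions per alignment (default 1).
#' @return List with `alignments` (data frame: `read_id`, `chrom`,
#'   `start0`, `strand`, `mismatches`) and `unmapped` (read ids with no
#'   alignment).
#' @export
map_reads <- function(reads, reference, max_mismatch = 1L) {
  if (is.data.frame(reads)) {
    seqs <- stats::setNames(reads$seq, reads$id)
  } else {
    seqs <- reads
    if (is.null(names(seqs))) names(seqs) <- sprintf("read%06d",
                                                     seq_along(seqs))
  }
  if (length(reference) == 0L) stop("empty reference")
  ref <- Biostrings::DNAStringSet(as.character(reference))
  if (is.null(names(ref))) names(ref) <- names(reference)

  uniq <- unique(unname(seqs))
  hits <- vector("list", length(uniq))
  for (ui in seq_along(uniq)) {
    s <- uniq[ui]
    pat <- Biostrings::DNAString(s)
    rcpat <- Biostrings::reverseComplement(pat)
    rows <- list()
    for (ci in seq_along(ref)) {
      for (str in c("+", "-")) {
        p <- if (str == "+") pat else rcpat
        mm <- Biostrings::matchPattern(p, ref[[ci]],
                                       max.mismatch = max_mismatch,
                                       with.indels = FALSE)
        if (length(mm)) {
          nmis <- Biostrings::neditStartingAt(
            p, ref[[ci]], starting.at = Biostrings::start(mm),
            with.indels = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = names(ref)[ci],
            start0 = Biostrings::start(mm) - 1L,
            strand = str, mismatches = as.integer(nmis),
            stringsAsFactors = FALSE)
        }
      }
    }
    hits[ui] <- list(if (length(rows)) do.call(rbind, rows) else NULL)
  }
  idx <- match(unname(seqs), uniq)
  out <- list()
  for (ri in seq_along(seqs)) {
    h <- hits[[idx[ri]]]
    if (!is.null(h)) {
      h$read_id <- names(seqs)[ri]
      out[[length(out) + 1L]] <- h
    }
  }
  aln <- if (length(out)) do.call(rbind, out)[, c("read_id", "chrom",
                                                 "start0", "strand",
                                                 "mismatches")]
  else data.frame(read_id = character(), chrom = character(),
                  start0 = integer(), strand = character(),
                  mismatches = integer(), stringsAsFactors = FALSE)
  rownames(aln) <- NULL
  list(alignments = aln,
       unmapped = setdiff(names(seqs), aln$read_id))
}

#' Per-chromosome, per-strand alignment counts
#'
#' @param alignments Alignment data frame from [map_reads()].
#' @return Data frame `chrom`, `strand`, `n_reads`.
#' @export
chromosome_strand_counts <- function(alignments) {
  ag <- stats::aggregate(list(n_reads = alignments$read_id),
                         by = list(chrom = alignments$chrom,
                                   strand = alignments$strand),
                         FUN = length)
  ag[order(ag$chrom, ag$strand), , drop = FALSE]
}

#' Count mature miRNAs in one library of clean reads
#'
#' A read is assigned to every mature miRNA of the same length within
#' `max_mismatch` substitutions (full-insert matching; multi-assignment is
#' the default, `multi = "best"` keeps only minimum-mismatch hits).
#'
#' @param reads Clean read data frame or character vector of insert
#'   sequences.
#' @param mature Named character vector of mature miRNA sequences
#'   (unique names).
#' @param max_mismatch Maximum substitutions (default 1).
#' @param multi `"all"` (default) or `"best"`.
#' @return List with `counts` (named integer vector per miRNA) and
#'   `total` (number of clean reads in the library).
#' @export
count_mirnas <- function(reads, mature, max_mismatch = 1L,
                         multi = c("all", "best")) {
  multi <- match.arg(multi)
  if (anyDuplicated(names(mature)))
    stop("duplicate miRNA names in the mature reference")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  counts <- stats::setNames(integer(length(mature)), names(mature))
  total <- length(seqs)
  if (total == 0L) return(list(counts = counts, total = 0L))

  tab <- table(seqs)
  useq <- names(tab)
  umult <- as.integer(tab)
  ulen <- nchar(useq)
  mlen <- nchar(mature)

  for (L in unique(mlen)) {
    ri <- which(ulen == L)
    mi <- which(mlen == L)
    if (!length(ri) || !length(mi)) next
    rmat <- matrix(utf8ToInt(paste(useq[ri], collapse = "")),
                   ncol = L, byrow = TRUE)
    mm_mat <- matrix(NA_integer_, nrow = length(ri), ncol = length(mi))
    for (j in seq_along(mi)) {
      mv <- utf8ToInt(mature[[mi[j]]])
      mm_mat[, j] <- rowSums(rmat != matrix(mv, nrow = length(ri),
                                            ncol = L, byrow = TRUE))
    }
    hit <- mm_mat <= max_mismatch
    if (multi == "best") {
      best <- apply(mm_mat, 1L, min)
      hit <- hit & (mm_mat == best)
    }
    add <- colSums(hit * umult[ri])
    counts[mi] <- counts[mi] + as.integer(add)
  }
  list(counts = counts, total = total)
}

#' Assemble a miRNA count table across libraries
#'
#' @param library_counts Named list of [count_mirnas()] results (one per
#'   library, in library order).
#' @return A `count_table`: list with `counts` (miRNA x library integer
#'   matrix), `totals` (clean reads per library), `libraries`.
#' @export
count_table <- function(library_counts) {
  libs <- names(library_counts)
  stopifnot(!is.null(libs))
  mirnas <- names(library_counts[[1]]$counts)
  counts <- vapply(library_counts, function(x) {
    stopifnot(identical(names(x$counts), mirnas))
    x$counts
  }, integer(length(mirnas)))
  counts <- matrix(counts, nrow = length(mirnas),
                   dimnames = list(mirnas, libs))
  totals <- vapply(library_counts, function(x) as.integer(x$total),
                   integer(1))
  if (any(totals <= 0)) stop("library with zero clean reads")
  structure(list(counts = counts, totals = totals, libraries = libs),
            class = "count_table")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Small-RNA read filter report\n")
  n <- x[["raw"]]
  for (cl in setdiff(names(x), "raw"))
    cat(sprintf("  %-22s %10d  (%.2f%%)\n", cl, x[[cl]],
                100 * x[[cl]] / n))
  cat(sprintf("  %-22s %10d\n", "raw", n))
  invisible(x)
}
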