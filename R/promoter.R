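#' Assign a transcription start site to each miRNA
#'
#' Three-step priority: (1) a curated TSS when the miRNA is present in
#' the curated table; (2) for intragenic miRNAs, the transcription
#' initiation site of the host-gene transcript; (3) the genomic position
#' of the first nucleotide of the precursor (strand-aware: on the minus
#' strand this is the highest coordinate).
#'
#' @param annotation miRNA annotation data frame (`mirna`, `chrom`,
#'   `start0`, `end0`, `strand`, `host_gene`), e.g.
#'   `mirna_reference$mirnas`.
#' @param curated_tss Optional curated table (`mirna`, `chrom`, `pos`,
#'   `strand`); positions are 1-based unless `curated_one_based = FALSE`.
#' @param host_transcripts Optional host-transcript table (`gene`,
#'   `chrom`, `tx_start0`, `tx_end0`, `strand`).
#' @param curated_one_based Declared coordinate basis of the curated
#'   table (default TRUE).
#' @return Data frame of TSS records: `mirna`, `chrom`, `pos0` (0-based
#'   coordinate of the first transcribed base), `strand`, `source`
#'   (curated / host_gene / premirna_start).
#' @export
assign_tss <- function(annotation, curated_tss = NULL,
                       host_transcripts = NULL, curated_one_based = TRUE) {
  need <- c("mirna", "chrom", "start0", "end0", "strand")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  n <- nrow(annotation)
  if (n == 0L) stop("no miRNAs in the annotation")
  pos0 <- integer(n); src <- character(n); chrom <- annotation$chrom
  strand <- annotation$strand
  for (i in seq_len(n)) {
    m <- annotation$mirna[i]
    ci <- if (!is.null(curated_tss)) match(m, curated_tss$mirna) else NA
    if (!is.na(ci)) {
      pos0[i] <- curated_tss$pos[ci] - if (curated_one_based) 1L else 0L
      chrom[i] <- curated_tss$chrom[ci]
      strand[i] <- curated_tss$strand[ci]
      src[i] <- "curated"
      next
    }
    host <- annotation$host_gene[i]
    hi <- if (!is.null(host_transcripts) && !is.na(host))
      match(host, host_transcripts$gene) else NA
    if (!is.na(hi)) {
      pos0[i] <- if (host_transcripts$strand[hi] == "+")
        host_transcripts$tx_start0[hi] else host_transcripts$tx_end0[hi] - 1L
      strand[i] <- host_transcripts$strand[hi]
      src[i] <- "host_gene"
      next
    }
    pos0[i] <- if (annotation$strand[i] == "+") annotation$start0[i]
    else annotation$end0[i] - 1L
    src[i] <- "premirna_start"
  }
  data.frame(mirna = annotation$mirna, chrom = chrom,
             pos0 = as.integer(pos0), strand = strand, source = src,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Strand-aware putative promoter windows around miRNA TSSs
#'
#' The promoter covers `upstream` bp upstream and `downstream` bp
#' downstream of the TSS in transcription orientation: on the plus strand
#' `[pos - U, pos + D)`, on the minus strand `[pos - D + 1, pos + U + 1)`,
#' clipped to the chromosome.
#'
#' @param tss TSS record data frame from [assign_tss()].
#' @param upstream,downstream Window extents in bp (default 10000 / 1000).
#' @param chrom_lengths Named chromosome lengths for clipping (optional;
#'   windows are always clipped at 0).
#' @return Data frame `mirna`, `chrom`, `start0`, `end0`, `strand`.
#' @export
promoter_window <- function(tss, upstream = 10000, downstream = 1000,
                            chrom_lengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  plus <- tss$strand == "+"
  start0 <- ifelse(plus, tss$pos0 - upstream, tss$pos0 - downstream + 1L)
  end0 <- ifelse(plus, tss$pos0 + downstream, tss$pos0 + upstream + 1L)
  start0 <- pmax(start0, 0L)
  if (!is.null(chrom_lengths))
    end0 <- pmin(end0, chrom_lengths[tss$chrom])
  if (any(start0 >= end0))
    stop("promoter window clipped to zero length for: ",
         paste(tss$mirna[start0 >= end0], collapse = ", "))
  data.frame(mirna = tss$mirna, chrom = tss$chrom,
             start0 = as.integer(start0), end0 = as.integer(end0),
             strand = tss$strand, tss_pos0 = as.integer(tss$pos0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect promoter windows with ChIP-seq peaks
#'
#' Any overlap of at least `min_overlap` bp between a peak and a promoter
#' window yields a binding site. The signed distance runs from the TSS to
#' the peak midpoint in transcription orientation (negative = upstream).
#' Peaks duplicated across study tags are retained with their tags.
#'
#' @param promoters Promoter windows from [promoter_window()]; a `pos0`
#'   column (TSS) is joined from `tss` when given.
#' @param peaks Peak data frame (`chrom`, `start0`, `end0`, `name`), e.g.
#'   from [read_bed()]; `name` carries the study tag.
#' @param tss Optional TSS table used for signed distances (`mirna`,
#'   `pos0`); when omitted distances are relative to the window-implied
#'   TSS.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return Data frame of binding sites: `mirna`, `chrom`, `peak_start0`,
#'   `peak_end0`, `study`, `signed_distance`, `upstream`,
#'   `within_5kb_upstream`.
#' @export
find_binding_sites <- function(promoters, peaks, tss = NULL,
                               min_overlap = 1L) {
  if (any(peaks$end0 <= peaks$start0))
    stop("malformed peak interval at line ",
         which(peaks$end0 <= peaks$start0)[1])
  pg <- GenomicRanges::GRanges(
    promoters$chrom,
    IRanges::IRanges(promoters$start0 + 1L, promoters$end0))
  kg <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start0 + 1L, peaks$end0))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(pg, kg,
                                minoverlap = as.integer(min_overlap)))
  pi <- S4Vectors::queryHits(ov); ki <- S4Vectors::subjectHits(ov)
  tss_pos <- if (!is.null(tss)) tss$pos0[match(promoters$mirna, tss$mirna)]
  else promoters$tss_pos0
  if (is.null(tss_pos))
    stop("TSS positions are required (pass `tss` or promoters with a ",
         "`tss_pos0` column)")
  mid <- (peaks$start0[ki] + peaks$end0[ki]) / 2
  sd_raw <- mid - tss_pos[pi]
  signed <- ifelse(promoters$strand[pi] == "+", sd_raw, -sd_raw)
  out <- data.frame(mirna = promoters$mirna[pi],
                    chrom = peaks$chrom[ki],
                    peak_start0 = peaks$start0[ki],
                    peak_end0 = peaks$end0[ki],
                    study = peaks$name[ki],
                    signed_distance = signed,
                    upstream = signed < 0,
                    within_5kb_upstream = signed < 0 & signed >= -5000,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mirna, out$chrom, out$peak_start0, out$study), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Summarize binding-site placement over the selected miRNAs
#'
#' @param sites Binding sites from [find_binding_sites()].
#' @param dems A `dem_set` with `mirna` and `direction`.
#' @return List: `n_mirnas_with_sites`, `n_up`, `n_down`,
#'   `n_multiple_sites` (miRNAs with >= 2 distinct overlapping peaks),
#'   `n_sites`, `fraction_upstream`, `fraction_within_5kb_upstream`
#'   (fractions NA when there are no sites).
#' @export
summarize_sites <- function(sites, dems) {
  if (nrow(dems) == 0L) stop("empty DEM set")
  bad <- setdiff(sites$mirna, dems$mirna)
  if (length(bad))
    stop("binding sites reference miRNAs outside the DEM set: ",
         paste(bad, collapse = ", "))
  if (nrow(sites) == 0L)
    return(list(n_mirnas_with_sites = 0L, n_up = 0L, n_down = 0L,
                n_multiple_sites = 0L, n_sites = 0L,
                fraction_upstream = NA_real_,
                fraction_within_5kb_upstream = NA_real_))
  peak_key <- paste(sites$chrom, sites$peak_start0, sites$peak_end0)
  per_mirna <- tapply(peak_key, sites$mirna,
                      function(k) length(unique(k)))
  with_sites <- names(per_mirna)
  dirs <- dems$direction[match(with_sites, dems$mirna)]
  list(n_mirnas_with_sites = length(with_sites),
       n_up = sum(dirs == "up"), n_down = sum(dirs == "down"),
       n_multiple_sites = sum(per_mirna >= 2L),
       n_sites = nrow(sites),
       fraction_upstream = mean(sites$upstream),
       fraction_within_5kb_upstream = mean(sites$within_5kb_upstream))
}
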