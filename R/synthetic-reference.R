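#' Construct a planted-truth record for a synthetic dataset
#'
#' Records everything the generators plant so downstream recovery can be
#' checked: per-miRNA log2 fold changes between conditions, the set of
#' miRNAs given promoter peaks, and per-class read contamination rates.
#'
#' @param planted_log2fc Named numeric vector, miRNA -> log2 fold change
#'   (treated over control). Unlisted miRNAs get 0.
#' @param bound_mirnas Character vector of miRNAs to receive >=1 planted
#'   promoter peak.
#' @param multi_bound Subset of `bound_mirnas` to receive two peaks
#'   (from different pseudo-studies).
#' @param contamination_rates Named numeric vector with any of
#'   `low_quality`, `adapter5_contaminant`, `no_adapter3`, `no_insert`,
#'   `polyA`, `length_out_of_bounds`; fractions in \[0,1\] summing to < 1.
#' @param enriched_pairs Optional data frame with columns `mirna`,
#'   `category` naming planted enriched (miRNA, category) pairs.
#' @param seed Integer seed recorded with the truth.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(planted_log2fc = numeric(),
                            bound_mirnas = character(),
                            multi_bound = character(),
                            contamination_rates = numeric(),
                            enriched_pairs = NULL,
                            seed = 1L) {
  known <- c("low_quality", "adapter5_contaminant", "no_adapter3",
             "no_insert", "polyA", "length_out_of_bounds")
  if (length(contamination_rates)) {
    bad <- setdiff(names(contamination_rates), known)
    if (length(bad)) stop("unknown contamination class: ",
                          paste(bad, collapse = ", "))
    if (any(contamination_rates < 0 | contamination_rates > 1))
      stop("contamination rates must lie in [0, 1]")
    if (sum(contamination_rates) >= 1)
      stop("contamination rates must sum to < 1")
  }
  if (!all(multi_bound %in% bound_mirnas))
    stop("multi_bound must be a subset of bound_mirnas")
  structure(list(planted_log2fc = planted_log2fc,
                 bound_mirnas = bound_mirnas,
                 multi_bound = multi_bound,
                 contamination_rates = contamination_rates,
                 enriched_pairs = enriched_pairs,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate a toy genome and a miRNA reference placed on it
#'
#' Builds random chromosomes, places non-overlapping miRNA precursors
#' (60-110 nt) on random strands, embeds a ~22-nt mature sequence in each
#' precursor, and assigns a fraction of miRNAs to synthetic host-gene
#' transcripts (intragenic miRNAs); the remainder are intergenic. All
#' placement is deterministic given `seed`.
#'
#' @param n_mirnas Number of miRNAs to place (>= 1).
#' @param genome_spec List with `n_chrom` and `chrom_length` (bp), or a
#'   named numeric vector of chromosome lengths.
#' @param seed Integer seed.
#' @param frac_intragenic Fraction of miRNAs given a host transcript.
#' @param min_gap Minimum intergenic distance (bp) enforced between
#'   consecutive precursors on a chromosome (default 0). A gap larger
#'   than the promoter span guarantees non-overlapping promoter windows.
#' @return A list of class `mirna_reference` with elements
#'   `genome` (named character vector of chromosome sequences),
#'   `mirnas` (data frame: name, chrom, precursor/mature coordinates
#'   0-based half-open, strand, sequences, locus type, host gene) and
#'   `hosts` (data frame of host transcripts).
#' @export
generate_mirna_reference <- function(n_mirnas,
                                     genome_spec = list(n_chrom = 2,
                                                        chrom_length = 100000),
                                     seed = 1L,
                                     frac_intragenic = 0.4,
                                     min_gap = 0L) {
  stopifnot(n_mirnas >= 1)
  if (is.list(genome_spec)) {
    lens <- rep(genome_spec$chrom_length, genome_spec$n_chrom)
    names(lens) <- paste0("chr", seq_along(lens))
  } else {
    lens <- genome_spec
    if (is.null(names(lens))) names(lens) <- paste0("chr", seq_along(lens))
  }
  if (any(lens <= 0)) stop("chromosome lengths must be positive")

  with_seed(seed, {
    genome <- vapply(lens, random_dna, character(1))

    pre_len <- sample(60:110, n_mirnas, replace = TRUE)
    chrom <- sample(names(lens), n_mirnas, replace = TRUE,
                    prob = lens / sum(lens))
    # place precursors per chromosome without overlap by distributing the
    # free space into random gaps (exact, no rejection sampling)
    start0 <- integer(n_mirnas)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      k <- length(i)
      free <- lens[[ch]] - sum(pre_len[i]) - min_gap * (k - 1L)
      if (free < 0)
        stop("cannot place ", k, " precursors on ", ch,
             ": total precursor length ", sum(pre_len[i]),
             " plus minimum gaps exceeds chromosome length ", lens[[ch]])
      cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
      starts <- cuts + cumsum(c(0L, pre_len[i][-k])) +
        min_gap * (seq_len(k) - 1L)
      ord <- sample.int(k)  # decouple placement order from miRNA index
      start0[i[ord]] <- starts
    }
    end0 <- start0 + pre_len
    strand <- sample(c("+", "-"), n_mirnas, replace = TRUE)

    mat_len <- sample(21:23, n_mirnas, replace = TRUE)
    mat_off <- vapply(seq_len(n_mirnas), function(i)
      sample.int(pre_len[i] - mat_len[i] + 1L, 1L) - 1L, integer(1))

    pre_fwd <- vapply(seq_len(n_mirnas), function(i)
      substr(genome[[chrom[i]]], start0[i] + 1L, end0[i]), character(1))
    precursor_seq <- ifelse(strand == "+", pre_fwd, revcomp(pre_fwd))
    mature_seq <- substr(precursor_seq, mat_off + 1L, mat_off + mat_len)
    # genomic coordinates of the mature miRNA (strand-aware offset)
    mat_start0 <- ifelse(strand == "+", start0 + mat_off,
                         end0 - mat_off - mat_len)
    mat_end0 <- mat_start0 + mat_len

    name <- sprintf("syn-mir-%03d", seq_len(n_mirnas))
    n_intra <- round(frac_intragenic * n_mirnas)
    intra <- seq_len(n_mirnas) %in% sample.int(n_mirnas, n_intra)
    host_gene <- ifelse(intra, sprintf("HOSTG%03d", seq_len(n_mirnas)), NA)
    locus_type <- ifelse(intra, "Intron", "Intergenic")

    # host transcript extends upstream of the precursor on the same strand
    up_ext <- sample(500:3000, n_mirnas, replace = TRUE)
    dn_ext <- sample(200:1000, n_mirnas, replace = TRUE)
    tx_start0 <- ifelse(strand == "+", pmax(0L, start0 - up_ext),
                        pmax(0L, start0 - dn_ext))
    tx_end0 <- ifelse(strand == "+",
                      pmin(lens[chrom], end0 + dn_ext),
                      pmin(lens[chrom], end0 + up_ext))
    hosts <- data.frame(gene = host_gene[intra], chrom = chrom[intra],
                        tx_start0 = as.integer(tx_start0[intra]),
                        tx_end0 = as.integer(tx_end0[intra]),
                        strand = strand[intra],
                        stringsAsFactors = FALSE)

    mirnas <- data.frame(
      mirna = name, chrom = chrom,
      start0 = as.integer(start0), end0 = as.integer(end0),
      strand = strand,
      mature_start0 = as.integer(mat_start0),
      mature_end0 = as.integer(mat_end0),
      mature_seq = mature_seq, precursor_seq = precursor_seq,
      locus_type = locus_type, host_gene = host_gene,
      stringsAsFactors = FALSE)

    structure(list(genome = genome, mirnas = mirnas, hosts = hosts),
              class = "mirna_reference")
  })
}

#' Write a miRNA reference to FASTA and TSV files
#'
#' Writes `genome.fa`, `mature.fa`, `precursor.fa`, `mirna_locations.tsv`
#' and `host_transcripts.tsv` under `dir`. Byte-identical for identical
#' references.
#'
#' @param reference A `mirna_reference`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_mirna_reference <- function(reference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(genome = file.path(dir, "genome.fa"),
         mature = file.path(dir, "mature.fa"),
         precursor = file.path(dir, "precursor.fa"),
         locations = file.path(dir, "mirna_locations.tsv"),
         hosts = file.path(dir, "host_transcripts.tsv"))
  write_fasta(reference$genome, p[["genome"]])
  write_fasta(stats::setNames(reference$mirnas$mature_seq,
                              reference$mirnas$mirna), p[["mature"]])
  write_fasta(stats::setNames(reference$mirnas$precursor_seq,
                              reference$mirnas$mirna), p[["precursor"]])
  loc_cols <- c("mirna", "chrom", "start0", "end0", "strand",
                "mature_start0", "mature_end0", "locus_type", "host_gene")
  write_tsv(reference$mirnas[, loc_cols], p[["locations"]])
  write_tsv(reference$hosts, p[["hosts"]])
  invisible(p)
}

#' Load the packaged table of differentially expressed miRNAs
#'
#' Returns the packaged 33-row table of replicate log2 fold changes and
#' p-values for the doxorubicin-induced miRNA set, with the significance
#' tier labels (`*` p<0.05, `**` p<0.01), locus type and host gene.
#'
#' @return Data frame with columns `mirna`, `log2fc_rep1`, `p_rep1`,
#'   `sig_rep1`, `log2fc_rep2`, `p_rep2`, `sig_rep2`, `locus_type`,
#'   `host_gene`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_dems.tsv", package = "p53mirnet")
  if (path == "" || !file.exists(path))
    stop("packaged DEM table fixture is missing")
  t1 <- read_tsv(path, colClasses = c(
    mirna = "character", log2fc_rep1 = "numeric", p_rep1 = "numeric",
    sig_rep1 = "character", log2fc_rep2 = "numeric", p_rep2 = "numeric",
    sig_rep2 = "character", locus_type = "character",
    host_gene = "character"))
  if (nrow(t1) != 33L || anyDuplicated(t1$mirna))
    stop("packaged DEM table fixture is corrupt")
  if (!all(t1$locus_type %in% c("Intergenic", "Intron", "Intron/Exon")))
    stop("packaged DEM table fixture has invalid locus types")
  t1
}
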