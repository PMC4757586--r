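#' Plant ChIP-seq peaks inside selected miRNA promoters
#'
#' Places one peak (two for `truth$multi_bound`, tagged with different
#' pseudo-studies) inside the strand-aware promoter window of every bound
#' miRNA, plus `decoy_count` peaks outside all promoter windows. Peaks are
#' 0-based half-open intervals; the BED name field carries the
#' pseudo-study tag.
#'
#' @param tss_table Data frame of TSS records (`mirna`, `chrom`, `pos0`,
#'   `strand`), as returned by [assign_tss()].
#' @param truth A `synthetic_truth` with `bound_mirnas` (and optionally
#'   `multi_bound`).
#' @param decoy_count Number of decoy peaks outside all promoters.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param seed Integer seed.
#' @param upstream,downstream Promoter window extents in bp.
#' @param peak_width Peak width in bp.
#' @param path Optional BED output path.
#' @return Data frame of peaks (`chrom`, `start0`, `end0`, `name`) with a
#'   `planted_mirna` column (NA for decoys).
#' @export
generate_chip_peaks <- function(tss_table, truth, decoy_count = 20,
                                chrom_lengths, seed = 1L,
                                upstream = 10000, downstream = 1000,
                                peak_width = 300, path = NULL) {
  bound <- truth$bound_mirnas
  if (!all(bound %in% tss_table$mirna))
    stop("bound miRNAs missing from the TSS table: ",
         paste(setdiff(bound, tss_table$mirna), collapse = ", "))
  windows <- promoter_window(tss_table, upstream = upstream,
                             downstream = downstream,
                             chrom_lengths = chrom_lengths)
  studies <- c("pseudo-study-A", "pseudo-study-B")

  with_seed(seed, {
    peaks <- list()
    for (m in bound) {
      wrow <- windows[windows$mirna == m, ]
      n_peaks <- if (m %in% truth$multi_bound) 2L else 1L
      lo <- wrow$start0
      hi <- wrow$end0 - peak_width
      if (hi < lo) { # narrow clipped window: shrink the peak to fit
        hi <- lo
        peak_width_m <- wrow$end0 - wrow$start0
      } else peak_width_m <- peak_width
      # keep planted peaks out of other miRNAs' windows so the planted
      # bound set is recovered exactly: sample from the allowed starts
      other <- windows[windows$mirna != m & windows$chrom == wrow$chrom, ,
                       drop = FALSE]
      allowed <- rep(TRUE, hi - lo + 1L)
      for (oi in seq_len(nrow(other))) {
        blo <- max(lo, other$start0[oi] - peak_width_m + 1L)
        bhi <- min(hi, other$end0[oi] - 1L)
        if (blo <= bhi) allowed[(blo - lo + 1L):(bhi - lo + 1L)] <- FALSE
      }
      pool <- which(allowed) + lo - 1L
      if (length(pool) < n_peaks)
        stop("cannot place ", n_peaks, " peaks for ", m,
             " inside its promoter without touching other promoters")
      starts <- pool[sample.int(length(pool), n_peaks)]
      peaks[[m]] <- data.frame(
        chrom = wrow$chrom, start0 = starts,
        end0 = starts + peak_width_m,
        name = studies[seq_len(n_peaks)],
        planted_mirna = m, stringsAsFactors = FALSE)
    }
    if (decoy_count > 0) {
      got <- 0L; tries <- 0L; dec <- list()
      while (got < decoy_count) {
        tries <- tries + 1L
        if (tries > 50L * decoy_count)
          stop("cannot place ", decoy_count,
               " decoy peaks outside all promoter windows")
        ch <- sample(names(chrom_lengths), 1L)
        s <- sample.int(max(1L, chrom_lengths[[ch]] - peak_width), 1L) - 1L
        e <- s + peak_width
        wch <- windows[windows$chrom == ch, , drop = FALSE]
        if (nrow(wch) == 0L || all(e <= wch$start0 | s >= wch$end0)) {
          got <- got + 1L
          dec[[got]] <- data.frame(chrom = ch, start0 = s, end0 = e,
                                   name = sample(studies, 1L),
                                   planted_mirna = NA_character_,
                                   stringsAsFactors = FALSE)
        }
      }
      peaks <- c(peaks, dec)
    }
    out <- do.call(rbind, peaks)
    rownames(out) <- NULL
    if (!is.null(path)) write_bed(out[, c("chrom", "start0", "end0", "name")],
                                  path)
    out
  })
}

#' Generate miRNA target tables with controlled inter-source overlap
#'
#' Builds two prediction tables whose per-miRNA Jaccard overlap is
#' approximately `overlap_fraction`, plus an independent validated-target
#' table. Genes are drawn from a universe `G00001..G<n_genes>`.
#'
#' @param mirnas Character vector of miRNA names.
#' @param n_genes Size of the gene universe.
#' @param overlap_fraction Target Jaccard index between the two
#'   prediction sources, in \[0,1\].
#' @param targets_per_mirna Predicted targets per miRNA per source.
#' @param validated_per_mirna Validated targets per miRNA.
#' @param seed Integer seed.
#' @param dir Optional directory to write `pred_a.tsv`, `pred_b.tsv`,
#'   `validated.tsv`.
#' @return List with data frames `pred_a`, `pred_b`, `validated`
#'   (columns `mirna`, `gene`) and the `genes` universe.
#' @export
generate_target_data <- function(mirnas, n_genes = 2000,
                                 overlap_fraction = 0.5,
                                 targets_per_mirna = 100,
                                 validated_per_mirna = 10,
                                 seed = 1L, dir = NULL) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  s <- targets_per_mirna
  shared <- round(2 * s * overlap_fraction / (1 + overlap_fraction))
  need <- 2 * s - shared
  if (n_genes < max(need, validated_per_mirna))
    stop("gene universe of size ", n_genes, " is too small for ",
         need, " distinct predicted targets per miRNA")
  genes <- sprintf("G%05d", seq_len(n_genes))

  with_seed(seed, {
    pa <- pb <- va <- list()
    for (m in mirnas) {
      pool <- sample(genes, need)
      common <- pool[seq_len(shared)]
      only_a <- pool[shared + seq_len(s - shared)]
      only_b <- pool[s + seq_len(s - shared)]
      pa[[m]] <- data.frame(mirna = m, gene = c(common, only_a),
                            stringsAsFactors = FALSE)
      pb[[m]] <- data.frame(mirna = m, gene = c(common, only_b),
                            stringsAsFactors = FALSE)
      va[[m]] <- data.frame(mirna = m,
                            gene = sample(genes, validated_per_mirna),
                            stringsAsFactors = FALSE)
    }
    out <- list(pred_a = do.call(rbind, pa), pred_b = do.call(rbind, pb),
                validated = do.call(rbind, va), genes = genes)
    rownames(out$pred_a) <- rownames(out$pred_b) <-
      rownames(out$validated) <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(out$pred_a, file.path(dir, "pred_a.tsv"))
      write_tsv(out$pred_b, file.path(dir, "pred_b.tsv"))
      write_tsv(out$validated, file.path(dir, "validated.tsv"))
    }
    out
  })
}

#' Generate category annotation sets with planted enrichment
#'
#' Builds `n_categories` gene sets over a universe. For each planted
#' (miRNA, category) pair the category over-samples that miRNA's target
#' genes by `overrep_fold` relative to the null expectation; all other
#' categories are uniform draws from the universe.
#'
#' @param genes Gene universe (character).
#' @param n_categories Number of categories.
#' @param targets Named list or `integrated_targets`, miRNA -> gene set
#'   (needed when `planted_pairs` is non-empty).
#' @param planted_pairs Data frame with columns `mirna`, `category`
#'   (category index or name) naming planted enriched pairs.
#' @param category_size Genes per category.
#' @param overrep_fold Planted over-representation factor.
#' @param seed Integer seed.
#' @param path Optional GMT output path.
#' @return Named list of gene sets (class `gmt`), with attribute
#'   `planted_pairs`.
#' @export
generate_annotation_sets <- function(genes, n_categories = 50,
                                     targets = NULL, planted_pairs = NULL,
                                     category_size = 50, overrep_fold = 5,
                                     seed = 1L, path = NULL) {
  if (category_size > length(genes))
    stop("category size ", category_size, " exceeds universe of ",
         length(genes), " genes")
  cat_names <- sprintf("CAT%04d", seq_len(n_categories))
  if (!is.null(planted_pairs)) {
    planted_pairs$category <- ifelse(
      grepl("^CAT", planted_pairs$category), planted_pairs$category,
      cat_names[as.integer(planted_pairs$category)])
    tg <- if (inherits(targets, "integrated_targets")) targets$sets else targets
    missing_m <- setdiff(planted_pairs$mirna, names(tg))
    if (length(missing_m))
      stop("planted pairs reference miRNAs without target sets: ",
           paste(missing_m, collapse = ", "))
  }
  with_seed(seed, {
    sets <- lapply(cat_names, function(cn) sample(genes, category_size))
    names(sets) <- cat_names
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        cn <- planted_pairs$category[i]
        tset <- intersect(tg[[planted_pairs$mirna[i]]], genes)
        null_k <- category_size * length(tset) / length(genes)
        k <- min(length(tset), category_size,
                 max(1L, round(overrep_fold * null_k)))
        hit <- sample(tset, k)
        rest <- sample(setdiff(genes, hit), category_size - k)
        sets[[cn]] <- sample(c(hit, rest))
      }
    }
    structure(sets, planted_pairs = planted_pairs, class = "gmt")
  }) -> sets
  if (!is.null(path)) write_gmt(unclass(sets), path)
  sets
}

#' Generate a sparse PPI graph and a TF direct-target gene list
#'
#' Samples an Erdos-Renyi G(n, p) undirected simple graph over the gene
#' universe (no self-loops) and a random subset of genes as direct
#' transcription-factor targets.
#'
#' @param genes Gene universe.
#' @param edge_density Edge probability in (0, 1].
#' @param n_p53_targets Number of TF direct-target genes to sample.
#' @param seed Integer seed.
#' @param dir Optional directory to write `ppi.tsv` and
#'   `p53_targets.tsv`.
#' @return List with `ppi` (data frame `gene_a`, `gene_b`) and
#'   `p53_targets` (character vector).
#' @export
generate_ppi_and_p53_targets <- function(genes, edge_density = 0.01,
                                         n_p53_targets = 50, seed = 1L,
                                         dir = NULL) {
  stopifnot(edge_density > 0, edge_density <= 1)
  if (n_p53_targets > length(genes))
    stop("requested ", n_p53_targets, " TF targets from a universe of ",
         length(genes), " genes")
  with_seed(seed, {
    g <- igraph::sample_gnp(length(genes), edge_density, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ppi <- data.frame(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]],
                      stringsAsFactors = FALSE)
    p53 <- sort(sample(genes, n_p53_targets))
    out <- list(ppi = ppi, p53_targets = p53)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv(ppi, file.path(dir, "ppi.tsv"))
      write_tsv(data.frame(gene = p53), file.path(dir, "p53_targets.tsv"))
    }
    out
  })
}
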