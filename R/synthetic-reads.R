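# Default small-RNA library adapters (classic single-end small-RNA kit).
DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
DEFAULT_ADAPTER3 <- "TCGTATGCCGTCTTCTGCTTG"

# paste a character matrix (n x width) row-wise into strings
paste_rows <- function(mat) {
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

random_dna_vec <- function(n, width) {
  if (n == 0L) return(character(0))
  paste_rows(matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                    nrow = n))
}

random_qual_vec <- function(n, width, qmin, qmax) {
  if (n == 0L) return(character(0))
  chars <- intToUtf8(33L + qmin:qmax, multiple = TRUE)
  paste_rows(matrix(sample(chars, n * width, replace = TRUE), nrow = n))
}

#' Simulate four small-RNA sequencing libraries with planted truth
#'
#' Generates raw 50-nt sequencing tags for a two-condition, two-replicate
#' design (control/treated). Clean tags carry a mature-miRNA insert
#' followed by the 3' adapter; miRNA abundances follow a log-normal base
#' profile shared across libraries, with the treated condition scaled by
#' the planted per-miRNA fold changes. A configurable fraction of clean
#' tags carries non-miRNA small-RNA inserts (background species), and
#' contaminant classes (low quality, 5' adapter contaminant, missing 3'
#' adapter, empty insert, polyA, out-of-bounds insert length) are injected
#' mutually exclusively per read at the planted rates.
#'
#' @param reference A `mirna_reference`.
#' @param truth A `synthetic_truth` carrying `planted_log2fc` and
#'   `contamination_rates`.
#' @param n_reads Reads per library (>= 1000 for stable fractions).
#' @param seed Integer seed; the full output is deterministic given it.
#' @param outdir Optional directory; when given, one FASTQ per library and
#'   a `truth.json` are written there.
#' @param other_frac Fraction of non-contaminant reads drawn from
#'   background (non-miRNA) small RNA species.
#' @param abundance_sdlog Log-sd of the log-normal base abundance profile.
#' @param induced_baseline Factor scaling the control-condition baseline
#'   of miRNAs with positive planted fold change (induced miRNAs start
#'   low, as stress-induced miRNA programs do; this also keeps the two
#'   conditions' total miRNA abundance comparable so relative
#'   normalization does not distort the planted effects).
#' @param adapter5,adapter3 Adapter sequences used to assemble the tags.
#' @return List with `libraries` (named list of read data frames),
#'   `design` (library/condition/replicate table), `planted_class_counts`
#'   (class x library matrix), `base_weights`, and `files` when written.
#' @export
generate_read_libraries <- function(reference, truth, n_reads = 100000,
                                    seed = 1L, outdir = NULL,
                                    other_frac = 0.3,
                                    abundance_sdlog = 1,
                                    induced_baseline = 0.15,
                                    adapter5 = DEFAULT_ADAPTER5,
                                    adapter3 = DEFAULT_ADAPTER3) {
  stopifnot(inherits(reference, "mirna_reference"),
            inherits(truth, "synthetic_truth"), n_reads >= 1000)
  mir <- reference$mirnas
  fc <- truth$planted_log2fc
  unknown <- setdiff(names(fc), mir$mirna)
  if (length(unknown))
    stop("planted fold change references unknown miRNA: ",
         paste(unknown, collapse = ", "))
  full_fc <- stats::setNames(rep(0, nrow(mir)), mir$mirna)
  full_fc[names(fc)] <- fc

  rates <- truth$contamination_rates
  classes <- c("low_quality", "adapter5_contaminant", "no_adapter3",
               "no_insert", "polyA", "length_out_of_bounds")
  full_rates <- stats::setNames(rep(0, length(classes)), classes)
  full_rates[names(rates)] <- rates
  clean_p <- 1 - sum(full_rates)
  probs <- c(full_rates, other = clean_p * other_frac,
             mirna = clean_p * (1 - other_frac))

  design <- data.frame(
    library = c("control_rep1", "control_rep2",
                "treated_rep1", "treated_rep2"),
    condition = c("control", "control", "treated", "treated"),
    replicate = c(1L, 2L, 1L, 2L), stringsAsFactors = FALSE)

  width <- 50L
  a8 <- substr(adapter3, 1L, 8L)
  a5_8 <- substr(adapter5, 1L, 8L)

  with_seed(seed, {
    w <- stats::setNames(rlnorm(nrow(mir), meanlog = 0,
                                sdlog = abundance_sdlog), mir$mirna)
    w[full_fc > 0] <- w[full_fc > 0] * induced_baseline
    libs <- list()
    planted <- matrix(0L, nrow = length(probs), ncol = nrow(design),
                      dimnames = list(names(probs), design$library))
    for (li in seq_len(nrow(design))) {
      cond <- design$condition[li]
      wl <- if (cond == "treated") w * 2^full_fc else w
      cls <- sample(names(probs), n_reads, replace = TRUE, prob = probs)
      planted[, li] <- tabulate(factor(cls, levels = names(probs)),
                                nbins = length(probs))
      seqs <- character(n_reads)
      fill <- random_dna_vec(n_reads, 30L)

      i <- cls %in% c("mirna", "low_quality")
      if (any(i)) {
        m <- sample(mir$mirna, sum(i), replace = TRUE, prob = wl)
        seqs[i] <- paste0(mir$mature_seq[match(m, mir$mirna)], adapter3)
      }
      i <- cls == "other"
      if (any(i)) {
        len <- sample(20:24, sum(i), replace = TRUE)
        seqs[i] <- paste0(substr(random_dna_vec(sum(i), 24L), 1L, len),
                          adapter3)
      }
      i <- cls == "adapter5_contaminant"
      if (any(i))
        seqs[i] <- paste0(substr(adapter5, 1L, 10L),
                          substr(random_dna_vec(sum(i), 22L), 1L, 22L),
                          adapter3)
      i <- cls == "no_adapter3"
      if (any(i)) {
        s <- random_dna_vec(sum(i), width)
        bad <- grepl(a8, s, fixed = TRUE) | startsWith(s, a5_8)
        while (any(bad)) {
          s[bad] <- random_dna_vec(sum(bad), width)
          bad <- grepl(a8, s, fixed = TRUE) | startsWith(s, a5_8)
        }
        seqs[i] <- s
      }
      i <- cls == "no_insert"
      if (any(i)) seqs[i] <- adapter3
      i <- cls == "polyA"
      if (any(i)) seqs[i] <- paste0(strrep("A", 22L), adapter3)
      i <- cls == "length_out_of_bounds"
      if (any(i)) {
        len <- sample(c(10:15, 31:36), sum(i), replace = TRUE)
        seqs[i] <- paste0(substr(random_dna_vec(sum(i), 36L), 1L, len),
                          adapter3)
      }
      seqs <- substr(paste0(seqs, fill, fill), 1L, width)
      qual <- random_qual_vec(n_reads, width, 30L, 40L)
      i <- cls == "low_quality"
      if (any(i)) qual[i] <- random_qual_vec(sum(i), width, 5L, 18L)

      lib <- design$library[li]
      libs[[lib]] <- data.frame(
        id = sprintf("%s:%06d", lib, seq_len(n_reads)),
        seq = seqs, qual = qual, stringsAsFactors = FALSE)
    }

    out <- list(libraries = libs, design = design,
                planted_class_counts = planted, base_weights = w,
                planted_log2fc = full_fc)
    if (!is.null(outdir)) {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      files <- character(0)
      for (lib in design$library) {
        fp <- file.path(outdir, paste0(lib, ".fastq"))
        write_fastq(libs[[lib]], fp)
        files[lib] <- fp
      }
      tj <- file.path(outdir, "truth.json")
      jsonlite::write_json(list(
        seed = truth$seed,
        planted_log2fc = as.list(full_fc),
        contamination_rates = as.list(full_rates),
        bound_mirnas = truth$bound_mirnas,
        multi_bound = truth$multi_bound,
        planted_class_counts = as.data.frame(planted)),
        tj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files["truth"] <- tj
      out$files <- files
    }
    out
  })
}
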