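#' Library-size normalization to reads per million
#'
#' Each count is scaled to reads per million clean reads of its library.
#' Stored values keep zeros; for fold-change computation zeros are
#' replaced by a small pseudo-expression (see [differential_table()]).
#'
#' @param counts A `count_table` (or an integer matrix with a `totals`
#'   attribute / argument).
#' @param totals Clean-read totals per library (taken from the
#'   `count_table` when omitted).
#' @return Numeric matrix of RPM values, same shape as the counts.
#' @export
normalize_counts <- function(counts, totals = NULL) {
  if (inherits(counts, "count_table")) {
    totals <- counts$totals
    counts <- counts$counts
  }
  if (is.null(totals)) stop("library totals are required")
  if (any(totals <= 0)) stop("library total must be positive")
  sweep(counts, 2L, totals, "/") * 1e6
}

#' Exact two-library count test (Audic-Claverie)
#'
#' Probability model for observing `y` tags of a transcript in a library
#' of `N2` total tags given `x` tags in a library of `N1`:
#' \deqn{p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^{x+y+1})}
#' evaluated in log-gamma space. The two-sided p-value doubles the
#' smaller of the lower tail \eqn{\sum_{k \le y} p(k|x)} and the upper
#' tail (computed as the complement of a finite lower sum), capped at 1.
#'
#' @param x,y Observed counts (non-negative integers; vectorized).
#' @param N1,N2 Library totals (positive).
#' @return Two-sided p-value(s) in (0, 1].
#' @export
audic_claverie_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n), function(i)
    ac_pvalue_one(x[i], y[i], N1[i], N2[i]), numeric(1))
}

ac_pvalue_one <- function(x, y, N1, N2) {
  r <- N2 / N1
  logterm <- function(k)
    k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * log1p(r)
  lower <- exp(logsumexp(logterm(0:y)))
  if (lower < 0.5) {
    # complement of the finite lower sum is accurate here
    upper <- if (y == 0) 1 else 1 - exp(logsumexp(logterm(0:(y - 1))))
  } else {
    # small upper tail: sum it directly in log space (the complement
    # would cancel catastrophically)
    lterm <- logterm(y)
    lsum <- lterm
    k <- y
    repeat {
      k <- k + 1
      lterm <- lterm + log(r) + log(x + k) - log(k) - log1p(r)
      hi <- max(lsum, lterm); lo <- min(lsum, lterm)
      lsum <- hi + log1p(exp(lo - hi))
      if ((lterm < lsum - 40 && k > y + 10) || k > y + 1000000L) break
    }
    upper <- exp(lsum)
  }
  p <- min(1, 2 * min(lower, upper))
  max(p, .Machine$double.xmin)
}

#' Differential expression table for one control/treated library pair
#'
#' Computes per-miRNA RPM, log2 fold change (treated over control, with a
#' pseudo-expression replacing zero RPM in the ratio only), the exact
#' two-library p-value and its Benjamini-Hochberg adjustment across all
#' miRNAs of the comparison.
#'
#' @param counts A `count_table` containing both libraries.
#' @param control,treated Library names within the table.
#' @param pseudo_rpm Pseudo-expression (RPM) substituted for zeros in the
#'   fold-change ratio (default 0.01).
#' @param adjust Multiple-testing method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Data frame with one row per miRNA: `mirna`, `count_control`,
#'   `count_treated`, `norm_control`, `norm_treated`, `log2fc`, `p`,
#'   `p_adjusted`.
#' @export
differential_table <- function(counts, control, treated,
                               pseudo_rpm = 0.01, adjust = "BH") {
  stopifnot(inherits(counts, "count_table"))
  if (!all(c(control, treated) %in% counts$libraries))
    stop("control/treated library not present in the count table")
  x <- counts$counts[, control]
  y <- counts$counts[, treated]
  N1 <- counts$totals[[control]]
  N2 <- counts$totals[[treated]]
  rpm1 <- x / N1 * 1e6
  rpm2 <- y / N2 * 1e6
  log2fc <- log2(pmax(rpm2, pseudo_rpm) / pmax(rpm1, pseudo_rpm))
  p <- audic_claverie_pvalue(x, y, N1, N2)
  data.frame(mirna = rownames(counts$counts),
             count_control = as.integer(x), count_treated = as.integer(y),
             norm_control = rpm1, norm_treated = rpm2,
             log2fc = log2fc, p = p,
             p_adjusted = p.adjust(p, method = adjust),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Selection thresholds for robustly differential miRNAs
#'
#' @param min_abs_log2fc Minimum |log2 fold change|, required with a
#'   consistent sign in both replicate comparisons (default 1).
#' @param min_reads Raw read count that must be exceeded in at least one
#'   of the four samples (default 10, strict inequality).
#' @param max_p Raw p-value bound required in at least one replicate
#'   comparison (default 0.01, strict inequality).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(min_abs_log2fc = 1, min_reads = 10,
                               max_p = 0.01) {
  stopifnot(min_abs_log2fc > 0, min_reads > 0, max_p > 0)
  structure(list(min_abs_log2fc = min_abs_log2fc, min_reads = min_reads,
                 max_p = max_p), class = "selection_criteria")
}

#' Select robustly differentially expressed miRNAs across two replicates
#'
#' A miRNA is selected iff (1) |log2 fold change| exceeds the threshold
#' with the same sign in both replicate comparisons, (2) its raw count
#' exceeds `min_reads` in at least one of the four samples, and (3) its
#' raw p-value is below `max_p` in at least one replicate comparison.
#' miRNAs passing the fold-change magnitude in both replicates with
#' opposite signs are excluded (recorded in the `sign_conflicts`
#' attribute). When the replicate tables carry no count columns the count
#' criterion is treated as satisfied.
#'
#' @param rep1,rep2 Per-replicate data frames with columns `mirna`,
#'   `log2fc`, `p` and optionally `count_control`, `count_treated`
#'   ([differential_table()] output, or the packaged DEM table via
#'   [table1_replicates()]).
#' @param criteria A [selection_criteria()].
#' @return A `dem_set` data frame: `mirna`, `log2fc_rep1`, `log2fc_rep2`,
#'   `p_rep1`, `p_rep2`, `direction` ("up"/"down"), with attribute
#'   `sign_conflicts`.
#' @export
apply_selection_criteria <- function(rep1, rep2,
                                     criteria = selection_criteria()) {
  if (!setequal(rep1$mirna, rep2$mirna))
    stop("replicate comparisons cover different miRNA universes")
  rep2 <- rep2[match(rep1$mirna, rep2$mirna), ]
  fc1 <- rep1$log2fc; fc2 <- rep2$log2fc
  big <- abs(fc1) > criteria$min_abs_log2fc &
    abs(fc2) > criteria$min_abs_log2fc
  same_sign <- sign(fc1) == sign(fc2)
  conflicts <- rep1$mirna[big & !same_sign]

  if (!is.null(rep1$count_control)) {
    reads_ok <- pmax(rep1$count_control, rep1$count_treated,
                     rep2$count_control, rep2$count_treated) >
      criteria$min_reads
  } else reads_ok <- TRUE

  p_ok <- rep1$p < criteria$max_p | rep2$p < criteria$max_p
  keep <- big & same_sign & reads_ok & p_ok
  out <- data.frame(mirna = rep1$mirna[keep],
                    log2fc_rep1 = fc1[keep], log2fc_rep2 = fc2[keep],
                    p_rep1 = rep1$p[keep], p_rep2 = rep2$p[keep],
                    direction = ifelse(fc1[keep] > 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sign_conflicts") <- conflicts
  class(out) <- c("dem_set", class(out))
  out
}

#' Split the packaged DEM table into two replicate comparison tables
#'
#' @param table1 Output of [load_table1_fixture()].
#' @return List with `rep1` and `rep2` data frames (`mirna`, `log2fc`,
#'   `p`), suitable for [apply_selection_criteria()].
#' @export
table1_replicates <- function(table1 = load_table1_fixture()) {
  list(rep1 = data.frame(mirna = table1$mirna, log2fc = table1$log2fc_rep1,
                         p = table1$p_rep1, stringsAsFactors = FALSE),
       rep2 = data.frame(mirna = table1$mirna, log2fc = table1$log2fc_rep2,
                         p = table1$p_rep2, stringsAsFactors = FALSE))
}

#' Cluster selected miRNAs by their replicate fold-change profile
#'
#' Agglomerative hierarchical clustering (Ward linkage on Euclidean
#' distances) of the miRNA x replicate log2 fold-change matrix, cut at
#' two clusters. Cluster 1 is the cluster with the higher mean fold
#' change (the induced group). Only the k = 2 partition is contractual;
#' leaf order is reported for heatmap display.
#'
#' @param dems A `dem_set` (or a numeric matrix of log2 fold changes with
#'   miRNA rownames).
#' @param linkage Agglomeration method for [stats::hclust()]
#'   (default `"ward.D2"`).
#' @return List with `cluster` (named integer vector, 1 = induced),
#'   `order` (leaf order of miRNA names) and `hclust` (the tree).
#' @export
cluster_dems <- function(dems, linkage = "ward.D2") {
  if (is.data.frame(dems)) {
    m <- as.matrix(dems[, c("log2fc_rep1", "log2fc_rep2")])
    rownames(m) <- dems$mirna
  } else m <- dems
  if (nrow(m) < 2L) {
    warning("fewer than two miRNAs: degenerate single cluster")
    return(list(cluster = stats::setNames(rep(1L, nrow(m)), rownames(m)),
                order = rownames(m), hclust = NULL))
  }
  hc <- hclust(dist(m), method = linkage)
  cl <- cutree(hc, k = 2L)
  means <- tapply(rowMeans(m), cl, mean)
  relabel <- if (means[["1"]] >= means[["2"]]) c(1L, 2L) else c(2L, 1L)
  list(cluster = stats::setNames(relabel[cl], rownames(m)),
       order = rownames(m)[hc$order], hclust = hc)
}
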