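#' Integrate predicted and validated miRNA target gene sets
#'
#' Per miRNA the integrated set is (predA intersect predB) union
#' validated, with provenance per gene: `predicted_both`, `validated`, or
#' `both` when a gene is in the prediction intersection and validated.
#'
#' @param pred_a,pred_b Prediction tables, data frames keyed by
#'   (`mirna`, `gene`).
#' @param validated Validated-interaction table, same columns (optional).
#' @return An `integrated_targets` object: list with `table` (data frame
#'   `mirna`, `gene`, `provenance`) and `sets` (named list miRNA -> gene
#'   vector).
#' @export
integrate_targets <- function(pred_a, pred_b, validated = NULL) {
  mirnas <- sort(unique(c(pred_a$mirna, pred_b$mirna,
                          if (!is.null(validated)) validated$mirna)))
  rows <- list()
  for (m in mirnas) {
    a <- unique(pred_a$gene[pred_a$mirna == m])
    b <- unique(pred_b$gene[pred_b$mirna == m])
    v <- if (!is.null(validated)) unique(validated$gene[validated$mirna == m])
    else character(0)
    ab <- intersect(a, b)
    genes <- union(ab, v)
    if (length(genes) == 0L) {
      warning("miRNA ", m, " has an empty integrated target set")
      next
    }
    prov <- ifelse(genes %in% ab & genes %in% v, "both",
                   ifelse(genes %in% ab, "predicted_both", "validated"))
    rows[[m]] <- data.frame(mirna = m, gene = sort(genes),
                            provenance = prov[order(genes)],
                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene = character(),
               provenance = character(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  sets <- split(tab$gene, tab$mirna)
  structure(list(table = tab, sets = sets), class = "integrated_targets")
}

#' Hypergeometric over-representation test against gene-set categories
#'
#' For each category the upper-tail hypergeometric probability
#' \eqn{P(X \ge k)} of observing `k` query genes in a category of size
#' `K` drawn from a universe of `N` genes with a query of size `n`,
#' followed by Benjamini-Hochberg adjustment across the categories tested
#' for this query.
#'
#' @param query Character vector of query genes (subset of `universe`;
#'   genes outside it are dropped with a warning).
#' @param categories Named list of gene sets (e.g. [read_gmt()]).
#' @param universe Background gene universe.
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return Data frame: `category`, `k`, `n`, `K`, `N`, `p`, `p_adjusted`,
#'   `significant`, ordered by `p`.
#' @export
enrich <- function(query, categories, universe, alpha = 0.05) {
  if (length(universe) == 0L) stop("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0L) stop("empty query gene set")
  N <- length(unique(universe))
  n <- length(query)
  cats <- lapply(categories, function(g) intersect(unique(g), universe))
  K <- vapply(cats, length, integer(1))
  k <- vapply(cats, function(g) length(intersect(g, query)), integer(1))
  # upper tail P(X >= k)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = names(categories), k = k, n = n, K = K,
                    N = N, p = p, p_adjusted = p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted < alpha
  out[order(out$p, out$category), , drop = FALSE]
}

#' Run enrichment for every miRNA target set (and the pooled union)
#'
#' @param targets An `integrated_targets` object.
#' @param categories Named list of gene sets.
#' @param universe Gene universe; default: genes in the categories
#'   intersected with the target-table gene space.
#' @param alpha Adjusted-p significance level.
#' @param pooled Also test the union of all target sets under the name
#'   `"pooled"` (default TRUE).
#' @return Named list of [enrich()] results per miRNA (plus `"pooled"`).
#' @export
enrich_targets <- function(targets, categories, universe = NULL,
                           alpha = 0.05, pooled = TRUE) {
  stopifnot(inherits(targets, "integrated_targets"))
  if (is.null(universe))
    universe <- intersect(unique(unlist(categories)),
                          unique(targets$table$gene))
  res <- lapply(targets$sets, function(g) {
    g <- intersect(g, universe)
    if (length(g) == 0L) return(NULL)
    enrich(g, categories, universe, alpha)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (pooled) {
    all_g <- intersect(unique(targets$table$gene), universe)
    if (length(all_g)) res$pooled <- enrich(all_g, categories, universe, alpha)
  }
  res
}

#' Heatmap-ready miRNA x category matrix of adjusted p-values
#'
#' @param results Named list of per-miRNA [enrich()] results.
#' @param value Column to tabulate (default `"p_adjusted"`).
#' @return Numeric matrix (sorted miRNA rows x sorted category columns);
#'   pairs never tested are NA.
#' @export
enrichment_matrix <- function(results, value = "p_adjusted") {
  if (length(results) == 0L) stop("no enrichment results")
  mirnas <- sort(names(results))
  cats <- sort(unique(unlist(lapply(results, `[[`, "category"))))
  mat <- matrix(NA_real_, length(mirnas), length(cats),
                dimnames = list(mirnas, cats))
  for (m in mirnas) {
    r <- results[[m]]
    mat[m, r$category] <- r[[value]]
  }
  mat
}

#' Count miRNAs with at least one significant category
#'
#' @param results Named list of per-miRNA [enrich()] results (the pooled
#'   entry, if present, is ignored).
#' @return Integer count.
#' @export
n_mirnas_enriched <- function(results) {
  results <- results[setdiff(names(results), "pooled")]
  sum(vapply(results, function(r) any(r$significant), logical(1)))
}
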