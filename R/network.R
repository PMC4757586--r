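#' Assemble the typed TF-miRNA-gene regulatory network
#'
#' Nodes are typed `TF`, `miRNA` or `gene`. Directed edges: `tf_mirna`
#' (only for selected miRNAs with at least one promoter binding site,
#' signed by the miRNA's expression direction), `mirna_gene` (from the
#' integrated target sets of those miRNAs) and `tf_gene` (from the
#' supplied TF direct-target gene list, restricted to genes already in
#' the network). Undirected `ppi` edges are decorative context between
#' network genes and take no part in loop finding.
#'
#' @param dems A `dem_set` (selected miRNAs with `direction`).
#' @param bound_mirnas Character vector of miRNAs with promoter binding
#'   sites, or a [find_binding_sites()] data frame.
#' @param targets An `integrated_targets` object.
#' @param p53_targets Character vector of TF direct-target genes.
#' @param ppi Optional data frame of undirected gene-gene edges
#'   (`gene_a`, `gene_b`).
#' @param tf Name of the transcription factor node (default `"TP53"`).
#' @return A `regulatory_network`: list with `nodes` (data frame `name`,
#'   `type`, `direction`) and `edges` (data frame `from`, `to`, `type`,
#'   `sign`).
#' @export
build_network <- function(dems, bound_mirnas, targets, p53_targets,
                          ppi = NULL, tf = "TP53") {
  if (is.data.frame(bound_mirnas)) bound_mirnas <- unique(bound_mirnas$mirna)
  bad <- setdiff(bound_mirnas, dems$mirna)
  if (length(bad))
    stop("bound miRNAs absent from the DEM set: ",
         paste(bad, collapse = ", "))
  mirnas <- sort(intersect(bound_mirnas, dems$mirna))
  tsets <- targets$sets[intersect(mirnas, names(targets$sets))]
  genes <- sort(unique(unlist(tsets)))

  e_tm <- if (length(mirnas)) data.frame(
    from = tf, to = mirnas, type = "tf_mirna",
    sign = dems$direction[match(mirnas, dems$mirna)],
    stringsAsFactors = FALSE) else NULL
  e_mg <- if (length(tsets)) do.call(rbind, lapply(names(tsets), function(m)
    data.frame(from = m, to = sort(unique(tsets[[m]])), type = "mirna_gene",
               sign = NA_character_, stringsAsFactors = FALSE))) else NULL
  tg <- sort(intersect(setdiff(p53_targets, tf), genes))
  e_tg <- if (length(tg)) data.frame(from = tf, to = tg, type = "tf_gene",
                                     sign = NA_character_,
                                     stringsAsFactors = FALSE) else NULL
  e_pp <- NULL
  if (!is.null(ppi) && nrow(ppi)) {
    keep <- ppi$gene_a %in% genes & ppi$gene_b %in% genes &
      ppi$gene_a != ppi$gene_b
    if (any(keep)) {
      a <- pmin(ppi$gene_a[keep], ppi$gene_b[keep])
      b <- pmax(ppi$gene_a[keep], ppi$gene_b[keep])
      u <- !duplicated(paste(a, b))
      e_pp <- data.frame(from = a[u], to = b[u], type = "ppi",
                         sign = NA_character_, stringsAsFactors = FALSE)
    }
  }
  edges <- rbind(e_tm, e_mg, e_tg, e_pp)
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        type = character(), sign = character(),
                        stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("from", "to", "type")]), ]
  edges <- edges[order(edges$type, edges$from, edges$to), ]
  rownames(edges) <- NULL

  # genes targeted by many miRNAs are flagged for display (cf. network
  # figures where 4- and 5-miRNA targets are colour-coded)
  tmult <- table(unlist(lapply(tsets, unique)))
  nodes <- rbind(
    data.frame(name = tf, type = "TF", direction = NA_character_,
               multiplicity = NA_integer_, stringsAsFactors = FALSE),
    if (length(mirnas)) data.frame(
      name = mirnas, type = "miRNA",
      direction = dems$direction[match(mirnas, dems$mirna)],
      multiplicity = NA_integer_, stringsAsFactors = FALSE),
    if (length(genes)) data.frame(
      name = genes, type = "gene", direction = NA_character_,
      multiplicity = as.integer(tmult[genes]), stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, tf = tf),
            class = "regulatory_network")
}

#' Enumerate miRNA-mediated feed-forward loops
#'
#' A feed-forward loop is a triple (TF, miRNA, gene) where the TF
#' regulates the miRNA (`tf_mirna`), the TF regulates the gene
#' (`tf_gene`) and the miRNA targets the same gene (`mirna_gene`).
#' Self-regulation (gene equal to the TF) is excluded. Enumeration is
#' exact and the output deterministically sorted.
#'
#' @param network A `regulatory_network`.
#' @return Data frame `tf`, `mirna`, `gene` (zero rows when none).
#' @export
enumerate_ffls <- function(network) {
  e <- network$edges
  tm <- e[e$type == "tf_mirna", ]
  tg <- e[e$type == "tf_gene", ]
  mg <- e[e$type == "mirna_gene", ]
  out <- list()
  for (i in seq_len(nrow(tm))) {
    tf <- tm$from[i]; m <- tm$to[i]
    tfg <- tg$to[tg$from == tf]
    common <- intersect(mg$to[mg$from == m], setdiff(tfg, tf))
    if (length(common))
      out[[length(out) + 1L]] <- data.frame(tf = tf, mirna = m,
                                            gene = common,
                                            stringsAsFactors = FALSE)
  }
  ffl <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(), mirna = character(), gene = character(),
               stringsAsFactors = FALSE)
  ffl <- ffl[order(ffl$tf, ffl$mirna, ffl$gene), ]
  rownames(ffl) <- NULL
  ffl
}

#' Export a regulatory network to SIF or GraphML
#'
#' SIF writes one `source<TAB>edge-type<TAB>target` line per typed edge,
#' with node and edge attribute TSVs alongside; GraphML (via igraph)
#' carries all attributes in one file. Both round-trip through
#' [import_network()].
#'
#' @param network A `regulatory_network`.
#' @param path Output path; for SIF, `<path>.sif`,
#'   `<path>_node_attributes.tsv` and `<path>_edge_attributes.tsv` are
#'   written, for GraphML `<path>.graphml`.
#' @param fmt `"SIF"` or `"GraphML"`.
#' @return Character vector of written paths, invisibly.
#' @export
export_network <- function(network, path, fmt = c("SIF", "GraphML")) {
  fmt <- match.arg(fmt)
  nodes <- network$nodes; edges <- network$edges
  if (fmt == "SIF") {
    sif <- file.path(paste0(path, ".sif"))
    writeLines(if (nrow(edges))
      paste(edges$from, edges$type, edges$to, sep = "\t") else character(0),
      sif)
    np <- paste0(path, "_node_attributes.tsv")
    ep <- paste0(path, "_edge_attributes.tsv")
    write_tsv(nodes, np)
    write_tsv(edges, ep)
    invisible(c(sif, np, ep))
  } else {
    g <- network_to_igraph(network)
    gp <- paste0(path, ".graphml")
    igraph::write_graph(g, gp, format = "graphml")
    invisible(gp)
  }
}

#' Re-import a network exported by [export_network()]
#'
#' @param path The same base path (SIF) or `.graphml` file (GraphML)
#'   given to [export_network()].
#' @param fmt `"SIF"` or `"GraphML"`.
#' @return A `regulatory_network` identical to the exported one.
#' @export
import_network <- function(path, fmt = c("SIF", "GraphML")) {
  fmt <- match.arg(fmt)
  if (fmt == "SIF") {
    nodes <- read_tsv(paste0(path, "_node_attributes.tsv"),
                      colClasses = c(name = "character"))
    edges <- read_tsv(paste0(path, "_edge_attributes.tsv"),
                      colClasses = c(from = "character", to = "character"))
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    va <- igraph::vertex_attr(g)
    nodes <- data.frame(name = va$name, type = va$type,
                        direction = va$direction,
                        multiplicity = va$multiplicity,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    ea <- igraph::edge_attr(g)
    edges <- data.frame(from = el[, 1], to = el[, 2], type = ea$type,
                        sign = ea$sign, stringsAsFactors = FALSE)
    edges <- edges[order(edges$type, edges$from, edges$to), ]
    nodes <- nodes[order(match(nodes$type, c("TF", "miRNA", "gene")),
                         nodes$name), ]
  }
  nodes$direction <- as.character(nodes$direction)
  nodes$direction[nodes$direction %in% c("", "NA")] <- NA_character_
  nodes$multiplicity <- suppressWarnings(as.integer(nodes$multiplicity))
  nodes$multiplicity[!is.na(nodes$multiplicity) & nodes$multiplicity < 0] <-
    NA_integer_
  edges$sign <- as.character(edges$sign)
  edges$sign[edges$sign %in% c("", "NA")] <- NA_character_
  rownames(nodes) <- rownames(edges) <- NULL
  tf <- nodes$name[nodes$type == "TF"][1]
  structure(list(nodes = nodes, edges = edges, tf = tf),
            class = "regulatory_network")
}

network_to_igraph <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  nodes$direction[is.na(nodes$direction)] <- "NA"
  nodes$multiplicity[is.na(nodes$multiplicity)] <- -1L
  edges$sign[is.na(edges$sign)] <- "NA"
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  print(table(x$nodes$type))
  print(table(x$edges$type))
  invisible(x)
}
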