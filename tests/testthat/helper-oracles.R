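# Independent oracles used across the suite. Each is deliberately written
# by a different route than the package implementation.

# two-library count test by direct term summation with the multiplicative
# recurrence p(k|x) = p(k-1|x) * r (x+k) / (k (1+r)), p(0|x) = (1+r)^-(x+1)
ac_oracle <- function(x, y, N1, N2) {
  r <- N2 / N1
  terms <- numeric(y + 1)
  terms[1] <- (1 + r)^(-(x + 1))
  if (y > 0) for (k in 1:y)
    terms[k + 1] <- terms[k] * r * (x + k) / (k * (1 + r))
  lower <- sum(terms)
  if (lower < 0.5) {
    upper <- if (y == 0) 1 else 1 - sum(terms[1:y])
  } else {
    # continue the recurrence upward until the remainder is negligible
    upper <- terms[y + 1]
    term <- terms[y + 1]
    k <- y
    repeat {
      k <- k + 1
      term <- term * r * (x + k) / (k * (1 + r))
      upper <- upper + term
      if ((term < upper * 1e-18 && k > y + 10) || k > y + 1000000) break
    }
  }
  min(1, 2 * min(lower, max(upper, 0)))
}

# Benjamini-Hochberg step-up by explicit sorting
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# quadratic all-pairs interval overlap (0-based half-open)
overlap_oracle <- function(promoters, peaks, min_overlap = 1L) {
  hits <- list()
  for (i in seq_len(nrow(promoters))) for (j in seq_len(nrow(peaks))) {
    if (promoters$chrom[i] != peaks$chrom[j]) next
    ov <- min(promoters$end0[i], peaks$end0[j]) -
      max(promoters$start0[i], peaks$start0[j])
    if (ov >= min_overlap)
      hits[[length(hits) + 1L]] <- data.frame(
        mirna = promoters$mirna[i], chrom = peaks$chrom[j],
        peak_start0 = peaks$start0[j], peak_end0 = peaks$end0[j],
        stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna = character(), chrom = character(),
               peak_start0 = integer(), peak_end0 = integer())
}

# cubic brute-force feed-forward loop enumeration over typed edge lists
ffl_oracle <- function(edges) {
  tm <- edges[edges$type == "tf_mirna", ]
  tg <- edges[edges$type == "tf_gene", ]
  mg <- edges[edges$type == "mirna_gene", ]
  out <- list()
  for (i in seq_len(nrow(tm))) for (j in seq_len(nrow(tg)))
    for (k in seq_len(nrow(mg))) {
      if (tm$from[i] == tg$from[j] && tm$to[i] == mg$from[k] &&
          tg$to[j] == mg$to[k] && tg$to[j] != tg$from[j])
        out[[length(out) + 1L]] <- data.frame(
          tf = tm$from[i], mirna = tm$to[i], gene = tg$to[j],
          stringsAsFactors = FALSE)
    }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(tf = character(), mirna = character(), gene = character())
  res <- res[order(res$tf, res$mirna, res$gene), ]
  rownames(res) <- NULL
  res
}

# brute-force sliding-window <=max_mismatch read alignment (both strands)
map_oracle <- function(seqs, reference, max_mismatch = 1L) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  out <- list()
  for (ci in seq_along(reference)) {
    refc <- strsplit(reference[[ci]], "")[[1]]
    for (ri in seq_along(seqs)) {
      for (str in c("+", "-")) {
        s <- if (str == "+") seqs[[ri]] else rc(seqs[[ri]])
        sc <- strsplit(s, "")[[1]]
        L <- length(sc)
        if (L > length(refc)) next
        for (st in 0:(length(refc) - L)) {
          mm <- sum(refc[(st + 1):(st + L)] != sc)
          if (mm <= max_mismatch)
            out[[length(out) + 1L]] <- data.frame(
              read_id = names(seqs)[ri], chrom = names(reference)[ci],
              start0 = st, strand = str, mismatches = mm,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(read_id = character(), chrom = character(),
               start0 = integer(), strand = character(),
               mismatches = integer())
}

# normalized sortable key for alignment comparison
aln_key <- function(df) {
  sort(paste(df$read_id, df$chrom, df$start0, df$strand, df$mismatches))
}

# tiny shared reference for read tests
tiny_reference <- function(n = 10, seed = 3, chrom_length = 50000) {
  generate_mirna_reference(n, list(n_chrom = 1,
                                   chrom_length = chrom_length),
                           seed = seed)
}
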