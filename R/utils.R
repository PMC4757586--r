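#' @keywords internal
"_PACKAGE"

#' @importFrom stats phyper pnbinom p.adjust hclust cutree dist rlnorm
#' @importFrom utils read.delim write.table
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# per-read mean Phred score from quality strings (Phred+33)
mean_phred <- function(qual) {
  nc <- nchar(qual)
  if (length(qual) == 0L) return(numeric(0))
  q <- utf8ToInt(paste(qual, collapse = "")) - 33L
  idx <- rep.int(seq_along(qual), nc)
  as.numeric(rowsum(q, idx)) / nc
}

# fraction of a given character in each string
char_fraction <- function(x, ch) {
  n <- nchar(x)
  cnt <- nchar(x) - nchar(gsub(ch, "", x, fixed = TRUE))
  ifelse(n > 0, cnt / n, 0)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
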