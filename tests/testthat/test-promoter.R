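anno <- data.frame(
  mirna = c("mA", "mB", "mC"),
  chrom = "chr1",
  start0 = c(5000L, 2000L, 1000L),
  end0 = c(5080L, 2090L, 1080L),
  strand = c("+", "+", "-"),
  host_gene = c(NA, "HG1", NA),
  stringsAsFactors = FALSE)

test_that("TSS assignment follows curated > host gene > precursor start", {
  curated <- data.frame(mirna = "mA", chrom = "chr1", pos = 4001L,
                        strand = "+", stringsAsFactors = FALSE)
  hosts <- data.frame(gene = "HG1", chrom = "chr1", tx_start0 = 1500L,
                      tx_end0 = 2500L, strand = "+",
                      stringsAsFactors = FALSE)
  tss <- assign_tss(anno, curated, hosts)
  expect_equal(tss$pos0[tss$mirna == "mA"], 4000L)   # 1-based curated input
  expect_equal(tss$source[tss$mirna == "mA"], "curated")
  expect_equal(tss$pos0[tss$mirna == "mB"], 1500L)
  expect_equal(tss$source[tss$mirna == "mB"], "host_gene")
  # minus-strand precursor [1000, 1080): first transcribed base at 1079
  expect_equal(tss$pos0[tss$mirna == "mC"], 1079L)
  expect_equal(tss$source[tss$mirna == "mC"], "premirna_start")
})

test_that("promoter windows are strand-aware and clipped", {
  tss <- data.frame(mirna = c("p", "m", "edge"), chrom = "chr1",
                    pos0 = c(100000L, 100000L, 5000L),
                    strand = c("+", "-", "+"), source = "curated",
                    stringsAsFactors = FALSE)
  w <- promoter_window(tss, upstream = 10000, downstream = 1000)
  expect_equal(unlist(w[w$mirna == "p", c("start0", "end0")], use.names = FALSE),
               c(90000L, 101000L))
  expect_equal(unlist(w[w$mirna == "m", c("start0", "end0")], use.names = FALSE),
               c(99001L, 110001L))
  expect_equal(unlist(w[w$mirna == "edge", c("start0", "end0")], use.names = FALSE),
               c(0L, 6000L))
  # unclipped windows have length U + D on both strands
  expect_equal(w$end0[1] - w$start0[1], 11000L)
  expect_equal(w$end0[2] - w$start0[2], 11000L)
  expect_error(promoter_window(tss[3, ], upstream = 0, downstream = 0),
               "zero length")
})

test_that("any 1-bp overlap yields a site; disjoint peaks do not", {
  tss <- data.frame(mirna = "mA", chrom = "chr1", pos0 = 50000L,
                    strand = "+", source = "curated")
  w <- promoter_window(tss)
  peaks <- data.frame(chrom = "chr1",
                      start0 = c(w$start0 - 199L, w$end0, w$end0 + 5L),
                      end0 = c(w$start0 + 1L, w$end0 + 200L, w$end0 + 205L),
                      name = c("s1", "s2", "s3"), stringsAsFactors = FALSE)
  sites <- find_binding_sites(w, peaks)
  expect_equal(sites$study, "s1")   # 1-bp overlap in; bookended/outside out
  expect_true(sites$upstream)
})

test_that("signed distances mirror under strand relabeling", {
  tssp <- data.frame(mirna = "x", chrom = "c", pos0 = 50000L,
                     strand = "+", source = "curated")
  tssm <- transform(tssp, strand = "-")
  peak_up_plus <- data.frame(chrom = "c", start0 = 47000L, end0 = 47400L,
                             name = "s")
  sp <- find_binding_sites(promoter_window(tssp), peak_up_plus)
  # mirrored peak position relative to the minus-strand TSS
  peak_up_minus <- data.frame(chrom = "c", start0 = 52600L, end0 = 53000L,
                              name = "s")
  sm <- find_binding_sites(promoter_window(tssm), peak_up_minus)
  expect_equal(sp$signed_distance, sm$signed_distance)
  expect_equal(sp$signed_distance, -2800)
  expect_true(sp$within_5kb_upstream && sm$within_5kb_upstream)
})

test_that("site discovery equals the all-pairs overlap oracle", {
  set.seed(17)
  n_win <- 40; n_peaks <- 500
  tss <- data.frame(mirna = sprintf("m%02d", 1:n_win),
                    chrom = sample(c("chr1", "chr2"), n_win, TRUE),
                    pos0 = sample(20000:980000, n_win),
                    strand = sample(c("+", "-"), n_win, TRUE),
                    source = "curated", stringsAsFactors = FALSE)
  w <- promoter_window(tss)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), n_peaks, TRUE),
                   start0 = sample(0:1000000, n_peaks),
                   name = "s", stringsAsFactors = FALSE)
  pk$end0 <- pk$start0 + sample(100:500, n_peaks, TRUE)
  pk <- pk[, c("chrom", "start0", "end0", "name")]
  got <- find_binding_sites(w, pk)
  want <- overlap_oracle(w, pk)
  key <- function(d) sort(paste(d$mirna, d$chrom, d$peak_start0,
                                d$peak_end0))
  expect_identical(key(got), key(want))
  # invariance to peak order
  got2 <- find_binding_sites(w, pk[rev(seq_len(n_peaks)), ])
  expect_identical(key(got2), key(got))
})

test_that("site summaries count miRNAs, multiplicity and placement", {
  dems <- data.frame(mirna = c("mA", "mB", "mC"),
                     direction = c("up", "down", "down"),
                     stringsAsFactors = FALSE)
  sites <- data.frame(
    mirna = c("mA", "mB", "mB"), chrom = "chr1",
    peak_start0 = c(100L, 500L, 900L), peak_end0 = c(300L, 700L, 1100L),
    study = "s1", signed_distance = c(-6000, -1000, 500),
    upstream = c(TRUE, TRUE, FALSE),
    within_5kb_upstream = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  s <- summarize_sites(sites, dems)
  expect_equal(s$n_mirnas_with_sites, 2)
  expect_equal(s$n_up, 1); expect_equal(s$n_down, 1)
  expect_equal(s$n_multiple_sites, 1)
  expect_equal(s$fraction_upstream, 2 / 3)
  expect_equal(s$fraction_within_5kb_upstream, 1 / 3)
  empty <- summarize_sites(sites[0, ], dems)
  expect_equal(empty$n_mirnas_with_sites, 0)
  expect_true(is.na(empty$fraction_upstream))
  expect_error(summarize_sites(sites, dems[0, ]), "empty DEM set")
  expect_error(summarize_sites(transform(sites, mirna = "zz"), dems),
               "outside the DEM set")
})

test_that("BED files round-trip through the interval reader", {
  pk <- data.frame(chrom = c("chr1", "chr2"), start0 = c(0L, 150L),
                   end0 = c(100L, 400L), name = c("sA", "sB"),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(pk, f)
  expect_equal(read_bed(f), pk)
})
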