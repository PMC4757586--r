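test_that("generated precursors match the genome at their coordinates", {
  ref <- generate_mirna_reference(1, list(n_chrom = 1,
                                          chrom_length = 10000), seed = 7)
  m <- ref$mirnas
  expect_equal(nrow(m), 1)
  g <- substr(ref$genome[[m$chrom]], m$start0 + 1, m$end0)
  pre_fwd <- if (m$strand == "+") m$precursor_seq else {
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(m$precursor_seq)))
  }
  expect_equal(g, pre_fwd)
  # the mature sequence sits at its recorded genomic coordinates
  gm <- substr(ref$genome[[m$chrom]], m$mature_start0 + 1, m$mature_end0)
  mat_fwd <- if (m$strand == "+") m$mature_seq else
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(m$mature_seq)))
  expect_equal(gm, mat_fwd)
  expect_true(grepl(m$mature_seq, m$precursor_seq, fixed = TRUE))
})

test_that("reference generation is byte-deterministic given a seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_mirna_reference(
    generate_mirna_reference(8, list(n_chrom = 2, chrom_length = 50000),
                             seed = 42), d1)
  write_mirna_reference(
    generate_mirna_reference(8, list(n_chrom = 2, chrom_length = 50000),
                             seed = 42), d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
})

test_that("50 precursors on a 1 Mb genome are pairwise non-overlapping", {
  ref <- generate_mirna_reference(50, list(n_chrom = 1,
                                           chrom_length = 1000000),
                                  seed = 1)
  m <- ref$mirnas
  for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
    if (m$chrom[i] != m$chrom[j]) next
    expect_true(m$end0[i] <= m$start0[j] || m$end0[j] <= m$start0[i],
                label = paste("overlap", i, j))
  }
})

test_that("impossible placement densities raise a constraint error", {
  expect_error(
    generate_mirna_reference(50, list(n_chrom = 1, chrom_length = 1000),
                             seed = 1),
    "exceeds chromosome length")
})

test_that("read libraries recover a planted fold change", {
  ref <- tiny_reference(n = 20, seed = 3)
  tr <- synthetic_truth(planted_log2fc = c("syn-mir-001" = 2), seed = 5)
  libs <- generate_read_libraries(ref, tr, n_reads = 30000, seed = 5,
                                  other_frac = 0.3)
  mature <- setNames(ref$mirnas$mature_seq, ref$mirnas$mirna)
  cnt <- lapply(libs$libraries[c("control_rep1", "treated_rep1")],
                function(r) count_mirnas(clean_reads(r)$clean, mature))
  ct <- count_table(cnt)
  rpm <- normalize_counts(ct)
  obs <- log2(rpm["syn-mir-001", "treated_rep1"] /
                rpm["syn-mir-001", "control_rep1"])
  expect_lt(abs(obs - 2), 0.2)
})

test_that("zero contamination yields a fully clean filter report", {
  ref <- tiny_reference(n = 5)
  tr <- synthetic_truth(seed = 2)
  libs <- generate_read_libraries(ref, tr, n_reads = 2000, seed = 2)
  rep <- clean_reads(libs$libraries$control_rep1)$report
  expect_equal(rep[["clean"]], rep[["raw"]])
})

test_that("planted polyA contamination is recovered within 3 binomial SDs", {
  ref <- tiny_reference(n = 5)
  tr <- synthetic_truth(contamination_rates = c(polyA = 0.05), seed = 9)
  libs <- generate_read_libraries(ref, tr, n_reads = 20000, seed = 9)
  rep <- clean_reads(libs$libraries$control_rep1)$report
  frac <- rep[["polyA"]] / rep[["raw"]]
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("a planted fold change for an unknown miRNA is an error", {
  ref <- tiny_reference(n = 3)
  tr <- synthetic_truth(planted_log2fc = c(nope = 1), seed = 1)
  expect_error(generate_read_libraries(ref, tr, n_reads = 1000, seed = 1),
               "unknown miRNA")
})

test_that("library generation is byte-deterministic given a seed", {
  ref <- tiny_reference(n = 4)
  tr <- synthetic_truth(contamination_rates = c(low_quality = 0.02),
                        seed = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_read_libraries(ref, tr, n_reads = 1500, seed = 8, outdir = d1)
  generate_read_libraries(ref, tr, n_reads = 1500, seed = 8, outdir = d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
})

test_that("planted peaks land only in the promoters of bound miRNAs", {
  ref <- tiny_reference(n = 10, seed = 4, chrom_length = 500000)
  tss <- assign_tss(ref$mirnas, host_transcripts = ref$hosts)
  lens <- vapply(ref$genome, nchar, integer(1))
  tr <- synthetic_truth(bound_mirnas = c("syn-mir-002", "syn-mir-005"),
                        multi_bound = "syn-mir-005", seed = 1)
  pk <- generate_chip_peaks(tss, tr, decoy_count = 15,
                            chrom_lengths = lens, seed = 3)
  win <- promoter_window(tss, chrom_lengths = lens)
  sites <- find_binding_sites(win, pk[, c("chrom", "start0", "end0",
                                          "name")])
  expect_setequal(unique(sites$mirna), c("syn-mir-002", "syn-mir-005"))
  expect_equal(sum(sites$mirna == "syn-mir-005"), 2)
  # determinism
  pk2 <- generate_chip_peaks(tss, tr, decoy_count = 15,
                             chrom_lengths = lens, seed = 3)
  expect_identical(pk, pk2)
})

test_that("target tables honour the requested inter-source overlap", {
  td1 <- generate_target_data("m1", n_genes = 500, overlap_fraction = 1,
                              targets_per_mirna = 50, seed = 2)
  expect_setequal(td1$pred_a$gene, td1$pred_b$gene)

  td0 <- generate_target_data("m1", n_genes = 500, overlap_fraction = 0,
                              targets_per_mirna = 50,
                              validated_per_mirna = 5, seed = 2)
  it <- integrate_targets(td0$pred_a, td0$pred_b, td0$validated)
  expect_setequal(it$sets[["m1"]], td0$validated$gene)

  td5 <- generate_target_data(paste0("m", 1:5), n_genes = 2000,
                              overlap_fraction = 0.5,
                              targets_per_mirna = 200, seed = 2)
  for (m in paste0("m", 1:5)) {
    a <- td5$pred_a$gene[td5$pred_a$mirna == m]
    b <- td5$pred_b$gene[td5$pred_b$mirna == m]
    jac <- length(intersect(a, b)) / length(union(a, b))
    expect_lt(abs(jac - 0.5), 0.1)
  }
  expect_error(generate_target_data("m1", n_genes = 10,
                                    targets_per_mirna = 50, seed = 1),
               "too small")
})

test_that("annotation sets plant recoverable enrichment and round-trip", {
  genes <- sprintf("G%05d", 1:1000)
  targets <- list(m1 = sample(genes, 120))
  gmt <- generate_annotation_sets(genes, n_categories = 30,
                                  targets = targets,
                                  planted_pairs = data.frame(
                                    mirna = "m1", category = 1),
                                  category_size = 50, overrep_fold = 5,
                                  seed = 11)
  res <- enrich(targets$m1, gmt, genes)
  expect_lt(res$p_adjusted[res$category == "CAT0001"], 0.05)
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(unclass(gmt)[1:30], f)
  back <- read_gmt(f)
  expect_identical(lapply(unclass(gmt)[1:30], unname), lapply(back, unname))
  expect_error(generate_annotation_sets(genes[1:10], 5,
                                        category_size = 50, seed = 1),
               "exceeds universe")
})

test_that("the PPI generator makes a simple graph of the expected size", {
  genes <- sprintf("G%03d", 1:50)
  res <- generate_ppi_and_p53_targets(genes, edge_density = 100 / choose(50, 2),
                                      n_p53_targets = 10, seed = 4)
  expect_lt(abs(nrow(res$ppi) - 100), 3 * sqrt(100 * (1 - 100 / 1225)))
  expect_false(any(res$ppi$gene_a == res$ppi$gene_b))
  expect_false(any(duplicated(paste(pmin(res$ppi$gene_a, res$ppi$gene_b),
                                    pmax(res$ppi$gene_a, res$ppi$gene_b)))))
  full <- generate_ppi_and_p53_targets(genes[1:4], edge_density = 1,
                                       n_p53_targets = 2, seed = 1)
  expect_equal(nrow(full$ppi), 6)
  expect_error(generate_ppi_and_p53_targets(genes[1:4], 0.5, 10, 1),
               "universe")
})
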