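#' Default planted truth emulating the study design
#'
#' Plants 33 differentially expressed miRNAs (12 induced, 21 repressed)
#' among the reference miRNAs, 18 of them (5 induced, 13 repressed) with
#' promoter binding sites and 7 of those with two sites, plus realistic
#' read-contamination rates (~2% low-quality, small rates for the other
#' contaminant classes). Induced effect sizes span +2..+4 log2 units and
#' repressed ones -2..-6.
#'
#' @param mirnas Character vector of reference miRNA names (>= 33).
#' @param seed Integer seed for the random assignment.
#' @return A [synthetic_truth()].
#' @export
default_planted_truth <- function(mirnas, seed = 1L) {
  stopifnot(length(mirnas) >= 33)
  with_seed(seed, {
    de <- sample(mirnas, 33)
    up <- de[1:12]; down <- de[13:33]
    fc <- c(stats::setNames(sample(seq(2, 4, length.out = 12)), up),
            stats::setNames(-sample(seq(2, 6, length.out = 21)), down))
    bound <- c(sample(up, 5), sample(down, 13))
    multi <- sample(bound, 7)
    synthetic_truth(
      planted_log2fc = fc, bound_mirnas = bound, multi_bound = multi,
      contamination_rates = c(low_quality = 0.02,
                              adapter5_contaminant = 0.01,
                              no_adapter3 = 0.03, no_insert = 0.005,
                              polyA = 0.01, length_out_of_bounds = 0.015),
      seed = seed)
  })
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with the package
#' defaults. Any field can be overridden; a YAML file with the same field
#' names can be loaded via `yaml = "config.yml"`.
#'
#' @param outdir Output directory for all stage files.
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_mirnas,n_reads Simulation sizes.
#' @param genome_spec Toy genome layout (`n_chrom`, `chrom_length`).
#' @param min_gap Minimum distance between precursors on a chromosome;
#'   the default (30 kb) exceeds the promoter span, so promoter windows
#'   never overlap and planted peaks stay unambiguous.
#' @param truth Optional `synthetic_truth`; default
#'   [default_planted_truth()].
#' @param criteria [selection_criteria()] for DEM selection.
#' @param upstream,downstream Promoter window extents (bp).
#' @param alpha Enrichment significance level (adjusted p).
#' @param overlap_fraction,targets_per_mirna,validated_per_mirna,n_genes
#'   Target-table generation parameters.
#' @param n_categories,category_size Annotation-set parameters.
#' @param edge_density,n_p53_targets PPI / TF-target parameters.
#' @param decoy_count ChIP decoy peaks outside promoters.
#' @param other_frac Background small-RNA fraction of clean reads.
#' @param yaml Optional YAML file of overrides (applied before the
#'   explicit arguments).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("p53mir_run"), seed = 1L,
                            n_mirnas = 40, n_reads = 20000,
                            genome_spec = list(n_chrom = 4,
                                               chrom_length = 1000000),
                            min_gap = 30000,
                            truth = NULL,
                            criteria = selection_criteria(),
                            upstream = 10000, downstream = 1000,
                            alpha = 0.05, overlap_fraction = 0.5,
                            targets_per_mirna = 60,
                            validated_per_mirna = 8, n_genes = 1500,
                            n_categories = 40, category_size = 50,
                            edge_density = 0.01, n_p53_targets = 120,
                            decoy_count = 20, other_frac = 0.3,
                            yaml = NULL) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    ov <- yaml::read_yaml(yaml)
    for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order — simulate inputs, clean and count reads,
#' differential expression and DEM selection, promoter/peak intersection,
#' target integration and enrichment, network assembly and loop
#' enumeration — writing every output file under `config$outdir` and a
#' manifest of paths with MD5 checksums. Reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param last_stage Stop after this stage (one of `"simulate"`,
#'   `"process_reads"`, `"diffexpr"`, `"promoter_chip"`,
#'   `"targets_enrichment"`, `"network_ffl"`); results of later stages
#'   are then absent.
#' @return List with the in-memory stage results (`reference`, `truth`,
#'   `count_table`, `de_tables`, `dems`, `clusters`, `sites`,
#'   `site_summary`, `targets`, `enrichment`, `network`, `ffls`,
#'   `expected_ffls`) and `manifest` (data frame `path`, `md5`).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         last_stage = "network_ffl") {
  cfg <- config
  stages <- c("simulate", "process_reads", "diffexpr", "promoter_chip",
              "targets_enrichment", "network_ffl")
  last <- match.arg(last_stage, stages)
  wanted <- function(s) match(s, stages) <= match(last, stages)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  out <- list()

  stage <- "simulate"
  res <- tryCatch({
    ref <- generate_mirna_reference(cfg$n_mirnas, cfg$genome_spec, seed,
                                    min_gap = cfg$min_gap)
    write_mirna_reference(ref, file.path(cfg$outdir, "reference"))
    truth <- cfg$truth %||% default_planted_truth(ref$mirnas$mirna, seed)
    libs <- generate_read_libraries(
      ref, truth, n_reads = cfg$n_reads, seed = seed + 1L,
      outdir = file.path(cfg$outdir, "fastq"),
      other_frac = cfg$other_frac)
    tss <- assign_tss(ref$mirnas, host_transcripts = ref$hosts)
    lens <- vapply(ref$genome, nchar, integer(1))
    peaks <- generate_chip_peaks(
      tss, truth, decoy_count = cfg$decoy_count, chrom_lengths = lens,
      seed = seed + 2L, upstream = cfg$upstream,
      downstream = cfg$downstream,
      path = file.path(cfg$outdir, "peaks.bed"))
    tdat <- generate_target_data(
      ref$mirnas$mirna, n_genes = cfg$n_genes,
      overlap_fraction = cfg$overlap_fraction,
      targets_per_mirna = cfg$targets_per_mirna,
      validated_per_mirna = cfg$validated_per_mirna, seed = seed + 3L,
      dir = file.path(cfg$outdir, "targets"))
    ppi <- generate_ppi_and_p53_targets(
      tdat$genes, edge_density = cfg$edge_density,
      n_p53_targets = cfg$n_p53_targets, seed = seed + 4L,
      dir = file.path(cfg$outdir, "network_inputs"))
    list(reference = ref, truth = truth, libraries = libs, tss = tss,
         chrom_lengths = lens, peaks = peaks, target_data = tdat,
         ppi_data = ppi)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)

  if (wanted("process_reads")) {
  stage <- "process_reads"
  res <- tryCatch({
    mature <- stats::setNames(out$reference$mirnas$mature_seq,
                              out$reference$mirnas$mirna)
    lib_counts <- list(); reports <- list()
    for (lib in out$libraries$design$library) {
      cl <- clean_reads(out$libraries$libraries[[lib]])
      reports[[lib]] <- cl$report
      lib_counts[[lib]] <- count_mirnas(cl$clean, mature)
    }
    ct <- count_table(lib_counts)
    cm <- data.frame(mirna = rownames(ct$counts), ct$counts,
                     check.names = FALSE)
    write_tsv(cm, file.path(cfg$outdir, "mirna_counts.tsv"))
    rep_df <- data.frame(class = names(reports[[1]]),
                         vapply(reports, as.integer,
                                integer(length(reports[[1]]))),
                         check.names = FALSE)
    write_tsv(rep_df, file.path(cfg$outdir, "filter_report.tsv"))
    list(count_table = ct, filter_reports = reports)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)

  }
  if (wanted("diffexpr")) {
  stage <- "diffexpr"
  res <- tryCatch({
    de1 <- differential_table(out$count_table, "control_rep1",
                              "treated_rep1")
    de2 <- differential_table(out$count_table, "control_rep2",
                              "treated_rep2")
    write_tsv(de1, file.path(cfg$outdir, "de_rep1.tsv"))
    write_tsv(de2, file.path(cfg$outdir, "de_rep2.tsv"))
    dems <- apply_selection_criteria(de1, de2, cfg$criteria)
    clusters <- if (nrow(dems) >= 2) cluster_dems(dems) else NULL
    dem_out <- dems
    if (!is.null(clusters))
      dem_out$cluster <- clusters$cluster[dem_out$mirna]
    write_tsv(dem_out, file.path(cfg$outdir, "dems.tsv"))
    list(de_tables = list(rep1 = de1, rep2 = de2), dems = dems,
         clusters = clusters)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)

  }
  if (wanted("promoter_chip")) {
  stage <- "promoter_chip"
  res <- tryCatch({
    dem_tss <- out$tss[out$tss$mirna %in% out$dems$mirna, ]
    windows <- promoter_window(dem_tss, upstream = cfg$upstream,
                               downstream = cfg$downstream,
                               chrom_lengths = out$chrom_lengths)
    write_tsv(windows, file.path(cfg$outdir, "promoters.tsv"))
    sites <- find_binding_sites(windows, out$peaks[, c("chrom", "start0",
                                                       "end0", "name")])
    write_tsv(sites, file.path(cfg$outdir, "binding_sites.tsv"))
    summ <- summarize_sites(sites, out$dems)
    jsonlite::write_json(summ, file.path(cfg$outdir, "site_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(promoters = windows, sites = sites, site_summary = summ)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)

  }
  if (wanted("targets_enrichment")) {
  stage <- "targets_enrichment"
  res <- tryCatch({
    td <- out$target_data
    dem_m <- out$dems$mirna
    tg <- integrate_targets(
      td$pred_a[td$pred_a$mirna %in% dem_m, ],
      td$pred_b[td$pred_b$mirna %in% dem_m, ],
      td$validated[td$validated$mirna %in% dem_m, ])
    write_tsv(tg$table, file.path(cfg$outdir, "integrated_targets.tsv"))
    gmt <- generate_annotation_sets(
      td$genes, n_categories = cfg$n_categories, targets = tg,
      planted_pairs = data.frame(
        mirna = names(tg$sets),
        category = seq_along(tg$sets) %% cfg$n_categories + 1L,
        stringsAsFactors = FALSE),
      category_size = cfg$category_size, seed = seed + 5L,
      path = file.path(cfg$outdir, "annotations.gmt"))
    enr <- enrich_targets(tg, gmt, alpha = cfg$alpha)
    mat <- enrichment_matrix(enr[setdiff(names(enr), "pooled")])
    write_tsv(data.frame(mirna = rownames(mat), mat, check.names = FALSE),
              file.path(cfg$outdir, "enrichment_matrix.tsv"))
    list(targets = tg, annotations = gmt, enrichment = enr,
         enrichment_mat = mat)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)

  }
  if (wanted("network_ffl")) {
  stage <- "network_ffl"
  res <- tryCatch({
    bound <- intersect(unique(out$sites$mirna), out$dems$mirna)
    net <- build_network(out$dems, bound, out$targets,
                         out$ppi_data$p53_targets, out$ppi_data$ppi)
    ffls <- enumerate_ffls(net)
    write_tsv(ffls, file.path(cfg$outdir, "ffls.tsv"))
    export_network(net, file.path(cfg$outdir, "network"), "SIF")
    export_network(net, file.path(cfg$outdir, "network"), "GraphML")
    expected <- expected_ffl_count(out$truth, out$targets,
                                   out$ppi_data$p53_targets)
    list(network = net, ffls = ffls, expected_ffls = expected)
  }, error = function(e) stop("pipeline stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))
  out <- c(out, res)
  }

  files <- list.files(cfg$outdir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(path = sub(paste0("^", cfg$outdir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(cfg$outdir, "manifest.tsv"))
  out$manifest <- manifest
  out$config <- cfg
  out
}

#' Feed-forward loops implied by the planted truth
#'
#' Counts the (TF, miRNA, gene) triples expected from the planted bound
#' miRNA set, the integrated target sets and the TF direct-target list —
#' the number the pipeline must report when DEM and binding-site
#' detection are perfect.
#'
#' @param truth A `synthetic_truth`.
#' @param targets An `integrated_targets`.
#' @param p53_targets TF direct-target genes.
#' @param tf TF node name (default "TP53").
#' @return Integer FFL count.
#' @export
expected_ffl_count <- function(truth, targets, p53_targets, tf = "TP53") {
  sum(vapply(intersect(truth$bound_mirnas, names(targets$sets)),
             function(m) length(intersect(targets$sets[[m]],
                                          setdiff(p53_targets, tf))),
             integer(1)))
}
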