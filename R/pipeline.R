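# End-to-end orchestration: simulate -> build-ref -> clean -> quantify ->
# DE test -> enrichment -> QC, with a manifest for reproducibility.

#' Random flat gene-term annotation
#'
#' Assigns each gene 0-3 terms uniformly at random — the synthetic stand-in
#' for a GO/pathway annotation table, independent of expression by
#' construction.
#'
#' @param genes Character vector of gene ids.
#' @param n_terms Number of distinct terms.
#' @param mean_terms_per_gene Expected annotations per gene.
#' @param seed Integer RNG seed.
#' @return data.frame `gene_id`, `term_id`.
#' @export
simulate_annotation <- function(genes, n_terms = 20L,
                                mean_terms_per_gene = 1.5, seed = 1L) {
  with_seed(seed, {
    k <- stats::rpois(length(genes), mean_terms_per_gene)
    df <- data.frame(
      gene_id = rep(genes, k),
      term_id = sprintf("T%03d", sample.int(n_terms, sum(k), replace = TRUE)),
      stringsAsFactors = FALSE)
    unique(df)
  })
}

#' Default demonstration configuration
#'
#' A small but complete run: 150 genes, five time points, two replicates per
#' condition, 30,000 tags per library, 0.1% substitution error, 12 planted
#' genes at |log2fc| = 3.
#'
#' @param outdir Output directory for [run_pipeline()].
#' @param seed Base seed.
#' @return Nested configuration list.
#' @export
demo_config <- function(outdir = tempfile("tagdge_run_"), seed = 101L) {
  list(
    outdir = outdir,
    seed = seed,
    simulate = list(n_genes = 150L, length_range = c(300L, 1500L),
                    catg_guarantee = TRUE, library_size = 30000L,
                    error_rate = 0.001, n_de = 12L, log2fc = 3,
                    base = "lognormal"),
    design = list(timepoints = c("1h", "4h", "8h", "12h", "24h"),
                  replicates = 2L),
    thresholds = list(fdr = 0.001, lfc = 2, bonferroni_alpha = 0.05,
                      q = 0.05),
    annotation = list(n_terms = 20L))
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_domain("`config` must be a list or a YAML path")
  defaults <- demo_config()
  config$thresholds <- utils::modifyList(defaults$thresholds,
                                         config$thresholds %||% list())
  for (f in c("outdir", "seed", "simulate", "design", "annotation"))
    config[[f]] <- config[[f]] %||% defaults[[f]]
  th <- config$thresholds
  if (th$fdr <= 0 || th$fdr > 1 || th$lfc < 0 ||
      th$bonferroni_alpha <= 0 || th$bonferroni_alpha >= 1 ||
      th$q <= 0 || th$q > 1)
    stop_domain("thresholds out of range")
  config
}

#' Run the full tag-DGE pipeline on synthetic data
#'
#' Executes simulate, reference-library construction, tag cleaning, mapping
#' and RPKM quantification, treated-vs-control exact tests per time point,
#' term enrichment of each DEG list, and QC, writing every table under
#' `config$outdir` along with a manifest (package version, seeds, input
#' digests, per-stage row counts). Deterministic for a fixed seed.
#'
#' @param config Configuration list (see [demo_config()]) or path to a YAML
#'   file with the same structure.
#' @return Invisibly, a list with the in-memory stage results: `truth`,
#'   `ref`, `libraries`, `clean`, `maps`, `counts`, `rpkm`, `de`,
#'   `deg_summary`, `enrichment`, `saturation`, `quality`, `manifest`.
#' @export
run_pipeline <- function(config = demo_config()) {
  config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  sim <- config$simulate
  stage_rows <- list()

  design <- default_design(config$design$timepoints, config$design$replicates)

  # --- simulate -------------------------------------------------------------
  tx <- generate_transcriptome(sim$n_genes, unlist(sim$length_range),
                               sim$catg_guarantee %||% TRUE, seed = seed)
  truth <- truth_table(tx, n_de = sim$n_de, log2fc = sim$log2fc,
                       base = sim$base %||% "uniform", seed = seed + 1L)
  libs <- simulate_experiment(tx, truth, design, sim$library_size,
                              sim$error_rate, seed = seed + 10L)
  fasta <- file.path(outdir, "transcriptome.fa")
  write_transcriptome_fasta(tx, fasta)
  write_gene_map(tx, file.path(outdir, "gene_map.tsv"))
  write_truth_table(truth, file.path(outdir, "truth.tsv"))
  stage_rows$simulate <- nrow(tx)

  # --- reference + clean ----------------------------------------------------
  ref <- build_reference_library(tx)
  write_reference_library(ref, file.path(outdir, "reference_tags.tsv"))
  clean <- lapply(libs, extract_and_filter_tags)
  stage_rows$build_ref <- nrow(ref$tags)
  stage_rows$clean <- sum(vapply(clean, function(x) nrow(x$counts), integer(1)))

  # --- quantify -------------------------------------------------------------
  maps <- lapply(clean, map_tags, ref = ref)
  counts <- count_matrix(maps)
  rpkm_mat <- vapply(maps, function(m)
    gene_expression(m$gene_counts, ref, N = m$summary$total_mapped)$rpkm,
    numeric(nrow(counts)))
  rownames(rpkm_mat) <- rownames(counts)
  write_gene_matrix(counts, file.path(outdir, "counts.tsv"))
  write_gene_matrix(round(rpkm_mat, 4), file.path(outdir, "rpkm.tsv"))
  quality <- quality_report(lapply(maps, `[[`, "summary"))
  utils::write.table(quality, file.path(outdir, "mapping_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_rows$quantify <- nrow(counts)

  # --- differential expression ----------------------------------------------
  th <- config$thresholds
  de <- de_pairwise(counts, design, fdr_threshold = th$fdr,
                    lfc_threshold = th$lfc)
  for (nm in names(de))
    utils::write.table(de[[nm]], file.path(outdir, sprintf("de_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  deg_summary <- call_deg(de)
  utils::write.table(deg_summary, file.path(outdir, "deg_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_rows$de_test <- sum(deg_summary$n_up + deg_summary$n_down)

  # --- enrichment -----------------------------------------------------------
  ann <- simulate_annotation(rownames(counts),
                             config$annotation$n_terms %||% 20L,
                             seed = seed + 2L)
  utils::write.table(ann, file.path(outdir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- lapply(de, function(r) {
    degs <- r$gene_id[r$call != "not_significant"]
    if (length(degs) == 0) NULL else enrich_terms(degs, ann)
  })
  enr_tab <- do.call(rbind, lapply(names(enr), function(nm) {
    if (is.null(enr[[nm]])) return(NULL)
    cbind(comparison = nm, enr[[nm]])
  }))
  if (!is.null(enr_tab))
    utils::write.table(enr_tab, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  stage_rows$enrichment <- if (is.null(enr_tab)) 0L else nrow(enr_tab)

  # --- QC -------------------------------------------------------------------
  sat <- saturation_analysis(maps[[1]], seed = seed + 3L)
  utils::write.table(sat, file.path(outdir, "saturation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage_rows$qc <- nrow(sat)

  manifest <- list(
    package = as.character(utils::packageVersion("tagdge")),
    seed = seed,
    config = config[c("simulate", "design", "thresholds")],
    input_digests = as.list(tools::md5sum(c(
      transcriptome = fasta,
      truth = file.path(outdir, "truth.tsv")))),
    stage_rows = stage_rows)
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(truth = truth, ref = ref, libraries = libs, clean = clean,
                 maps = maps, counts = counts, rpkm = rpkm_mat, de = de,
                 deg_summary = deg_summary, enrichment = enr,
                 saturation = sat, quality = quality, manifest = manifest))
}
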