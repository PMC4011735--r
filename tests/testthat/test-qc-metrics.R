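# Hand-assembled map_tags-result and reference shims for QC functions.
fake_map_result <- function(gene_ids, counts, library_id = "qc") {
  tags <- vapply(seq_along(gene_ids), function(i) random_tag(), character(1))
  structure_list <- list(
    gene_counts = tapply(counts, gene_ids, sum),
    summary = structure(list(library_id = library_id,
                             total_reads = sum(counts),
                             total_mapped = sum(counts),
                             perfect_match = sum(counts), one_mismatch = 0L,
                             unique_match = sum(counts),
                             multi_position_match = 0L, unmapped = 0L),
                        class = "mapping_summary"),
    assignments = data.frame(tag = tags, count = counts,
                             match_type = "perfect", n_positions = 1L,
                             gene_id = gene_ids, stringsAsFactors = FALSE))
  structure_list
}

test_that("saturation curves are monotone, bounded and complete at fraction 1", {
  tx <- generate_transcriptome(60, c(100, 400), seed = 41)
  ab <- condition_abundance(truth_table(tx, base = "lognormal", seed = 41),
                            "control")
  lib <- simulate_tag_reads(tx, ab, 2e4, error_rate = 0, seed = 42)
  ref <- build_reference_library(tx)
  m <- map_tags(extract_and_filter_tags(lib), ref)
  sat <- saturation_analysis(m, fractions = seq(0.1, 1, by = 0.1), seed = 43)
  expect_true(all(diff(sat$genes_detected) >= 0))
  full_detect <- sum(m$gene_counts > 0)
  expect_equal(sat$genes_detected[nrow(sat)], full_detect)
  expect_true(all(sat$genes_detected <= length(ref$gene_lengths)))
  expect_error(saturation_analysis(m, fractions = c(0, 0.5)), "fractions")
})

test_that("subsampled detection follows the occupancy expectation", {
  set.seed(55)
  n_genes <- 100
  ids <- sprintf("g%03d", 1:n_genes)
  counts <- as.vector(rmultinom(1, 1e5, rep(1 / n_genes, n_genes)))
  m <- fake_map_result(ids, counts)
  fr <- c(0.005, 0.01, 0.02, 0.05)
  sat <- saturation_analysis(m, fractions = fr, seed = 8)
  for (i in seq_along(fr)) {
    k <- sat$reads_sampled[i]
    mu <- n_genes * (1 - (1 - 1 / n_genes)^k)
    v <- n_genes * (1 - 1 / n_genes)^k +
      n_genes * (n_genes - 1) * (1 - 2 / n_genes)^k -
      n_genes^2 * (1 - 1 / n_genes)^(2 * k)
    expect_lt(abs(sat$genes_detected[i] - mu), 3 * sqrt(max(v, 1)))
  }
})

test_that("the plateau flag fires for saturated libraries only", {
  deep <- fake_map_result(sprintf("g%02d", 1:20),
                          as.vector(rmultinom(1, 5e4, rep(0.05, 20))))
  sat <- saturation_analysis(deep, seed = 2)
  expect_true(attr(sat, "plateau"))
})

test_that("gene-body histogram concentrates where the tags sit", {
  # all tags at 90% of the gene body on equal-length transcripts
  L <- 200
  insert <- function() paste(sample(c("A", "C", "G", "T"), 21 - 4, replace = TRUE),
                             collapse = "")
  set.seed(12)
  seqs <- vapply(1:10, function(i) {
    body <- paste(sample(c("A", "C", "T"), L, replace = TRUE), collapse = "")
    # wipe stray CATGs so the planted site is 3'-most and unique
    body <- gsub("CATG", "CTTG", body, fixed = TRUE)
    pos <- floor(0.9 * L)
    paste0(substr(body, 1, pos - 1), "CATG", insert(),
           substr(body, pos + 21, L))
  }, character(1))
  tx <- make_tx(seqs)
  ref <- build_reference_library(tx)
  ab <- setNames(rep(0.1, 10), tx$gene_id)
  lib <- simulate_tag_reads(tx, ab, 5000, error_rate = 0, seed = 13)
  m <- map_tags(extract_and_filter_tags(lib), ref)
  prof <- gene_body_distribution(m, ref)
  expect_equal(sum(prof$histogram), m$summary$total_mapped)
  hot <- which(prof$histogram > 0)
  expect_true(all(hot >= 88 & hot <= 92))
})

test_that("dynamic range reflects the planted abundance span", {
  # two genes detected -> log10 ratio of their RPKMs; equal lengths so the
  # ratio is the count ratio
  m <- fake_map_result(c("gHi", "gLo"), c(10000L, 1L))
  ref <- list(hits = data.frame(tag = m$assignments$tag,
                                gene_id = m$assignments$gene_id,
                                transcript_id = paste0(m$assignments$gene_id, "_t1"),
                                position = 50L, stringsAsFactors = FALSE),
              gene_lengths = c(gHi = 500L, gLo = 500L))
  prof <- gene_body_distribution(m, ref)
  expect_equal(prof$dynamic_range, 4, tolerance = 1e-9)

  single <- fake_map_result("gOnly", 100L)
  ref1 <- list(hits = data.frame(tag = single$assignments$tag,
                                 gene_id = "gOnly", transcript_id = "gOnly_t1",
                                 position = 10L, stringsAsFactors = FALSE),
               gene_lengths = c(gOnly = 300L))
  expect_equal(gene_body_distribution(single, ref1)$dynamic_range, 0)
})

test_that("uniform tag positions pass a chi-square uniformity check", {
  # randomness QC: tags spread uniformly over the gene body
  n_ok <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 5000
    pos <- sample.int(100, n, replace = TRUE)  # uniform bins directly
    obs <- tabulate(pos, nbins = 100)
    p <- stats::chisq.test(obs)$p.value
    if (p > 0.01) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 19)
})

test_that("quality report emits per-library rows and zero rows for empty input", {
  empty <- structure(list(library_id = "empty", total_reads = 0L,
                          total_mapped = 0L, perfect_match = 0L,
                          one_mismatch = 0L, unique_match = 0L,
                          multi_position_match = 0L, unmapped = 0L),
                     class = "mapping_summary")
  rep1 <- quality_report(list(empty))
  expect_equal(rep1$total_reads, 0)
  expect_equal(rep1$total_mapped_pct, 0)
  expect_equal(rep1$unmapped_pct, 0)
})
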