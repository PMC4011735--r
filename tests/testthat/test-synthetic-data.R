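test_that("generated transcriptomes honour length and CATG constraints", {
  tx <- generate_transcriptome(25, c(100, 400), catg_guarantee = TRUE, seed = 7)
  expect_equal(nrow(tx), 25)
  expect_true(all(tx$length >= 100 & tx$length <= 400))
  expect_true(all(tx$length == nchar(tx$sequence)))
  expect_true(all(grepl("^[ACGT]+$", tx$sequence)))
  expect_false(anyDuplicated(tx$transcript_id) > 0)
  # every transcript has a CATG with >= 17 nt downstream of its 3'-most site
  pos <- vapply(tx$sequence, tagdge:::eligible_catg_pos, integer(1))
  expect_true(all(!is.na(pos)))
  expect_true(all(pos + 20 <= tx$length))

  one <- generate_transcriptome(1, c(100, 100), catg_guarantee = TRUE, seed = 7)
  expect_true(grepl("CATG", one$sequence))

  expect_error(generate_transcriptome(0, c(100, 100)), "n_genes")
  expect_error(generate_transcriptome(5, c(10, 20)), "length_range")
})

test_that("transcriptome generation is deterministic under a fixed seed", {
  a <- generate_transcriptome(10, c(50, 200), seed = 42)
  b <- generate_transcriptome(10, c(50, 200), seed = 42)
  expect_identical(a, b)
  c <- generate_transcriptome(10, c(50, 200), seed = 43)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("CATG-free fraction matches the closed-form occurrence probability", {
  # P(no CATG in length L) ~ (1 - 4^-4)^(L-3) for iid uniform sequence
  L <- 300
  n <- 2000
  tx <- generate_transcriptome(n, c(L, L), catg_guarantee = FALSE, seed = 11)
  frac_free <- mean(!grepl("CATG", tx$sequence, fixed = TRUE))
  p_free <- (1 - 4^-4)^(L - 3)
  se <- sqrt(p_free * (1 - p_free) / n)
  expect_lt(abs(frac_free - p_free), 4 * se)
})

test_that("noiseless reads reproduce the reference tag exactly", {
  tx <- make_tx("AAAACATGACGTACGTACGTACGTTTTT")
  lib <- simulate_tag_reads(tx, c(g01 = 1), library_size = 50, error_rate = 0,
                            seed = 3)
  expect_equal(sum(lib$reads$count), 50)
  tag <- substr(tx$sequence, 5, 25)
  expect_true(all(substr(lib$reads$sequence, 1, 21) == tag))
  expect_true(all(nchar(lib$reads$sequence) == 49))
})

test_that("read counts follow the configured abundances", {
  tx <- generate_transcriptome(2, c(200, 200), seed = 5)
  ab <- setNames(c(0.9, 0.1), tx$gene_id)
  lib <- simulate_tag_reads(tx, ab, library_size = 1e5, error_rate = 0,
                            seed = 9)
  expect_equal(sum(lib$truth_counts), 1e5)
  p_hat <- lib$truth_counts[tx$gene_id[1]] / 1e5
  se <- sqrt(0.9 * 0.1 / 1e5)
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("transcripts without an eligible site are dropped and logged", {
  tx <- make_tx(c(strrep("A", 60),                       # no CATG at all
                  paste0(strrep("A", 30), "CATGACGTACGTACGTACGTA")))
  ab <- setNames(c(0.5, 0.5), tx$gene_id)
  lib <- simulate_tag_reads(tx, ab, library_size = 100, error_rate = 0,
                            seed = 2)
  expect_equal(lib$dropped_genes, "g01")
  expect_equal(sum(lib$reads$count), 100)   # conservation after renormalization
  expect_equal(names(lib$truth_counts), "g02")
})

test_that("every noiseless simulated tag exists in the reference library", {
  tx <- generate_transcriptome(40, c(150, 600), catg_guarantee = TRUE, seed = 21)
  truth <- truth_table(tx, n_de = 5, log2fc = 3, seed = 22)
  lib <- simulate_tag_reads(tx, condition_abundance(truth, "treated"),
                            library_size = 2e4, error_rate = 0, seed = 23)
  ref <- build_reference_library(tx)
  tags <- unique(substr(lib$reads$sequence, 1, 21))
  expect_true(all(tags %in% ref$tags$tag))
})

test_that("identical seeds give byte-identical FASTQ output", {
  tx <- generate_transcriptome(10, c(100, 300), seed = 31)
  ab <- condition_abundance(truth_table(tx, seed = 31), "control")
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_library_fastq(simulate_tag_reads(tx, ab, 500, 0.01, seed = 77), f1)
  write_library_fastq(simulate_tag_reads(tx, ab, 500, 0.01, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0)
})

test_that("truth tables normalize abundances and keep nulls at zero fold change", {
  tx <- generate_transcriptome(30, c(100, 200), seed = 4)
  truth <- truth_table(tx, n_de = 6, log2fc = 2.5, base = "lognormal", seed = 5)
  expect_equal(sum(truth$base_abundance), 1)
  expect_equal(sum(condition_abundance(truth, "treated")), 1)
  expect_true(all(truth$log2fc[!truth$is_planted_de] == 0))
  expect_equal(sum(truth$is_planted_de), 6)
  expect_true(all(abs(truth$log2fc[truth$is_planted_de]) == 2.5))
  expect_error(truth_table(tx, n_de = 31), "n_de")
})

test_that("error model hits the expected per-read substitution frequency", {
  tx <- make_tx(paste0(strrep("G", 20), "CATGACGTACGTACGTACGTA", strrep("G", 10)))
  e <- 0.02
  lib <- simulate_tag_reads(tx, c(g01 = 1), library_size = 2e4, error_rate = e,
                            seed = 13)
  clean_tag <- substr(tx$sequence, 21, 41)
  reads <- rep(substr(lib$reads$sequence, 1, 21), lib$reads$count)
  frac_intact <- mean(reads == clean_tag)
  # the error mask is an iid Binomial(49, e) mask, so the tag region is
  # intact with probability exactly (1-e)^21
  p_intact <- (1 - e)^21
  se <- sqrt(p_intact * (1 - p_intact) / 2e4)
  expect_lt(abs(frac_intact - p_intact), 4 * se)
})
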