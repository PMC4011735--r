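# Hand-built reference for mapping tests: three genes with known tags.
quantify_fixture <- function() {
  tagA <- paste0("CATG", "ACGTACGTACGTACGTA")
  tagB <- paste0("CATG", "GGCCTTAAGGCCTTAAG")
  tagC <- paste0("CATG", "TTGACCTGATTGACCTG")
  tx <- make_tx(c(paste0(strrep("T", 10), tagA, strrep("G", 20)),
                  paste0(strrep("A", 15), tagB, strrep("C", 25)),
                  paste0(strrep("C", 12), tagC, strrep("A", 18))),
                gene_ids = c("gA", "gB", "gC"))
  list(tx = tx, ref = build_reference_library(tx),
       tagA = tagA, tagB = tagB, tagC = tagC)
}

clean_from_tags <- function(tags, counts) {
  extract_and_filter_tags(make_library(pad_read(tags), counts = counts))
}

test_that("exact unique hits are counted and tallied as perfect matches", {
  f <- quantify_fixture()
  res <- map_tags(clean_from_tags(f$tagA, 5L), f$ref)
  expect_equal(unname(res$gene_counts["gA"]), 5L)
  expect_equal(res$summary$perfect_match, 5L)
  expect_equal(res$summary$unique_match, 5L)
  expect_equal(res$summary$unmapped, 0L)
})

test_that("a tag near two genes is multi-position and excluded from counts", {
  f <- quantify_fixture()
  # one substitution turns tagA into a tag at distance 1 from tagA only;
  # build a tag at distance 1 from BOTH gene tags: needs two reference tags
  # differing at 2 positions; construct explicitly
  t1 <- paste0("CATG", "AAAAAAAACCCCCCCCC")
  t2 <- paste0("CATG", "AAAAAAAATCCCCCCCG")
  mid <- paste0("CATG", "AAAAAAAATCCCCCCCC")  # dist 1 from both
  tx <- make_tx(c(paste0(strrep("G", 5), t1, strrep("T", 20)),
                  paste0(strrep("T", 5), t2, strrep("G", 20))),
                gene_ids = c("g1", "g2"))
  ref <- build_reference_library(tx)
  res <- map_tags(clean_from_tags(mid, 7L), ref)
  expect_equal(res$summary$one_mismatch, 7L)
  expect_equal(res$summary$multi_position_match, 7L)
  expect_equal(sum(res$gene_counts), 0L)
  expect_equal(res$summary$total_mapped, 7L)
})

test_that("an exact match preempts one-mismatch hits to other genes", {
  t1 <- paste0("CATG", "AAAAAAAACCCCCCCCC")
  t2 <- paste0("CATG", "AAAAAAAACCCCCCCCG")  # distance 1 from t1
  tx <- make_tx(c(paste0(strrep("G", 5), t1, strrep("T", 20)),
                  paste0(strrep("T", 5), t2, strrep("G", 20))),
                gene_ids = c("g1", "g2"))
  ref <- build_reference_library(tx)
  res <- map_tags(clean_from_tags(t1, 4L), ref)
  expect_equal(unname(res$gene_counts["g1"]), 4L)
  expect_equal(res$summary$perfect_match, 4L)
})

test_that("unmappable tags accumulate in unmapped", {
  f <- quantify_fixture()
  far <- paste0("CATG", "GGGGGGGGAAAAAAAAT")  # distance > 1 from all tags
  res <- map_tags(clean_from_tags(c(f$tagA, far), c(3L, 6L)), f$ref)
  expect_equal(res$summary$unmapped, 6L)
  expect_equal(res$summary$total_mapped, 3L)
  expect_equal(res$summary$total_reads, 9L)
})

test_that("indexed mapping agrees with brute-force Hamming comparison", {
  tx <- generate_transcriptome(30, c(100, 500), seed = 14)
  ab <- condition_abundance(truth_table(tx, seed = 14), "control")
  lib <- simulate_tag_reads(tx, ab, 8000, error_rate = 0.01, seed = 15)
  ref <- build_reference_library(tx)
  clean <- extract_and_filter_tags(lib)
  res <- map_tags(clean, ref)

  # oracle: all-pairs Hamming distance between every clean tag and every
  # reference tag
  ref_mat <- do.call(rbind, strsplit(ref$tags$tag, ""))
  gene_sets <- split(ref$hits$gene_id, ref$hits$tag)
  oracle_counts <- setNames(integer(length(ref$gene_lengths)),
                            names(ref$gene_lengths))
  for (i in seq_len(nrow(clean$counts))) {
    q <- strsplit(clean$counts$tag[i], "")[[1]]
    d <- colSums(t(ref_mat) != q)
    hit <- if (any(d == 0)) which(d == 0) else which(d == 1)
    if (length(hit) == 0) next
    genes <- unique(unlist(gene_sets[ref$tags$tag[hit]]))
    if (length(genes) == 1)
      oracle_counts[genes] <- oracle_counts[genes] + clean$counts$count[i]
  }
  expect_equal(res$gene_counts, oracle_counts)
})

test_that("noiseless per-gene counts equal simulation truth", {
  tx <- generate_transcriptome(50, c(100, 800), seed = 16)
  ab <- condition_abundance(truth_table(tx, base = "lognormal", seed = 16),
                            "control")
  lib <- simulate_tag_reads(tx, ab, 3e4, error_rate = 0, seed = 17)
  ref <- build_reference_library(tx)
  res <- map_tags(extract_and_filter_tags(lib), ref)
  truth <- lib$truth_counts
  expect_equal(res$gene_counts[names(truth)], truth)
  expect_equal(res$summary$unmapped, 0L)
})

test_that("adding reads never decreases a gene's count", {
  f <- quantify_fixture()
  r1 <- map_tags(clean_from_tags(c(f$tagA, f$tagB), c(5L, 4L)), f$ref)
  r2 <- map_tags(clean_from_tags(c(f$tagA, f$tagB, f$tagC), c(9L, 4L, 2L)),
                 f$ref)
  expect_true(all(r2$gene_counts >= r1$gene_counts))
})

test_that("rpkm follows 10^9 C / (N L)", {
  expect_equal(rpkm(0, 1e6, 1000), 0)
  expect_equal(rpkm(1000, 1000, 1000), 1e6)     # C == N identity
  expect_equal(rpkm(250, 5e6, 2000), 25)
  expect_equal(rpkm(c(0, 250), 5e6, c(100, 2000)), c(0, 25))
  expect_error(rpkm(1, 0, 100), "N and L")
  expect_error(rpkm(-1, 10, 100), "C")
})

test_that("mapping percentages reproduce count ratios at 2 decimals", {
  s <- structure(list(library_id = "all", total_reads = 100L,
                      total_mapped = 100L, perfect_match = 100L,
                      one_mismatch = 0L, unique_match = 100L,
                      multi_position_match = 0L, unmapped = 0L),
                 class = "mapping_summary")
  expect_equal(mapping_percentages(s)$total_mapped_pct, 100.00)
  bad <- s; bad$unmapped <- 5L
  expect_error(mapping_percentages(bad), "inconsistent")
})
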