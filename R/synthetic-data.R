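# Read layout: the 21-nt tag (CATG + 17) sits at offset 0 of each 49-nt read;
# the remaining 28 nt are a constant adapter suffix. An "adapter-only" read is
# one whose tag region is adapter sequence instead of a tag.
TAG_LENGTH <- 21L
READ_LENGTH <- 49L

#' Constant adapter sequence used to pad simulated reads
#'
#' Returns the fixed 49-nt adapter; simulated reads append its first
#' `READ_LENGTH - TAG_LENGTH` (28) nt after the tag, and adapter-only reads
#' (library artefacts with no insert) consist of this sequence alone.
#'
#' @return A single 49-character DNA string.
#' @export
tag_adapter <- function() {
  "GATCGGAAGAGCTCGTATGCCGTCTTCTGCTTGAAAAAAAAAAAAAAAA"
}

#' Generate a synthetic transcriptome
#'
#' Draws one random transcript per gene with iid uniform A/C/G/T bases. With
#' `catg_guarantee` every transcript is forced to contain at least one CATG
#' site with >= 17 nt downstream, so every gene is detectable by NlaIII/MmeI
#' tag sequencing; without it, short or CATG-free transcripts may be
#' undetectable, as in real 3'-tag libraries.
#'
#' @param n_genes Number of genes (one transcript each), >= 1.
#' @param length_range Integer pair `c(min, max)` of transcript lengths in nt;
#'   both >= 25 so a CATG + 17 nt tag can fit.
#' @param catg_guarantee Logical; plant an eligible CATG site when a transcript
#'   lacks one.
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @return A data.frame of class `transcriptome` with columns `transcript_id`,
#'   `gene_id`, `sequence`, `length`.
#' @examples
#' tx <- generate_transcriptome(5, c(100, 200), seed = 1)
#' @export
generate_transcriptome <- function(n_genes, length_range = c(200L, 2000L),
                                   catg_guarantee = TRUE, seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop_domain("`n_genes` must be a single integer >= 1")
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || any(length_range < 25L) ||
      length_range[1] > length_range[2])
    stop_domain("`length_range` must be c(min, max) with 25 <= min <= max")
  n_genes <- as.integer(n_genes)

  with_seed(seed, {
    lens <- if (length_range[1] == length_range[2]) {
      rep(length_range[1], n_genes)
    } else {
      sample(length_range[1]:length_range[2], n_genes, replace = TRUE)
    }
    seqs <- vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    if (catg_guarantee) {
      for (i in seq_along(seqs)) {
        if (is.na(eligible_catg_pos(seqs[i]))) {
          # plant CATG at a random position leaving >= 17 nt downstream
          pos <- sample.int(lens[i] - TAG_LENGTH + 1L, 1L)
          substr(seqs[i], pos, pos + 3L) <- "CATG"
        }
      }
    }
    ids <- sprintf("g%04d", seq_len(n_genes))
    structure(
      data.frame(transcript_id = paste0(ids, "_t1"), gene_id = ids,
                 sequence = seqs, length = lens, stringsAsFactors = FALSE),
      class = c("transcriptome", "data.frame"))
  })
}

# 1-based position of the C of the 3'-most CATG with >= 17 nt downstream,
# or NA if the transcript has no eligible site.
eligible_catg_pos <- function(sequence) {
  hits <- gregexpr("CATG", sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  ok <- hits[hits + TAG_LENGTH - 1L <= nchar(sequence)]
  if (length(ok) == 0L) NA_integer_ else max(ok)
}

#' Build a planted-truth expression table
#'
#' Assigns each gene a base relative abundance (molarity) and plants log2 fold
#' changes on a chosen subset; the rest are null (log2fc = 0). Abundances are
#' normalized to sum to 1 within each condition after fold-change application.
#'
#' @param transcriptome A `transcriptome` (or character vector of gene ids).
#' @param n_de Number of genes given a planted fold change.
#' @param log2fc Magnitude(s) of planted log2 fold changes; recycled over the
#'   DE genes, with alternating signs when a single magnitude is given.
#' @param base Base abundance model: `"uniform"` (equal molarity) or
#'   `"lognormal"` (sdlog 1, the skewed profile typical of transcriptomes).
#' @param seed Integer RNG seed.
#' @return A data.frame of class `truth_table` with columns `gene_id`,
#'   `base_abundance`, `log2fc`, `is_planted_de`.
#' @export
truth_table <- function(transcriptome, n_de = 0L, log2fc = 3,
                        base = c("uniform", "lognormal"), seed = 1L) {
  genes <- if (is.character(transcriptome)) transcriptome
           else unique(transcriptome$gene_id)
  base <- match.arg(base)
  n <- length(genes)
  if (n_de > n) stop_domain("`n_de` cannot exceed the number of genes")
  with_seed(seed, {
    ab <- switch(base,
                 uniform = rep(1 / n, n),
                 lognormal = { a <- stats::rlnorm(n, 0, 1); a / sum(a) })
    fc <- numeric(n)
    de <- rep(FALSE, n)
    if (n_de > 0) {
      idx <- sample.int(n, n_de)
      mag <- rep_len(abs(log2fc), n_de)
      sgn <- if (length(log2fc) > 1) rep_len(sign(log2fc), n_de)
             else rep_len(c(1, -1), n_de)
      fc[idx] <- mag * sgn
      de[idx] <- TRUE
    }
    structure(
      data.frame(gene_id = genes, base_abundance = ab, log2fc = fc,
                 is_planted_de = de, stringsAsFactors = FALSE),
      class = c("truth_table", "data.frame"))
  })
}

#' Per-condition relative abundances from a truth table
#'
#' @param truth A `truth_table`.
#' @param condition `"control"` (base abundances) or `"treated"` (base times
#'   `2^log2fc`, renormalized to sum to 1).
#' @return Named numeric vector of abundances summing to 1.
#' @export
condition_abundance <- function(truth, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  ab <- truth$base_abundance
  if (condition == "treated") ab <- ab * 2^truth$log2fc
  stats::setNames(ab / sum(ab), truth$gene_id)
}

#' Simulate one DGE tag-sequencing library
#'
#' Emulates NlaIII/MmeI library preparation: each read carries the 21-nt tag
#' anchored at the 3'-most eligible CATG of a transcript drawn multinomially
#' in proportion to its abundance, padded to 49 nt with a constant adapter
#' suffix. Per-base iid substitution errors are applied across the read.
#' Transcripts without an eligible CATG site contribute no reads and are
#' recorded in `dropped_genes`; abundance is renormalized over detectable
#' genes so the library always holds exactly `library_size` reads.
#'
#' @param transcriptome A `transcriptome`.
#' @param abundance Named numeric vector of relative gene abundances (e.g.
#'   from [condition_abundance()]); need not sum to 1.
#' @param library_size Number of reads to generate.
#' @param error_rate Per-base substitution probability in `[0, 0.25)`.
#' @param seed Integer RNG seed; identical seeds give byte-identical output.
#' @param library_id,condition,replicate Library metadata carried through the
#'   pipeline.
#' @param site_leakage Probability that a read originates from a random
#'   non-3'-most eligible CATG site (incomplete digestion); default 0.
#' @return A `simulated_library`: list with `reads` (data.frame `sequence`,
#'   `count`; counts sum to `library_size`), `truth_counts` (named per-gene
#'   read counts), `dropped_genes`, and the metadata fields.
#' @export
simulate_tag_reads <- function(transcriptome, abundance, library_size,
                               error_rate = 0, seed = 1L,
                               library_id = "lib1", condition = "control",
                               replicate = 1L, site_leakage = 0) {
  if (error_rate < 0 || error_rate >= 0.25)
    stop_domain("`error_rate` must be in [0, 0.25)")
  if (library_size < 1) stop_domain("`library_size` must be >= 1")
  if (is.null(names(abundance)))
    stop_domain("`abundance` must be named by gene_id")

  pos <- vapply(transcriptome$sequence, eligible_catg_pos, integer(1),
                USE.NAMES = FALSE)
  eligible <- !is.na(pos)
  dropped <- unique(transcriptome$gene_id[!eligible])
  tx <- transcriptome[eligible, , drop = FALSE]
  pos <- pos[eligible]
  ab <- abundance[tx$gene_id]
  if (any(is.na(ab)) || sum(ab) <= 0)
    stop_domain("no detectable gene has positive abundance")

  tags <- substr(tx$sequence, pos, pos + TAG_LENGTH - 1L)
  n_alt <- integer(nrow(tx))
  alt_tags <- vector("list", nrow(tx))
  if (site_leakage > 0) {
    for (i in seq_len(nrow(tx))) {
      hits <- gregexpr("CATG", tx$sequence[i], fixed = TRUE)[[1]]
      hits <- hits[hits + TAG_LENGTH - 1L <= tx$length[i] & hits != pos[i]]
      if (length(hits) > 0)
        alt_tags[[i]] <- substr(rep(tx$sequence[i], length(hits)),
                                hits, hits + TAG_LENGTH - 1L)
      n_alt[i] <- length(hits)
    }
  }

  adapter_suffix <- substr(tag_adapter(), 1L, READ_LENGTH - TAG_LENGTH)

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, library_size, ab / sum(ab)))
    read_tag <- tags
    # incomplete-digestion leakage: some reads use a non-3'-most site
    leak <- if (site_leakage > 0) stats::rbinom(length(counts), counts,
                                                ifelse(n_alt > 0, site_leakage, 0))
            else integer(length(counts))
    main_counts <- counts - leak
    seqs <- paste0(read_tag, adapter_suffix)
    read_df <- data.frame(sequence = seqs, count = main_counts,
                          gene_id = tx$gene_id, stringsAsFactors = FALSE)
    if (any(leak > 0)) {
      extra <- lapply(which(leak > 0), function(i) {
        pick <- sample(alt_tags[[i]], leak[i], replace = TRUE)
        data.frame(sequence = paste0(pick, adapter_suffix),
                   count = 1L, gene_id = tx$gene_id[i],
                   stringsAsFactors = FALSE)
      })
      read_df <- rbind(read_df, do.call(rbind, extra))
    }
    read_df <- read_df[read_df$count > 0, , drop = FALSE]

    if (error_rate > 0 && nrow(read_df) > 0) {
      p_any <- 1 - (1 - error_rate)^READ_LENGTH
      n_mut <- stats::rbinom(nrow(read_df), read_df$count, p_any)
      mut_src <- rep(read_df$sequence, n_mut)
      mut_gene <- rep(read_df$gene_id, n_mut)
      read_df$count <- read_df$count - n_mut
      if (length(mut_src) > 0) {
        mutated <- mutate_reads(mut_src, error_rate)
        read_df <- rbind(
          read_df[read_df$count > 0, , drop = FALSE],
          data.frame(sequence = mutated, count = 1L, gene_id = mut_gene,
                     stringsAsFactors = FALSE))
      }
    }

    truth_counts <- tapply(read_df$count, read_df$gene_id, sum)
    truth_counts <- stats::setNames(as.integer(truth_counts),
                                    names(truth_counts))
    structure(list(
      library_id = library_id, condition = condition,
      replicate = as.integer(replicate),
      reads = read_df[, c("sequence", "count")],
      truth_counts = truth_counts,
      dropped_genes = dropped, seed = as.integer(seed),
      library_size = as.integer(library_size), error_rate = error_rate),
      class = "simulated_library")
  })
}

# Apply >= 1 substitution errors to each read (per-base rate `e`, conditioned
# on at least one error having occurred).
mutate_reads <- function(reads, e) {
  n <- length(reads)
  L <- nchar(reads[1])
  k <- sample.int(L, n, replace = TRUE, prob = stats::dbinom(1:L, L, e))
  mat <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    p <- sample.int(L, k[i])
    mat[i, p] <- vapply(mat[i, p],
                        function(b) sample(setdiff(bases, b), 1L),
                        character(1), USE.NAMES = FALSE)
  }
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

#' @export
print.simulated_library <- function(x, ...) {
  cat(sprintf("simulated_library '%s' (%s, rep %d): %d reads, %d genes, %d dropped\n",
              x$library_id, x$condition, x$replicate,
              sum(x$reads$count), length(x$truth_counts),
              length(x$dropped_genes)))
  invisible(x)
}

#' Simulate a full multi-library experiment
#'
#' Generates one library per design row. Treated libraries draw from the
#' fold-change-applied abundances of `truth`; control libraries from the base
#' abundances. Replicates differ only by seed (biological replicate noise is
#' the multinomial sampling itself).
#'
#' @param transcriptome A `transcriptome`.
#' @param truth A `truth_table`.
#' @param design data.frame with columns `library_id`, `condition`
#'   (`"control"`/`"treated"`), `timepoint`, `replicate`.
#' @param library_size Reads per library.
#' @param error_rate Per-base substitution rate.
#' @param seed Base seed; library i uses `seed + i`.
#' @return Named list of `simulated_library` objects.
#' @export
simulate_experiment <- function(transcriptome, truth, design,
                                library_size = 50000L, error_rate = 0,
                                seed = 1L) {
  need <- c("library_id", "condition", "timepoint", "replicate")
  if (!all(need %in% names(design)))
    stop_domain("`design` needs columns ", paste(need, collapse = ", "))
  libs <- lapply(seq_len(nrow(design)), function(i) {
    ab <- condition_abundance(truth, design$condition[i])
    simulate_tag_reads(transcriptome, ab, library_size, error_rate,
                       seed = seed + i, library_id = design$library_id[i],
                       condition = design$condition[i],
                       replicate = design$replicate[i])
  })
  stats::setNames(libs, design$library_id)
}

#' Five-timepoint two-replicate design
#'
#' The treated-vs-control time-course layout used throughout the package's
#' examples: two conditions, five time points (1, 4, 8, 12, 24 h), two
#' biological replicates each.
#'
#' @param timepoints Character vector of time-point labels.
#' @param replicates Replicates per condition and time point.
#' @return Design data.frame (`library_id`, `condition`, `timepoint`,
#'   `replicate`).
#' @export
default_design <- function(timepoints = c("1h", "4h", "8h", "12h", "24h"),
                           replicates = 2L) {
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = c("control", "treated"),
                      timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$library_id <- sprintf("%s_%s_r%d", grid$timepoint,
                             ifelse(grid$condition == "control", "CK", "DA"),
                             grid$replicate)
  grid[, c("library_id", "condition", "timepoint", "replicate")]
}
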