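---
title: "Tag-based digital gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay

Tag-based digital gene expression (DGE) is the SAGE-descended protocol in
which each mRNA molecule is represented by a single short 3'-anchored tag
rather than by full-length reads. cDNA bound to oligo(dT) beads is digested
with NlaIII, which cuts at CATG; the retained 3'-most fragment is ligated to
an adapter whose junction creates an MmeI site, and MmeI releases a tag of
fixed length — CATG plus 17 nt — which is sequenced as part of a 49-nt read.
Expression is quantified by counting tags per gene, so the unit of
measurement is molecules, not nucleotides: a transcript's expected tag count
is proportional to its molar abundance and independent of its length. This
has consequences for normalization discussed below.

`tagdge` implements the full analysis chain for such libraries — reference
tag-library construction, tag filtering and mapping, RPKM quantification, an
exact test of differential expression, term enrichment, sequencing QC, and
qPCR validation — together with a synthetic-data generator that plants known
truth, so every stage can be tested end to end without any external data.

## The synthetic-data generator

`generate_transcriptome()` draws iid uniform A/C/G/T transcripts; with
`catg_guarantee` a CATG site with at least 17 nt downstream is planted when
missing, making every gene detectable. `truth_table()` assigns relative
molar abundances (uniform, or log-normal with sdlog 1 — the skewed profile
typical of transcriptomes) and plants log2 fold changes on a chosen subset,
with signs alternating so both directions are exercised; abundances are
renormalized to sum to one within each condition, which means planting
changes also shift null genes' proportions slightly (by the renormalization
factor), exactly as competition for sequencing capacity does in real
libraries.

`simulate_tag_reads()` draws a multinomial sample of the configured library
size over detectable genes, emits for each molecule the tag anchored at the
*3'-most* eligible CATG site, pads it to 49 nt with a constant adapter
suffix (tag at offset 0 — the protocol fixes the read length but not the
layout, so the package documents its own), and applies iid per-base
substitution errors across the read. Substitutions are the relevant error
class because downstream mapping tolerates one mismatch; indels, PCR
duplication and GC bias are deliberately not modelled. Quality strings are
constant: filtering in this pipeline operates at the tag level. An optional
`site_leakage` parameter lets a fraction of reads originate from
non-3'-most CATG sites (incomplete digestion); it defaults to 0 because the
protocol gives no rate to emulate.

The defaults follow the study conditions the package emulates: five time
points, control versus treated, two biological replicates per condition,
and per-base error around 0.1–0.5%. Real libraries run to ~7 × 10^6 tags;
the bundled analyses and tests use 10^4–10^6 tags so that the whole suite
runs in minutes — counts scale linearly and no algorithm changes with
depth (the read store is run-length encoded, so noiseless simulations at
5 × 10^7 tags cost no more than the distinct-tag count).

What passing tests on these simulations shows is that the *pipeline
arithmetic* is right: counts are conserved, planted effects are recovered,
error control holds under the generative model. What they cannot show is
robustness to features the generator omits — real 3' bias, PCR artefacts,
annotation errors, biological replicate variance beyond multinomial
sampling.

## Reference library and clean tags

`build_reference_library()` indexes **all** CATG+17 sites of every
transcript (0-based positions, plus strand only — transcripts are
sense-strand mRNA), while the simulator draws reads only from the 3'-most
site. The asymmetry is intentional: the in-silico reference must cover every
tag a read could produce, but bead capture retains only the 3'-most
fragment. A tag whose occurrences all lie in one gene is `unique_gene`;
shared 21-mers are `multi_gene` and can never contribute to gene counts.
Genes with no eligible site are reported as undetectable — a real
phenomenon of the assay (roughly `(1 - 4^-4)^(L-3)` of random L-nt
sequences lack CATG entirely).

`extract_and_filter_tags()` applies the protocol's cleaning rules in a
fixed order, logging removals per category so raw totals always reconcile:
tags containing N; adapter-only reads (tag region equals the adapter
prefix); low-complexity tags; and singletons (library copy number 1, the
signature of sequencing error at these depths). The low-complexity rule —
one nucleotide occupying at least 80% of the 17 variable positions, i.e.
14 of 17 — is the package's own testable stand-in, since vendor pipelines
never published theirs.

## Mapping and RPKM

`map_tags()` matches clean tags against the reference at Hamming distance
at most 1, using exact-match priority: a tag identical to a reference tag is
assigned there even if other reference tags lie at distance 1. This is the
standard tag-mapping convention and prevents error tags from stealing
counts. A tag is *unambiguous* when the union of genes over its accepted
hits is a single gene; only unambiguous tags enter per-gene counts.
The mapping summary tallies perfect/one-mismatch and
unique-position/multi-position categories whose identities
(`unique + multi = mapped`, `mapped + unmapped = total`,
`perfect + one_mismatch = mapped`) are asserted on every run.

RPKM is `10^9 * C / (N * L)` with `C` the gene's unambiguous tag count, `N`
the library's total mapped tags (the conventional denominator; configurable
via the `N` argument of `gene_expression()`), and `L` the length of the
gene's longest transcript — the pipeline needs *a* gene length and no
published definition exists for tag data. Because tag counts measure
molarity, dividing by `L` makes RPKM rank-match molar abundance only when
lengths are equal; the recovery analyses therefore check count identity on
variable-length transcriptomes and rank preservation on fixed-length ones,
with abundance levels spaced geometrically (factor 1.3) so multinomial
noise cannot reorder adjacent genes at the depth used (5 × 10^7). Printed
percentages use half-up rounding to 2 decimals, matching how such tables
are conventionally formatted.

## The exact test of differential expression

For a gene with `x` tags among `N1` in library 1 and `y` among `N2` in
library 2, equal expression implies that, conditional on `x`, `y` follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,\left(1+\frac{N_2}{N_1}\right)^{x+y+1}},$$

the Audic–Claverie conditional distribution — the unique published statistic
taking exactly these four inputs. This is the negative binomial with size
`x + 1` and success probability `N1 / (N1 + N2)`, so both tails are computed
through the regularized incomplete beta function (`pbeta`): no factorials
are ever formed and the test is stable for library sizes beyond 10^7. The
two-sided p-value doubles the smaller of the inclusive tails
`P(Y <= y | x)` and `P(Y >= y | x)` and caps at 1.

Two numerical footnotes. First, this doubled-tail convention is not exactly
symmetric under exchanging the libraries at small counts (the conditional
distributions for `y | x` and `x | y` differ); the one-sided tails do obey
the exact duality `P(Y >= y+1 | x; N1, N2) = P(X <= x | y; N2, N1)`, which
the test suite asserts, and the two-sided value is validated against direct
summation of the mass function to 10^-9 relative error over the full grid
`x + y <= 500` at depth ratios 0.5, 1 and 2. Second, at `x = y = 0` the
statistic equals 1 only for equal depths; at unequal depths it is
`2 min(N1, N2) / (N1 + N2)` — still never significant.

Significance thresholds are FDR <= 0.001 (Benjamini–Hochberg, via
`p.adjust`) jointly with |log2 ratio| >= 2. The log2 ratio compares
normalized proportions `(y/N2) / (x/N1)` with a pseudocount of 1 added
*only* on a zero side, so on/off genes report finite large ratios while
nonzero counts are untouched; an RPKM-based ratio is equivalent up to the
length factor, which cancels within a gene. Replicates are pooled per
condition before testing — the two-library formulation of the statistic —
with `pool_replicates = FALSE` available to test replicate pairs
separately.

Error-control properties verified by the acceptance suite: on all-null
pairs of libraries (2,000 genes, 10^6 tags each, 200 replicates) the
fraction of genes called at the joint threshold stays below 0.005; on a
planted design (20 genes at |log2fc| = 3 among 500 nulls, 10^6 tags per
library) at least 90% of planted genes are recovered with no sign errors
and no false calls.

## Term enrichment

`enrich_terms()` forms, per term, the counts `N` (background genes with any
annotation — the background is annotated genes, not the whole
transcriptome), `n` (DEGs within it), `M` (genes carrying the term), `m`
(DEGs carrying it), and computes the hypergeometric upper tail
`P(X >= m)` via `phyper` (exactly 1 at `m = 0`). GO-style significance uses
Bonferroni (`min(1, k p)` at alpha 0.05); pathway-style significance uses
Benjamini–Hochberg Q-values at 0.05 — "Q-value" is taken as BH, with
Storey's estimator a possible alternative not currently implemented.
Annotations are flat gene–term pairs; propagation up an ontology DAG is out
of scope, since no propagation rule is part of the pipeline being modelled.
The implementation is checked against exhaustive log-binomial enumeration
for all valid configurations with `N <= 30` at 10^-12.

## Sequencing QC

`saturation_analysis()` subsamples the unambiguous tag stream at increasing
fractions and counts detected genes. Subsamples are *nested* — one
permutation, prefix subsets — so curves are monotone by construction rather
than merely in expectation; detection at a subsample of size `k` from a
uniform library follows the classical occupancy expectation
`m (1 - (1 - 1/m)^k)`, which the tests verify to 3 SD. A plateau is flagged
when the last 10% of reads adds fewer than 0.5% new genes.
`gene_body_distribution()` histograms relative tag-start positions over 100
gene-body bins and reports a dynamic range defined as
`log10(max RPKM / min nonzero RPKM)` — the package's own explicit
definition, since "dynamic range" is used loosely in the field.

## qPCR validation

`ddct()` implements relative quantification by 2^-ddCt: per replicate,
dCt = Ct(target) - Ct(reference); ddCt is the treated-minus-control
difference of mean dCt; fold change is 2^-ddCt. The estimator is invariant
to any constant Ct offset (machine calibration cancels) and inverts exactly
under swapping conditions. The reported SD is taken over treated-replicate
2^-dCt values normalized to the control mean — mean ± SD is how such tables
are reported, and this is the package's explicit choice of method. The
p-value is an equal-variance two-sample t-test on dCt values (Welch by
flag); idealized zero-variance inputs yield `NA` rather than an error.
Fold changes below 1 are displayed as negative reciprocals
(`-1/fold`), the fold-repression convention of published validation tables;
`concordance()` joins DGE and qPCR results and counts sign and significance
agreement. The bundled validation table (20 measurements, two flagged
non-significant) exercises this bookkeeping; `simulate_qpcr()` generates Ct
data with known fold changes for recovery tests.

## Pipeline orchestration and problem sizes

`run_pipeline()` chains the stages under a single configuration (R list or
YAML), writes every table plus a manifest (package version, seeds, input
digests, per-stage row counts), and is byte-reproducible for a fixed seed.
The `analysis/` scripts present the same chain as a narrated, step-by-step
workflow at a scale chosen for interactive use: 150 genes, twenty libraries
of 30,000 tags, 12 planted genes. The acceptance script uses 520 genes and
10^6-tag libraries for the planted-recovery run. These sizes are the
package's chosen demonstration conditions; all statistics are
depth-agnostic.

## Known limitations

- Biological replicate variability beyond multinomial sampling
  (overdispersion) is neither simulated nor modelled; the exact test is a
  two-library test, and pooling replicates treats them as technical.
  Dispersion-modelling frameworks (negative binomial GLMs) are deliberately
  out of scope.
- Genome-level mapping (as opposed to transcriptome-level) is not
  implemented; published genome-section summary counts are handled by the
  reporting functions only.
- Antisense tags, isoform-level quantification and multi-mapped tag rescue
  are not supported.
- The enrichment background is a single configurable annotation table;
  separate GO and pathway backgrounds must be supplied as separate tables.
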