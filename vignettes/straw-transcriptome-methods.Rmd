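---
title: "Methods: strand-specific quantification, induction filtering, and antisense detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-specific quantification, induction filtering, and antisense detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawdeg)
library(dplyr)
```

# The analysis problem

When a saprotrophic fungus such as *Aspergillus niger* is moved from a simple
sugar onto a lignocellulosic substrate like milled wheat straw, it remodels
its transcriptome drastically: genes encoding plant-cell-wall-degrading
enzymes (the CAZy classes GH, CE and PL) rise from a few percent to roughly a
fifth of the mRNA population. Strand-specific RNA-seq of such experiments
supports four analyses that this package implements as one pipeline:

1. **strand-aware quantification** of single-end stranded reads per gene,
2. **count-based differential expression** with three independent tests,
3. an **induction filter** that defines "strongly induced" gene lists, and
4. **natural antisense transcript (NAT)** quantification with detection of
   antisense:sense dominance switches between growth conditions.

A stranded-read simulator with complete ground truth makes every stage
testable without any external data.

# Gene models and counting

A gene model is the union of all exons of all its transcripts; one expression
value per gene is produced, with the exon-union length `L` as the length
term. Internally all intervals are 0-based half-open; GFF3/GTF input is
converted on read. The union choice (rather than a representative transcript)
is this package's own convention: with per-gene (not per-isoform)
quantification it is the length measure consistent with counting any exonic
read.

Counting follows the union overlap rule of the `htseq-count` family: per
read, the set of genes whose exon union overlaps at least one base of at
least one aligned block is formed; the read is counted iff that set is a
singleton. Ambiguous and feature-less reads still count toward the library
size `N`, because "per million mapped reads" is a mapping-level denominator
(this is a documented assumption: published analyses rarely state whether
ambiguous reads stay in `N`). Only primary alignments are used. Reads
aligned to rRNA references are removed before anything else and never enter
`N`.

The **sense convention** is `protocol = "forward"`: the read strand equals
the gene strand, as produced by forward-stranded whole-transcriptome
protocols of SOLiD-era single-end sequencers; a `reverse` flag covers
dUTP-style libraries.

**Antisense counts** are the mode difference `AS = max(0, U - S)` between
unstranded and stranded-sense counting of the same library. The clamp at
zero handles the one configuration where the difference can go negative: a
read that is sense to gene B but antisense to an overlapping gene A is
assigned to B in stranded mode yet ambiguous in unstranded mode. Such
residuals are reported, never silently dropped.

# Expression values

`RPKM = 1e9 * C / (N * L)`. Replicates of a condition are pooled by
**summing counts and library sizes** before the formula is applied
("combined mapping"), not by averaging per-replicate RPKMs; a per-library
mode exists for reproducibility checks (squared Pearson correlation of
`log2(RPKM + 1)`, which exceeds 0.9 for replicate libraries at the
simulator's default depth). Antisense RPKM deliberately reuses the sense
gene's `L` and the same `N`, even though NATs extend beyond the annotated
gene: giving NATs their own length model would make sense/antisense values
incomparable.

# The three significance tests

All three operate on counts, not RPKMs:

* **Poisson likelihood-ratio test** (per-lane): gene counts are Poisson with
  per-library mean `lambda * s_i`; the alternative allows one rate per
  condition. `Lambda = 2 * sum_i x_i log(lambda_c(i)/lambda)` is compared to
  chi-squared with 1 df. Because the per-condition MLE is the pooled ratio,
  the per-lane statistic reduces exactly to its pooled form.
* **Fisher's exact test** on the pooled 2x2 table
  `[cA, nA - cA; cB, nB - cB]`, two-sided by the minimum-likelihood rule
  with the conventional `1 + 1e-7` tie tolerance, so results agree
  bit-for-bit with the standard implementation and with exhaustive
  hypergeometric enumeration.
* **MA-plot random-sampling (MARS) z-test**: under the null both counts are
  binomial with a common `p_hat`; a delta-method bivariate-normal model of
  `(M, A)` yields `E(M | A)` and `Var(M | A)` and a standard-normal z-score.

For the MARS moments, the leading-order delta-method terms
(`Var(log2 c_i) = (1 - p_hat)/(n_i p_hat ln^2 2)`, `E(log2 c_i) =
log2(n_i p_hat)`) are biased at moderate counts: at a mean count of 100 the
variance is low by about `1.5/(n p_hat)^2`, which a 1e5-draw Monte-Carlo
oracle resolves clearly. The implementation therefore carries the
second-order corrections

```
E(log2 c)  = (log mu - q/(2 mu)) / ln 2
Var(log2 c) = (q/mu + (2.5 q^2 - q + 2 p q)/mu^2) / ln^2 2,   mu = n p_hat
```

which match the exact distribution of `log2 Binomial(n, p)` to within 0.05%
at `mu = 100`. The corrections change p-values negligibly but are the form
validated against simulation; the test suite asserts the match at three
Monte-Carlo standard errors. Counts of zero are replaced by 0.5 for the M/A
computation only (flagged); a degenerate `p_hat` of 0 or 1 returns p = 1
with a flag.

Fisher and MARS pool replicates (their native two-library form); the LRT
uses per-lane counts. No multiple-testing correction is applied by default —
induced-gene lists in this field are defined by raw `p < 0.001` on all three
tests — but a Benjamini–Hochberg switch is available.

# The induction filter

A gene is called strongly induced when

* fold change `RPKM_target / RPKM_baseline >= 20`,
* `RPKM_target >= 50`, and
* all three tests give `p < 0.001` (when count data are available).

A baseline RPKM of exactly 0 with an expressed target satisfies the fold
criterion with an infinite reported fold (zero-baseline policy) — published
tables contain such rows. When the filter is applied to published RPKM
tables that carry no counts, the two expression criteria alone decide; this
is how the package reproduces the printed 30-gene CAZy and 28-gene non-CAZy
induced lists exactly.

# Antisense analysis

Per condition, the antisense read fraction is `sum(AS counts)/sum(N)`
exactly. Genes with antisense RPKM above `theta_as = 1` in at least one
condition form the NAT gene list; for those, the ratio `rho = AS/S` is
computed per condition (`S = 0` flags the ratio undefined, never an error).
A **ratio switch** is called when `rho > 1` in the repressing condition,
`rho < 1` in the inducing condition, and the sense transcript is induced at
least 20-fold. The thresholds (`rho` crossing 1; 20-fold sense induction)
are explicit configuration, since dominance switching is otherwise a
qualitative notion.

# Category (CAZy) summaries

RPKM is proportional to molar transcript abundance, so the percentage of
total mRNA held by a gene set is `100 * sum(RPKM in set)/sum(RPKM)`. The
transcriptome denominator includes every annotated gene, categorised or not
(a documented choice; excluding unannotated genes would inflate shares).
Family shares are reported within the categorised set, in decreasing order
with lexicographic tie-breaks; classes (GH/CE/PL) are inferred from family
prefixes of a user-supplied two-column gene-to-family table.

# The simulator

`sim_config()` fixes the study conditions; `simulate_dataset()` emits a
genome FASTA, a GTF, per-replicate SAM alignments, a category table and
complete ground truth, all reproducible byte-for-byte from one seed. The
defaults describe a desk-scale version of a glucose-to-straw induction
experiment:

* 300 genes on 4 chromosomes, exon-union lengths log-normal around 1.4 kb,
  1–4 exons, introns 50–300 bp, intergenic gaps wide enough that antisense
  flanks never reach a neighbour;
* two conditions x 3 replicate libraries of 2e6 single-end 50-bp
  stranded reads (Poisson counts per gene and orientation);
* 15% of genes induced with planted folds log-uniform on 20–4000x from
  repressed baselines (~3 RPKM, log-normal), emulating the span of published
  straw-induction tables;
* a CAZy-like category covering 15% of genes whose mRNA share is calibrated
  to 3% under glucose (with one glucoamylase-like gene at 65% of the
  category) and 19% on straw;
* an antisense program on 10% of genes: unspliced transcripts spanning the
  whole locus plus 100-bp flanks on the opposite strand, with a global
  countable antisense fraction of 2% of mapped reads, and 4 induced genes
  planted as ratio switches with glucose AS:S ratios in [2, 4] cut to 30%
  on straw;
* 5% residual rRNA reads on a dedicated contig.

Three numerical choices deserve note. First, the **antisense budget is
defined over countable reads** — reads overlapping the exon union of exactly
one gene — because the mode-difference method cannot see purely intronic or
flanking antisense coverage; emission rates are scaled up by each gene's
exon-overlap probability so that the planted 2% is what the pipeline should
measure. Second, **category-share calibration happens in transcript-abundance
space after induction folds are applied**, so planted folds are
pre-normalisation quantities; ground truth records realised RPKMs, folds,
ratios and shares, and all recovery tests compare against the realised
truth. Third, **switch genes are drawn from the induced non-category
genes**, whose repressed baselines are untouched by the category
calibration; their glucose ratios are planted in [2, 4] rather than at the
published example's 1.6 so that antisense dominance is a property of the
design rather than a coin flip at ratio parity under Poisson noise.

Replicate noise is Poisson, matching the LRT's model; the generator does not
model over-dispersion between biological replicates, sequencing errors,
mapping bias, positional coverage bias, or colour-space artefacts. Passing
recovery tests therefore demonstrates correctness of the pipeline's
arithmetic and logic under its own statistical assumptions — not robustness
to the extra-Poisson variability of real biological replicates, for which
negative-binomial methods would be the tool of choice.

Problem sizes in the test suite (300 genes, 6 x 2e6 reads; 1e4 null genes
for calibration; 1e5 Monte-Carlo draws) are the package's chosen desk-scale
study conditions: large enough that binomial/Poisson error bands are tight,
small enough to re-run routinely.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg, "sim")
counts <- quantify_libraries(sim$libraries, sim$annotation, rrna_refs = sim$rrna_refs)
expr <- build_expression_table(counts, sim$annotation)
tests <- de_test(counts, "glucose_48h", "straw_24h")
de <- apply_induction_filter(expr, "glucose_48h", "straw_24h", tests = tests)
glance(de)
autoplot(de)

asum <- antisense_summary(counts, expr)
rec <- as_s_ratios(expr, c("glucose_48h", "straw_24h"))
detect_ratio_switch(rec, "glucose_48h", "straw_24h")
percent_of_transcriptome(expr, sim$categories$gene_id, "straw_24h")
```

# Known limitations

* Single-end logic only; no paired-end fragments, no duplicate marking.
* One gene model per gene; no isoform-level quantification.
* The mode-difference antisense estimate is blind to antisense coverage
  outside exons and slightly conservative where genes overlap.
* The three tests share the Poisson/binomial sampling model and will be
  anti-conservative on over-dispersed biological replicates.
* The simulator's category-share calibration rescales planted folds; the
  recorded realised truth, not the nominal fold draw, is the reference.
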