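---
title: "Methods: differential expression, signature recurrence and TF co-binding modules"
author: "gyncomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression, signature recurrence and TF co-binding modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gyncomod)
```

# Scope

`gyncomod` implements a comparative cancer-transcriptomics and regulatory
genomics pipeline: per-tissue two-group differential expression on
microarray-style intensity matrices, cross-signature overlap and recurrence
scoring against GMT collections, strand-aware promoter-window transcription
factor (TF) binding with up/down enrichment, and the discovery of TF
co-binding modules from ChIP-style peak sets. Everything runs end to end on
synthetic data with planted structure, so each stage's statistical behaviour
is testable without any external download. This vignette records the models,
the tunable parameters, and the design decisions taken where the procedure
was genuinely open.

# Differential expression

Input matrices hold positive, linear-scale intensities (RMA-style
normalization is assumed upstream and is out of scope). Genes represented by
several probes are collapsed by keeping the probe with the highest mean
intensity across *all* samples; exact ties go to the lexicographically
smallest probe id so the collapse is deterministic.

Testing uses the classical pooled-variance (Student) two-sample t statistic
computed on the **unlogged** values, two-sided. Log-scale testing and the
Welch statistic are exposed as options (`log_scale`, `welch`) but are not the
default: the pipeline's contract is the linear-scale Student test. Two
degenerate rules avoid undefined statistics: when both groups have zero
variance the p-value is 1 if the means are equal and 0 otherwise.

The effect size is the **signed fold change**
$\mathrm{fc} = \bar{x}_\text{cancer}/\bar{x}_\text{normal}$ when the cancer
mean is at least the normal mean, and
$-\bar{x}_\text{normal}/\bar{x}_\text{cancer}$ otherwise, so
$|\mathrm{fc}| \ge 1$ always and the sign carries the direction. A gene is
called *up* when $p < 0.05$ and $\mathrm{fc} > 1.5$ (strictly), *down*
symmetrically, *ns* otherwise. Both thresholds live in `de_thresholds()`;
no multiple-testing correction is applied by default (raw-p calling is the
pipeline's contract; Benjamini–Hochberg is available via `adjust = "BH"`).

Sample-profile similarity (`correlate_profiles`) is Pearson correlation over
the gene intersection of two matrices, computed on log2 values by default —
array-to-array agreement is conventionally judged on the log scale, while
the *test* runs on the linear scale; the flag `log2_transform = FALSE`
disables the transform.

# Signature overlap and recurrence

Gene sets follow GMT semantics; symbols are upper-cased and deduplicated,
and symbol aliasing is deliberately out of scope. Overlap between a query
list and a signature is tested with the one-sided hypergeometric tail
$P(X \ge k)$ — the over-representation convention; the classical pass rule
is **more than 5 genes in common** (read strictly, so `min_common = 6`) at
$p < 0.01$. Signature collections can be merged by tissue of origin before
testing (union of member sets; provenance retained). Recurrence scoring
counts, per query gene, the number of collection sets containing it; genes
in **more than five** sets (`min_studies = 6`) form the robust signature.
Both boundary readings are configuration parameters because the external
databases needed to adjudicate them are not part of this package.

The universe for overlap tests defaults to the post-collapse platform gene
count; it can be overridden (`universe_size`) when a database-specific
universe is more appropriate — which one the original analyses used is not
stated anywhere authoritative, so the choice is explicit configuration.

# Promoter windows and TF binding

Coordinates are BED-style: 0-based, half-open `[start, end)`. The promoter
window around a TSS is strand-aware: on the + strand
`[tss - upstream, tss + downstream)`, mirrored on the − strand, clipped at
zero. Two window presets matter: −1000/+200 bp for TF-target annotation and
enrichment, and −2500/+2500 bp for module assignment.

A gene is *bound* by a TF when any peak overlaps its promoter window by at
least one base; an abutting peak (sharing only the half-open boundary) does
not bind. A midpoint-based predicate (`mode = "midpoint"`) is provided as an
alternative reading. Per-TF enrichment among upregulated genes is the
hypergeometric tail on (bound ∩ up) against the annotation universe, and the
headline descriptive statistic is the **up/down ratio**: the fraction of
upregulated genes bound divided by the fraction of downregulated genes
bound, with an infinity sentinel when the TF binds upregulated genes but no
downregulated one.

# Module discovery

The module procedure works purely from the peak files:

1. **Overlap counting.** For TFs $i, j$, the directed count $c_{ij}$ is the
   number of $i$ peaks overlapping at least one $j$ peak. Directed counts
   are not symmetric; the stored raw count is $\min(c_{ij}, c_{ji})$, which
   is symmetric and bounded by both peak-set sizes. Alternatives (mean,
   merged-union counting) were considered; the minimum is the most
   conservative and is recorded in the matrix object.
2. **Normalization.** The raw count is divided by the smaller peak-set
   size — the overlap (Szymkiewicz–Simpson) coefficient — mapping identical
   sets to 1 and disjoint sets to 0 regardless of size imbalance. This is
   the natural reading of "normalization by the number of binding sites";
   Jaccard is available (`method = "jaccard"`).
3. **Clustering.** Rows of the normalized matrix are clustered with
   unweighted average linkage (UPGMA) on correlation distance
   $d = 1 - r_\text{Pearson}$ between row profiles, cut at `k` modules.
   `k = 4` is the default; a mean-silhouette scan over $k \in [2, n-1]$ is
   available (`k = "auto"`) because nothing in the procedure itself fixes
   the module count. Equal-height merges are resolved toward the
   lexicographically smallest label pair, which makes the partition
   deterministic and invariant to input order — the property the test suite
   checks by permuting TFs.
4. **Gene assignment.** A gene belongs to module $M$ when at least
   `min_tfs = 2` of $M$'s members bind its −2500/+2500 bp window. The
   "at least two regulators" rule admits two readings: two regulators *of
   that module* (primary here — it is the only reading under which
   module-specific assignment is meaningful) or two regulators overall
   (`scope = "global"`). Genes may belong to several modules.

Downstream statistics: per-module coverage of the up and down lists with a
hypergeometric p and the up/down coverage ratio; pair co-occurrence folds
(fraction of up genes assigned to both modules over the same fraction for
down genes); ranking of modules per biological-process term by coverage;
and module-versus-external-set association by chi-square on the 2×2 table
over the universe, Yates-corrected automatically when any expected cell is
below 5 ("with or without correction, when needed"). Degenerate tables with
a zero margin return statistic 0, p 1, sign 0 instead of erroring, because
empty categories arise legitimately in pipeline output.

# Statistical conventions

* Enrichment p-values are one-sided upper tails, $P(X \ge k)$; the
  two-sided Fisher alternative is exposed where a symmetric question is
  asked.
* `fisher_exact_2x2(greater)` on the table $(k, n-k; K-k, N-K-n+k)$ equals
  the hypergeometric tail by construction; the suite verifies this
  exhaustively for all universes up to $N = 20$.
* Infinity sentinels (never `NA`) mark ratios with an empty denominator but
  a non-empty numerator; `NaN` marks 0/0.
* Pearson correlation on a constant vector is an error, not silently zero.

# The synthetic-data generator

The generator emulates the study design the pipeline targets: three tissues
with cancer/normal groups of 5/5, 7/5 and 6/7 samples, ~10% of genes
differentially expressed (5% up, 5% down per tissue) of which 30% are
shared across tissues — consistent with the 15–40% cross-tissue signature
overlap such comparative designs report. Expression is log-normal: each
gene gets a log-normal baseline mean (meanlog 6, sdlog 1), planted genes
have the cancer mean multiplied or divided by `effect_size` (default 3),
and every value carries multiplicative log-normal noise with coefficient of
variation `noise_cv` (default 0.2). Multi-probe genes (1–3 probes, probe
affinities log-normal) exercise the collapse step. All generators are pure
functions of `(config, seed)`.

The annotation places genes 6 kb apart on one synthetic chromosome with
alternating strands, so −2500/+2500 windows are pairwise disjoint and each
1 kb intergenic gap offers two non-overlapping 200 bp peak slots allocated
globally without replacement — distinct peak groups never collide by
construction.

Peak sets plant the module structure directly. Each TF's peaks decompose
into: a module core shared by all module members (fraction
`within_module_overlap`, default 0.9, of the TF's peaks, minus the global
share), a small global core shared by *all* TFs (fraction
`between_module_overlap`, default 0.05) setting the background overlap, and
TF-specific intergenic background. Of the module core,
`promoter_core_fraction` (default 0.3) sits at promoters; the rest is
shared intergenic background. Keeping the promoter share partial serves two
purposes: the per-module promoter pools can be disjoint (so modules are
identifiable) and the up-bias does not saturate (if nearly every promoter
were targeted, biased and unbiased genes would be covered alike).

Promoter targets come from one joint sample over genes, with planted-up
genes weighted by `up_bias` (default 3), dealt round-robin across modules
by planted class (up / down / background). The dealing makes modules
exchangeable in composition, so the planted up/down coverage ratio is a
property of the configuration rather than of per-module sampling noise.
Configured module pairs (`cotarget_pairs`, default (M1,M2) and (M3,M4))
additionally share a co-target pool (`cotarget_genes`, default 44 genes,
carved out of each participating module's intergenic core so peak counts
and overlap targets are unchanged). Co-target pools are reserved before the
module pools and stratified by planted class with the class counts a
weighted draw gives in expectation; the resulting planted pair
co-occurrence fold sits near `up_bias`, inside the 2.5–10-fold span such
analyses report.

Signature collections draw `signature_size` genes per set uniformly,
insert each planted recurrent gene into exactly `recurrence_depth` sets
(default 7), and cap background genes strictly below the planted depth so
that recovery at the matching threshold is exact by construction.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: probe-level platform artifacts, gene–gene
expression correlation, batch and array effects, realistic peak-width and
peak-score distributions, multiple TSSs per gene, overlapping promoters,
and any genome sequence context. The generator validates the statistical
machinery, not biological discovery.

# Problem sizes and runtime choices

The test suite and the acceptance script work at sizes chosen to make the
statistics informative while keeping a full run inside a few minutes on one
CPU: 2000-gene expression matrices with 10 null replicates for the type-I
error check (20 000 tests, so the binomial standard error on the 5% rate is
about 0.15 percentage points), 1000-gene / 300-peak configurations for ten
module-recovery replicates, 100 random interval instances of up to 1000
intervals for the overlap oracles, and a default 2000-gene bundle for the
end-to-end statistics.

# Known limitations

* The unlogged Student test is faithful to the pipeline's contract but is
  not the recommended modern practice (moderated log-scale statistics);
  options exist but defaults follow the contract.
* Gene-symbol handling is purely syntactic (upper-casing); no alias
  resolution.
* The module count `k` must be supplied or chosen by the silhouette scan;
  there is no inferential test for the number of modules.
* Enrichment treats catalogs as flat term lists; no ontology hierarchy or
  term-term dependence is modeled.
* With `scope = "per_module"`, genes bound by two regulators from
  *different* modules are unassigned; the global reading is available but
  blurs module specificity.
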