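---
title: "Stage-specific lncRNA–immune-checkpoint synergy: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific lncRNA–immune-checkpoint synergy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagesynergy)
```

## The question and the model

As a tumour progresses, the regulatory coupling between long noncoding RNAs
(lncRNAs) and immune-checkpoint (ICP) pathways is not static: a pair of
genes may co-express tightly in one stage and not at all in another. This
package quantifies that behaviour. The unit of analysis is a candidate
lncRNA–mRNA pair anchored to at least one ICP gene: the mRNA is either an
ICP itself or shares a protein–protein interaction (PPI) edge with one. We
read "proteins that interact with ICPs" as first neighbours only; the depth
is configurable, but distance 1 is the literal reading and keeps the
anchored set interpretable.

Within each stage $j$ the pair's Pearson correlation $r_j$ is computed over
that stage's samples, with a two-sided p-value from the $t$ reference on
$n_j - 2$ degrees of freedom, and zeroed when non-significant:
$a_j = r_j \cdot \mathbb{1}[p_j < 0.05]$ (the *adjusted* correlation). The
stage-specificity synergy score over $N$ stages is

$$\mathrm{ssLIss} \;=\; \frac{\sum_j \bigl(1 - |a_j| / \max_j |a_j|\bigr)}{N-1}
\;\cdot\; \frac{\max_j |a_j|}{0.75}.$$

The first factor measures concentration: it is 1 when exactly one stage is
significant and 0 when all stages are equally correlated. The second factor
rewards strength; the 0.75 normaliser is part of the score's definition and
is deliberately not capped, so a pair with $\max|a_j| > 0.75$ can score
above 1 (the attainable range is $[0, 4/3]$). Two degenerate conventions
are ours: when every $a_j = 0$ the formula is $0/0$ and we define the score
as 0 (no significant correlation anywhere is no synergy), and arg-max ties
for the specific stage break to the earliest stage, deterministically.

## Permutation significance

The null hypothesis is "no stage-specific structure", not "no correlation".
We therefore permute the sample-to-stage labels across all samples,
preserving stage sizes, and recompute the full adjusted-correlation +
score path in each of $B$ trials (default $B = 1000$). Permuting labels
preserves each gene's marginal distribution and the pair's pooled
correlation, which is exactly what the null should keep. The empirical
p-value uses the add-one estimator $(1 + \#\{s^{null} \ge s^{obs}\})/(B+1)$,
which is never zero and is super-uniform under the null. A pair is a
stage-specific synergy pair when this p-value is below 0.05 *and* at least
one stage is significant. Per-pair RNG substreams are keyed by
(master seed, pair id), so results are identical regardless of the order in
which pairs are scored.

Two calibration facts shape interpretation. First, the score distribution
has an atom at zero (a pair with no significant stage scores exactly 0 and
can never be rejected), so rejections come only from pairs that are
significant somewhere; the permutation test remains close to exact at the
5% level, which the test suite verifies empirically. Second, with $B$
trials the smallest attainable p-value is $1/(B+1)$; at $B = 500$ that is
0.002, comfortably below the 0.05 threshold.

## Candidate filtering

Stages with ten or fewer cases are dropped before anything else (strict
"> 10" rule); if fewer than two stages survive the analysis stops, because
the score's $N - 1$ denominator needs at least two. A catalogue pair is
retained only if at least one member is stage-differential by a
tie-corrected Kruskal–Wallis test at a raw $\alpha = 0.05$ — no
multiple-testing correction at this step, since the filter is a screen, not
an inference. Genes present in catalogues but absent from the expression
matrix are dropped with a warning rather than an error, because annotation
mismatches are routine in real data. A gene whose expression is constant
within a stage has an undefined correlation there; we set $r = 0, p = 1$
and warn. Expression is assumed already normalised and log-scaled upstream;
the package never transforms values, and every statistic downstream of the
Pearson step is rank-based or correlation-based, hence invariant to
per-gene affine rescaling.

## Pattern taxonomy

Significant pairs are classified from the *signs* of their adjusted
correlations alone, with stages partitioned into early (I–II) and advanced
(III–IV) sets. Sign conversion dominates: any pair with both positive and
negative significant stages is *stage-converted*. Otherwise location
decides: all significant stages early → *early-specific*; all advanced →
*advanced-specific*; otherwise *stage-common*. These rules are a declared
convention — the four labels are standard but their operational definitions
are not fixed anywhere — chosen so that the four categories form a
partition and single-stage pairs fall into a "specific" class by location.

## Downstream modules

**Enrichment.** Overlap between identified lncRNAs and a functional
catalogue uses the upper-tail cumulative hypergeometric
$P = 1 - \sum_{i=0}^{k-1}\binom{m}{i}\binom{N-m}{n-i}/\binom{N}{n}$,
evaluated in log space via `phyper`, so catalogue-scale inputs
($N \approx 20{,}000$) neither overflow nor underflow. The universe
defaults to all lncRNAs in the expression matrix.

**Immune-cell association.** Cell-type enrichment scores are consumed as
produced by an external scorer (e.g. xCell) — never computed here. Per
(gene, cell type, stage) we report the tie-corrected Spearman correlation
and keep raw $p < 0.05$. Early-vs-advanced score differences use a
two-sided Wilcoxon rank-sum test; the choice of test is ours (the natural
nonparametric two-group default, consistent with the rank-based flavour of
the rest of the analysis) and a t-test could be substituted without
touching any other module. Direction consistency is summarised for
(gene, cell type) relationships seen in at least 10 cancer-stage
combinations as $\max(n_+, n_-)/(n_+ + n_-)$.

**Spatial co-occurrence.** A gene is present in a spot when its count is
positive (spot-level sparsity makes any positive count meaningful; the
threshold is configurable), and a cell type is present when its score
exceeds the per-sample median, since enrichment scores have no absolute
zero. From the $2\times2$ presence table we report Fisher's exact p —
two-sided by the standard point-probability summation by default, with
one-sided tails available as a flag — and the ratio $(a+d)/(b+c)$
($\infty$ when $b+c=0$): significant with ratio $>1$ is co-occurrence,
$<1$ mutual exclusivity, anything else (including ratio exactly 1) no
call. Degenerate margins (an entity present everywhere or nowhere) are a
refusal, not a p-value. Marker-based spot cell-type scores (mean log1p
counts-per-10k over marker genes, z-scored across spots) are a simple
declared scoring rule for spot-level cell-type abundance.

**Survival.** Genes of final-stage-specific significant pairs are split
into up- and down-regulated sets by a two-sided Wilcoxon test of the final
stage against the rest, with direction from the median difference (again
our choice of test; nothing downstream depends on it beyond the gene
lists). Each set is scored per sample by PLAGE: z-score each gene across
samples, take the first right singular vector of the resulting matrix. The
SVD sign is arbitrary, so we orient the score to correlate non-negatively
with the mean z-scored set expression, making "high score" mean "high set
expression". Samples are split at the median score — ties and, for odd
cohorts, the median sample itself go to the low group, deterministically —
and groups are compared by the standard two-group log-rank test. A cohort
with no events yields a zero statistic and $p = 1$ with a warning rather
than an error, so fully censored corner cases remain usable in calibration
loops.

## The synthetic-data generator

Every input the pipeline consumes can be simulated with planted ground
truth (`synergy_sim_config()`, `simulate_study()`). The reference
configuration — used by the test suite and the acceptance script — is 3
stages of 150 samples; 20 stage-specific pairs at $r = 0.8$ (round-robin
across stages), 20 uniformly correlated pairs at $r = 0.6$, 200 null
pairs, and 30 unanchored decoy pairs that must be filtered out; 10 ICP
genes; 8 cell types with 6 planted monotone gene associations at residual
SD 0.5; a $30\times30$ spot grid with 5 planted co-occurring and 5
mutually exclusive pairs (presence 0.9 inside a planted region, 0.05
outside); and exponential survival at baseline hazard $10^{-3}$/day with a
log-hazard effect of 1 per unit signature score and independent censoring
at $5\times10^{-4}$/day. These sizes keep a full run in tens of seconds on
one core while leaving wide statistical margins for recovery checks.

Design choices worth knowing:

* Gene marginals are standard normal within each stage, and planted
  correlations are induced by Cholesky mixing
  ($y = r x + \sqrt{1-r^2}\,z$), which hits the target Pearson correlation
  exactly in expectation. Marginal family is immaterial because the
  pipeline only uses correlations and ranks.
* Each catalogued pair's lncRNA receives a small deterministic per-stage
  mean offset (0.5 SD per stage step, centred), so pair genes are
  genuinely stage-differential and pass the Kruskal–Wallis screen; a
  constant within-stage shift leaves within-stage correlations untouched.
  Setting `stage_shift = 0` produces a cohort with no stage structure at
  all, which is what the permutation-calibration checks use.
* Each generator draws from its own RNG stream at a fixed offset from the
  master seed, so adding or re-running one generator never perturbs
  another's output, and a fixed seed reproduces everything byte for byte.
* Spatial counts are Bernoulli presence times $1+\mathrm{Poisson}$
  magnitude; the analysis binarises presence anyway.

What the generator does *not* emulate: read-level sequencing noise, UMI
counts, batch effects, realistic single-cell structure, correlated gene
backgrounds, or non-exponential survival. Passing tests on synthetic data
therefore demonstrate that the implementation recovers the structures it
claims to detect at realistic sizes and calibrated error rates — not that
those structures are detectable in any particular real cohort.

## Numerical and degenerate-input conventions

* Pearson p-values: closed-form $t$ on $n-2$ df; $|r| = 1$ maps to
  $p = 0$; correlations are clamped to $[-1, 1]$ against rounding.
* All-equal Kruskal–Wallis input returns $p = 1$ (such a gene cannot be
  differential).
* Permutation trials recompute group sums via a single $O(n)$ pass over
  the pair's moment matrix, which is what keeps $B = 1000$ per pair
  affordable.
* Empty candidate lists, empty enrichment overlaps ($k = 0 \Rightarrow
  p = 1$) and all-censored survival are quiet, well-defined results;
  degenerate Fisher margins, single-stage cohorts, empty gene universes
  and one-sided median splits are refusals with informative errors.

## A short tour

```{r example, eval = FALSE}
cfg   <- synergy_sim_config(seed = 1)
study <- simulate_study(cfg)
expr  <- filter_stages(study$expr)
cand  <- build_candidates(expr, study$ppi, study$catalog, study$icps)
scan  <- score_synergy(expr, cand, B = 500, seed = 1)
glance(scan)
autoplot(scan)

calls <- classify_patterns(scan, early_stages = c(1, 2), advanced_stages = 3)
plot_pattern_distribution(calls)

sets <- stage_differential_sets(expr, unique(c(tidy(scan)$lncrna,
                                               tidy(scan)$mrna)))
ss <- signature_survival(expr, sets$up, study$survival, direction = "up")
glance(ss)
autoplot(ss)
```

`run_pipeline(pipeline_config(outdir, seed))` executes the same steps end
to end, writes every table as TSV with a provenance header (seed and
configuration hash) and a JSON run report, and is byte-reproducible under
a fixed configuration.

## Known limitations

* The per-stage correlation threshold (raw $p < 0.05$) is applied without
  multiple-testing correction, by design; interpret single-pair calls
  accordingly and rely on the permutation p for the synergy claim itself.
* The pattern taxonomy depends on the early/advanced partition; cohorts
  staged on other systems need an explicit mapping.
* Spatial calls are sample-wide: no spatial clustering, deconvolution or
  neighbourhood smoothing is attempted.
* The survival module stops at the log-rank comparison; covariate
  adjustment (Cox models) is out of scope.
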