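# stagesynergy

Tools for finding lncRNA–mRNA pairs whose co-expression is concentrated in a
single tumour stage, anchored to immune-checkpoint (ICP) genes through a
protein–protein interaction network. The package is aimed at computational
biologists studying how regulatory relationships between long noncoding RNAs
and immune-checkpoint pathways shift as cancers progress: which pairs
co-express only early, only late, in all stages, or flip sign along the way,
and what that implies for the immune microenvironment and patient outcome.

## The score

For a candidate pair, Pearson correlations are computed separately within
each tumour stage and significance-adjusted:

    adjusted r_j = r_j   if p_j < 0.05
                 = 0     otherwise

The stage-specificity synergy score over the N stages is

    ssLIss = [ Σ_j (1 − |adjusted r_j| / max_j |adjusted r_j|) / (N − 1) ]
             × ( max_j |adjusted r_j| / 0.75 )

A pair significantly correlated in exactly one stage scores
`max|adjusted r|/0.75`; a pair equally correlated in every stage scores 0.
Significance is assessed by permutation: sample-to-stage labels are shuffled
(stage sizes preserved), the whole computation is repeated, and the
empirical p-value uses the add-one convention `(1 + #{null ≥ obs})/(B + 1)`.
The stage attaining the maximum `|adjusted r|` is the pair's specific stage.

Around this core the package implements the full analysis pipeline:

* **candidate construction** — interaction-catalogue pairs whose mRNA is an
  ICP or a first PPI neighbour of one, filtered by a Kruskal–Wallis test for
  stage-differential expression (stages with ≤ 10 cases are dropped first);
* **pattern classification** — early-specific / advanced-specific /
  stage-common / stage-converted calls from the signs of the adjusted
  correlations;
* **functional-lncRNA enrichment** — cumulative hypergeometric overlap test;
* **immune-cell association** — stage-wise Spearman correlation of genes
  with externally supplied cell-type enrichment scores (e.g. xCell), with
  cancer-stage-cell process counts and direction-consistency summaries;
* **spatial co-occurrence** — Fisher's exact test and the `(a+d)/(b+c)`
  ratio on spot-presence tables to call co-occurrence or mutual exclusivity;
* **survival stratification** — final-stage up/down differential signatures
  scored per sample by PLAGE (first right singular vector of the z-scored
  set submatrix), median-split into high/low groups and compared by
  log-rank test;
* **synthetic data** — a generator that plants stage-specific, uniform and
  null pairs, monotone gene–cell associations, co-occurring/exclusive
  spatial pairs and a survival hazard tied to a signature score, so the
  whole pipeline is testable without any external download.

## Worked example

```r
library(stagesynergy)

cfg   <- synergy_sim_config(seed = 1)     # 3 stages x 150 samples;
                                          # 20 specific / 20 uniform / 200 null pairs
study <- simulate_study(cfg)
expr  <- filter_stages(study$expr)        # drop stages with <= 10 cases
cand  <- build_candidates(expr, study$ppi, study$catalog, study$icps)
scan  <- score_synergy(expr, cand, B = 500, seed = 1)
glance(scan)
#>   n_pairs n_significant n_stages     B sig_alpha perm_alpha  seed
#> 1     240            31        3   500      0.05       0.05     1

head(dplyr::arrange(tidy(scan), perm_p, dplyr::desc(ssliss)), 5)
#>   lncrna  mrna     ssliss max_abs_adjusted n_stages  perm_p specific_stage
#> 1 LNC0012 MRNA0012   1.13            0.844        3 0.00200              3
#> 2 LNC0007 MRNA0007   1.11            0.834        3 0.00200              1
#> 3 LNC0009 MRNA0009   1.11            0.832        3 0.00200              3
#> 4 LNC0019 MRNA0019   1.10            0.822        3 0.00200              1
#> 5 LNC0004 MRNA0004   1.09            0.820        3 0.00200              1

classify_patterns(scan, early_stages = c(1, 2), advanced_stages = 3) |>
  dplyr::count(pattern)
#>   pattern               n
#> 1 advanced_specific     9
#> 2 early_specific       21
#> 3 stage_converted       1
```

Of the 240 candidates, 31 pairs are called significant: all 20 planted
stage-specific pairs (ssLIss ≈ 1.1, i.e. a strong correlation in one stage
and none elsewhere; the minimum attainable empirical p at B = 500 is
1/501 ≈ 0.002) plus a handful of decoys at the 5% error rate. Each
significant pair's specific stage matches the stage in which its
correlation was planted, and the pattern calls reflect the round-robin
placement of planted pairs across stages 1–3.

The same objects feed the downstream modules: `stage_spearman()` against
`study$cell_scores`, `call_pairs()` against `study$spatial$counts`, and
`signature_survival()` against `study$survival`. `run_pipeline()` executes
everything end to end from a single `pipeline_config()` and writes TSV
outputs plus a JSON run report; `autoplot()` methods visualise scans and
survival stratifications.

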