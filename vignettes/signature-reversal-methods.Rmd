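---
title: "Signature-reversal drug repurposing: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-reversal drug repurposing: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreverse)
```

## The problem

Transcriptome-wide association studies (TWAS) impute the genetically
regulated component of gene expression from GWAS summary statistics and
SNP-expression weight panels, yielding a per-gene association z-score whose
sign indicates up- or downregulation in cases. If a disease phenotype is
characterized by such an imputed expression signature, a compound whose
induced expression profile is *anti-correlated* with it is a candidate for
counteracting the disease alterations — the signature-reversal principle
behind connectivity-map (CMap/LINCS) drug repurposing.

`sigreverse` implements this pipeline end to end for psychiatric
phenotypes of the treatment-resistant-depression (TRD) family, including
the upstream definition of TRD itself from primary-care prescription
records. Four analysis stages are covered, plus seeded generators that
plant known structure so every stage is testable without external data.

## TWAS post-processing

A TWAS emits one feature per (gene, SNP-weight panel). The stages are:

* **z to p**: `z_to_p()` computes the two-sided normal tail
  `p = 2 * pnorm(-|z|)`. Supplied p-values that disagree with the z-score
  beyond 1% relative are rejected as corrupted input; missing p-values are
  recomputed.
* **Feature collapsing**: when a gene carries features from several
  panels, `collapse_features()` keeps the one with the highest
  cross-validation R² of its expression model. Exact R² ties are broken by
  lexicographically smallest panel id — a deterministic, data-independent
  rule.
* **Significance filter**: `significance_filter()` retains features below
  the transcriptome-wide threshold, default `1.37e-6`.
* **Query sets**: `make_query_set()` takes the top *N* genes by `|z|`
  over the whole signature and splits them by sign into up/down sets.
  Two readings of "top N dysregulated genes" were possible — *N* per
  direction or *N* in total — and the total reading was chosen because the
  ranking is a single ordering of dysregulation strength; ranking by `|z|`
  rather than by p is equivalent under the normal model and remains
  well-defined when panels differ. Genes with `z = 0` carry no direction
  and never enter a query set. Ties in `|z|` break by gene id, which makes
  query sets nest monotonically in *N*.

Gene identifiers are opaque strings; `map_symbols()` converts symbols
through a static two-column table (no live annotation service), reporting
unmapped symbols instead of dropping them.

## Connectivity screening

The similarity of a query to a compound signature is the weighted
Kolmogorov–Smirnov enrichment statistic. With the signature's genes ranked
by decreasing z, a running sum gains `|z|^w / sum(|z|^w over hits)` at each
query gene and loses `1/(number of non-query genes)` elsewhere;
`weighted_es()` returns the signed extremum of largest magnitude. The
weight exponent `w` defaults to 1 (hits weighted by the signature's
z-magnitude); `w = 0` recovers the classic unweighted KS statistic. On an
exact magnitude tie between the positive and negative extremum the positive
one is reported; with continuous z-scores and `w > 0` such ties have
probability zero.

`connectivity_score()` combines the up- and down-set enrichments: when
they disagree in sign the score is `(ES_up - ES_down)/2`, otherwise 0 (a
query that is "enriched the same way" at both ends carries no directional
evidence). This combining rule is the standard CMap convention; the
one-sided variants pass the single enrichment through, negated for the
down set. Query genes absent from the library universe are dropped with a
warning, and a query losing half its genes is rejected.

Raw scores are made comparable across experimental contexts by
`normalize_scores()`: within each group (cell line × perturbagen type by
default, or one global group for small libraries) positive scores are
divided by the mean positive score and negative scores by the absolute
mean negative score. After normalization the same-signed group means are
±1 by construction, which the tests assert to 1e-12.

Significance is empirical: `screen_library()` scores one seeded panel of
`null_queries` (default 1000) random query sets of matched up/down sizes
against every signature and assigns `p = (k + 1)/(n + 1)`, two-sided on
`|score|`, so p is never zero. The null panel is shared across signatures
within a screen: the positions of a uniformly drawn random gene set in any
signature's ranking are uniform, so each signature's p-value is marginally
valid, while sharing the panel makes p-values comparable across signatures
and avoids re-drawing hundreds of thousands of random sets. The exported
`empirical_p()` draws a fresh seeded null for a single signature.
Multiple testing uses Benjamini–Hochberg q-values (`fdr_adjust()`, backed
by `stats::p.adjust`).

Candidate signatures then pass five criteria
(`apply_selection_criteria()`): negative normalized score; FDR q below a
deliberately liberal 0.10; a compound (not genetic) perturbagen; not on
the exclusion list (existing antidepressants/antipsychotics, toxic
compounds); and passing library QC. A signature failing *only* QC is
replaced by the QC-passing signature(s) of the same compound with the most
similar metadata — same cell line outranking same dose outranking same
exposure time — preferring high-quality flags and keeping all equally
similar alternatives. The criteria are evaluated on the normalized score
(sign-consistent with the raw score either way) for every query size, and
a signature passing at any size is a candidate.

## Reversal ranking

Ranked dissimilarity combines three methods — signed two-sample KS,
Spearman and Pearson correlation — evaluated over all shared genes and
over the nested top-`{25, 50, 100, 150, 250}` subsets. The signed KS
statistic compares the signature's z among disease-upregulated versus
disease-downregulated genes, negative when upregulated genes sit at
stochastically lower signature values; all three methods are negative for
reversal. The KS method is evaluated on the same subset sizes as the
correlations (the sizes attach to all methods), with an all-genes KS also
averaged in.

`aggregate_ranks()` ranks signatures ascending within each
(method, size) cell — rank 1 is the strongest reversal, so smaller is
better — with average ranks on ties, then averages ranks over sizes within
each method and finally across methods. The aggregation depends only on
within-cell orderings, so it is invariant under strictly monotone
transforms of any cell's scores, and in tie-free instances the overall
ranks average to `(m + 1)/2` across `m` signatures.

Significance comes from permutations: `permutation_p()` shuffles the
disease z-scores across gene ids (once per permutation, for all
signatures jointly, preserving the cross-signature coupling of ranks),
re-runs the whole score→rank→aggregate pipeline, pools the null overall
ranks across all signatures of the phenotype, and assigns
`perm_p = (k + 1)/(K + 1)` with `k` the pooled null ranks at or below the
observed one. Pooling is per phenotype. The default is 100 permutations.

One design point deserves emphasis: **the ranking stage needs the library
as background**. An aggregate rank is meaningful only relative to the set
being ranked; if only a handful of pre-selected strong reversers are
ranked, their observed ranks 1..m are statistically exchangeable with
their own permutation null and no compound can reach a small `perm_p`.
`repurpose_pipeline()` therefore ranks every structurally eligible
signature (compound perturbagen, not excluded, QC-passing) and flags which
of them the screen selected, rather than ranking the screened set alone;
`rank_compounds()` accepts any signature set for callers who want the
narrower behaviour. Compounds with several signatures are reported
per-signature, with `compound_best_rank` giving the compound's best
(minimum) overall rank.

## EHR phenotyping of treatment resistance

TRD is defined from prescription streams as at least two switches between
different antidepressants, where each drug was prescribed for at least six
consecutive weeks and consecutive drugs are separated by at most 14 weeks
(so that treatment was not simply suspended). The implementation uses
exact calendar arithmetic: six weeks = 42 days, fourteen weeks = 98 days.

* `build_episodes()` merges per-person, per-drug prescriptions at most 98
  days apart into episodes; episode duration is last minus first issue
  date. Issue-date records carry no dosage coverage, so this span is a
  conservative proxy for "prescribed for six weeks"; a
  `coverage_days` option adds a nominal per-prescription coverage for
  sensitivity analyses. The same 98-day constant bounds gaps within a drug
  and between drugs.
* `classify_trd()` scans qualifying (≥ 42-day) episodes in start order
  and counts a switch when the drug changes and the gap is at most 98
  days. Switches need not be between consecutive distinct drugs — A→B→A
  counts two switches, since each transition is a switch. Non-qualifying
  episodes are invisible to switch counting but their elapsed time still
  separates qualifying episodes. Overlapping qualifying episodes of
  different drugs count as an immediate switch and are flagged as
  co-prescription.
* `odds_ratio()` computes the 2×2 association of a depression subtype
  with TRD: `ad/bc` with the Haldane–Anscombe 0.5 correction when a cell
  is zero, a Wald 95% CI on the log scale, and the two-sided Wald p.
  Subtype association is deliberately a plain 2×2 odds ratio, not a
  covariate-adjusted regression: ancestry, centre and batch adjustments
  belong to the GWAS stage, which this package does not reimplement.
  `bonferroni_select()` separates risk (OR > 1) from protective
  associations at `p < 0.05/m`.

## What the generators emulate — and what they do not

* `gen_disease_signature()` draws null genes from `N(0, 1)` and a minority
  of causal genes from `N(0, sqrt(1 + effect_sd²))`, mimicking the mixture
  of null and large-effect genes in TWAS output. It does not model LD,
  the MHC region, or correlation between neighbouring genes' features.
* `gen_library()` builds reversers as
  `-rho * standardized disease z + noise`, giving an analytically
  predictable Pearson correlation `-rho/sqrt(rho² + noise_sd²)`
  (≈ −0.85 at the default `rho = 0.8`, `noise_sd = 0.5`); mixing the whole
  standardized vector, rather than resampling gene subsets, is what makes
  recovery tests calibratable. Replicates differ by independent noise
  across cell lines. QC failures are random but never silence every
  replicate of a reverser, and at least one reverser replicate is flagged
  when failures are requested, so the substitution path is exercised
  deterministically. Real level-5 libraries have heavy-tailed z, gene-gene
  correlation, dose-response structure and batch effects, none of which is
  simulated — passing recovery tests shows the machinery is correct, not
  that real libraries behave this way.
* `gen_twas_table()` plants one maximal-CV carrier per gene whose z equals
  the disease z, so collapsing recovers the signature exactly — a
  conservation check, not a model of tissue sharing.
* `gen_prescriptions()` constructs cohorts where intended labels follow
  from the rule's definition: TRD subjects get three qualifying episodes
  of distinct drugs with admissible gaps; near-miss subjects violate
  exactly one criterion (a 41-day episode, a 99-day gap, or a single
  switch). Dates, drug choices and gaps are randomized within those
  constraints.
* `gen_fourfold()` draws a 2×2 cohort from the logistic model implied by a
  baseline risk and a true odds ratio.

All generators are pure functions of their parameters and seed and restore
the caller's RNG state.

## Numerical choices and degenerate inputs

* Running-sum extremum ties: positive extremum reported (both in the
  weighted KS and the signed two-sample KS).
* Ranking ties: average ranks, preserving rank-mass conservation.
* `|z|` ties in query construction and z-ties in signature ordering break
  by gene id.
* Both empirical estimators use `(k + 1)/(n + 1)`, so no p-value is 0.
* A query covering the whole universe, an empty overlap, an all-zero
  weight vector, a degenerate 2×2 table (empty row/column) and an
  incomplete scoring design all raise informative errors rather than
  returning values.
* All randomness derives from explicit integer seeds through
  `derive_seed()`, a deterministic mixer keeping every derived seed a
  valid 32-bit integer.

## Problem sizes used in the test-suite

The recovery setting used by the tests and the acceptance script is 2000
genes (100 causal, effect SD 3), 200 compounds in duplicate with five
planted reversers (`rho = 0.8`, `noise_sd = 0.5`), 1000 null queries per
screen and 100 permutations per ranking — large enough for clean
separation of planted structure, small enough to iterate on a laptop.
Null calibration runs 50-compound pure-noise libraries over many seeds;
EHR checks use 500-subject cohorts. These sizes are the package's chosen
reference conditions for its own validation.

## Known limitations

* The screen and ranking assume a shared, moderate-sized gene universe;
  the real LINCS universe (~12k genes, landmark + inferred) and its GCTX
  binary format are out of scope, as is the clue.io "tau" percentile
  statistic.
* Episode duration from issue dates underestimates exposure when
  prescriptions carry long coverage; the `coverage_days` option is a blunt
  correction.
* The 2×2 subtype association ignores confounding by design (see above).
* Permutation p-values are pooled across signatures and therefore
  slightly conservative for signatures whose null rank distribution is
  narrower than the pool's.
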