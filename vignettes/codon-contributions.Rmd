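---
title: "Decomposing rapid protein-abundance change into sequence-feature contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing rapid protein-abundance change into sequence-feature contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codoncontrib)
```

## The question and the model

Under short-term heat stress (an hour at elevated temperature) the protein
complement of a tissue shifts faster than transcription alone can drive it.
The working hypothesis this package operationalizes is that *sequence
features of the transcript* — above all the usage of specific codons such
as lysine's AAG, whose tRNA remains efficiently translated under heat —
predispose some mRNAs to rapid translation, so that protein fold changes
are partly predictable from static sequence properties plus the
transcriptional change.

The response modelled is the per-gene protein fold change between a
treatment and a control condition. The predictors are a registry of
103 features in six categories: 64 in-frame codon frequencies, 20
amino-acid frequencies, A/C/G/T base frequencies and GC fraction and length
for each of CDS, 5′UTR and 3′UTR, and the transcript fold change. (The
registry is an ordinary data frame; analyses can subset or extend it, and
every output carries the category map so contributions aggregate
consistently.)

The core estimator is a multivariate adaptive regression splines (MARS)
fit:

* **Forward pass** — starting from the intercept, repeatedly add the
  reflected hinge pair `max(0, x_j − t)` / `max(0, t − x_j)` (knot `t` an
  observed value of feature `j`) that most reduces the residual sum of
  squares, until the basis reaches `max_terms` (default 21) or the relative
  improvement drops below `thresh` (default 0.001). Because the pair plus
  the intercept spans the same space as `{x_j, max(0, x_j − t)}`, each
  candidate reduces to a two-predictor least-squares problem in the current
  residual space, solved in closed form for all knots of a feature at once.
* **Backward pass** — drop, at each size, the term whose removal least
  increases the RSS; keep the size minimizing the generalized
  cross-validation score `GCV(k) = (RSS/n) / (1 − C(k)/n)²` with effective
  parameters `C(k) = k + penalty·(k−1)/2` (penalty 2 for additive models,
  3 when interactions are enabled).
* **Importance and contributions** — walking the pruning path from the
  single-term model up to the selected size, the RSS decrease between
  consecutive subsets is attributed to the feature(s) of the term that
  enters; a feature's contribution is its share of these decreases times
  the selected model's training R², in percent. Contributions therefore
  sum exactly to the explained percentage, and `100 − R²·100` is reported
  as unexplained. This attribution rule is a package design decision: pie
  percentages need an explicit decomposition, and importance-share × R² is
  the simplest rule that conserves mass; a GCV-based importance column is
  also reported for comparison.

Two independent estimators verify the MARS selection: ordinary least
squares on the selected features (signs and t-based p-values) and an
elastic net (mixing 0.5, 10-fold cross-validated λ, seeded folds). The
`verification_report()` flags any feature whose direction the three methods
disagree on.

## Scales and screens

The correlation screen (Pearson r with two-tailed t-based p, stars at 0.05
and 0.01) runs on **raw fold changes**, matching how such tables are
conventionally reported. The regression stage instead models **log2 fold
changes** (response and transcript-fold-change feature): fold changes are
ratio-scaled, so the log transform treats a doubling and a halving
symmetrically and keeps the planted linear structure of the generator
exactly linear. Correlation signs are invariant to this monotone
difference, so screen and regression remain directly comparable.

## Upstream rules

Protein reporter tables follow the TMT reliability convention: a gene needs
at least 3 observed values among 4 replicates *in every condition of the
contrast* (the rule is stated ambiguously in common usage between
per-condition and overall; per-condition is the stricter reading and is
what `filter_and_impute_protein()` applies). A single missing replicate is
imputed with the mean of the other three; afterwards each sample is scaled
so its median matches the grand median — "normalized" is otherwise
unspecified for reporter intensities, and median scaling is the standard
robust choice. Imputation never alters an observed value.

Transcript differential calls use a Welch t-test on `log2(FPKM + 1)` with
Benjamini–Hochberg correction; DET = fold change > 2 (or < 1/2) and
q < 0.05. This replaces a negative-binomial count model deliberately: the
package's scope starts from abundance matrices, not reads, and the
contract is the thresholding logic. Protein DEP calls are a two-sided
t-test at p < 0.01 without FDR, on log2 intensities (a `t_raw` option
exists). A zero control mean is handled by adding half the smallest
nonzero abundance of the table to both means and flagging the gene; genes
at zero everywhere are excluded.

Group comparisons (AAG frequency across whole-genome, identified, up- and
down-regulated proteins; cutoffs 1.2 / 0.83, significance q < 0.05 by
default) use the tie-corrected Kruskal–Wallis statistic with a chi-square
reference on k−1 degrees of freedom; when any group has fewer than 5
members a seeded permutation p-value is added, since the chi-square
approximation is then unreliable. Only the omnibus test is run by default.
Enrichment is flat upper-tail hypergeometric testing (`phyper`) with BH
FDR over terms having at least one study-set hit, filtered at count ≥ 7
and q < 0.05; the universe defaults to the genes present in both the
annotation and the feature matrix.

## Annotation handling

Coordinates are GFF3 1-based inclusive throughout. UTRs are taken from
explicit `five_prime_UTR`/`three_prime_UTR` features when present and
otherwise inferred as exon-minus-CDS in transcript orientation. When a
gene has several isoforms the longest-CDS transcript represents the gene
(a guess — annotation sets rarely state the collapsing rule — exposed via
`collapse = "none"`). Transcripts whose CDS length is not a multiple of 3
are kept but flagged and never reach codon-level features. Codons
containing N are excluded from both numerator and denominator of codon and
amino-acid frequencies; stop codons count in the codon block but not in
the amino-acid denominator. Genes lacking a UTR get that region's
composition features imputed with the genome-wide column mean (length
stays 0) so the design matrix is complete without pushing those genes to
compositional extremes; the assembly report records every imputed value.

## The synthetic study conditions

`simulation_spec()` defaults define the reference conditions used by the
tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| genes | 3000 | regression-scale proteome subset |
| interior CDS length | Normal(300, 80) codons, min 60 | typical plant CDS scale |
| codon weights | uniform over 61 sense codons | neutral baseline |
| AAG-rich subset | 10% of genes, +0.08 AAG probability | creates a distinct AAG-rich class above the 0.08 threshold |
| UTR lengths | 5′ N(150, 70), 3′ N(250, 110); 5% absent | plant-like UTRs, exercises the imputation path |
| planted effects | 0.5 on log2 transcript FC, 0.4 on AAG frequency (standardized) | transcription-plus-codon structure |
| planted R² | 0.6 | noise solved so the linear predictor explains 60% |
| replicates | 3 transcript, 4 protein | RNA-seq triplicates, TMT quadruplicates |
| replicate noise | lognormal sdlog 0.2 / 0.15 | ~15–20% CV |
| protein missingness | 5% MCAR, ≤1 per gene×condition | sporadic TMT dropouts |

Effects are planted on standardized features so "standardized beta" is
comparable across features with different scales. Each stage of the
generator draws from a named substream seeded from the master seed
(sequences, transcript fold changes, noise, baselines, replicates,
missingness), so changing one component never perturbs another, and
identical (spec, seed) pairs are bitwise reproducible down to the written
files.

What the generator does **not** emulate: count-level sampling noise
(negative-binomial mean–variance coupling), isoform complexity,
non-uniform real codon usage, correlated missingness, batch structure, or
any dependence between UTR composition and regulation. Passing recovery
tests therefore demonstrate the pipeline's correctness and power under
clean planted structure, not performance guarantees on real data.

## Numerical choices

* Knot candidates are all distinct observed values of a feature up to
  `max_knots` (default 50), thinned to evenly spaced order statistics
  beyond that — knots stay observed data values either way.
* Forward-pass ties break toward the lowest feature index, then the
  smallest knot; backward-pass ties keep the smaller model.
* A hinge whose twin is linearly dependent on the current basis (e.g. a
  knot at the feature minimum) is dropped by a QR rank check and logged.
* Candidate sizes where `1 − C/n ≤ 0` are inadmissible for GCV and skipped
  with a warning.
* Constant features report r = 0, p = 1 with a flag rather than NA, and
  are excluded from the regression design.
* Backward elimination visits nested subsets only; on noisy small-n data
  the GCV-best subset it finds can differ from an exhaustive subset
  search. The small-instance optimality tests use clean signals, where
  the two provably coincide.
* The hypergeometric tail delegates to `phyper`, which is evaluated
  stably; tests verify agreement with direct pmf enumeration to 1e-12 on
  every instance with a universe up to 50.

## Problem sizes used by the test suite

Unit tests run on toy instances (3–300 genes). The recovery acceptance
check runs the full pipeline at the reference conditions (3000 genes)
across 20 seeds; the null-calibration checks use 1000-gene simulations and
a 100,000-permutation Kruskal–Wallis oracle; determinism is verified
end-to-end at 150 genes. These sizes were chosen as the smallest at which
the statistical claims under test are sharp.

## Known limitations

* The registry's 103 features are a reconstruction; published analyses of
  this kind often quote slightly different factor counts without
  enumerating them, and the registry is configurable for that reason.
* MARS interactions (degree > 1) are implemented but default off: the
  contribution decomposition is only cleanly additive for degree 1.
* The contribution attribution (importance share × R²) is one defensible
  rule among several; GCV-based importance is reported alongside so users
  can compare.
* No GO DAG propagation or term redundancy reduction — enrichment is flat
  by design.
* No count-model differential testing; users with read-level data should
  quantify and test upstream and feed abundance tables in.
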