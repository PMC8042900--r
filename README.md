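# codoncontrib

Short-term heat stress changes a cell's protein complement within an hour —
too fast for transcription alone to explain. `codoncontrib` implements a
reusable pipeline for asking *which sequence features drive those rapid
protein-abundance changes*: it quantifies how far codon usage (in
particular the lysine codon AAG), amino-acid composition, base/GC content,
region lengths and the transcriptional change itself account for protein
fold changes between a control and a heat-stressed condition. It is aimed
at analysts holding a genome + GFF3 annotation, replicate transcript
abundances (FPKM-like), and replicate protein reporter intensities
(TMT-like) for the same conditions.

## What it computes

For each gene *g* with fold change FC = treatment / control:

* **Sequence features** — in-frame codon frequencies over the CDS
  (`f_c = n_c / Σ n`, codons containing N excluded), amino-acid frequencies
  (stop codons excluded from the denominator), per-region A/C/G/T and GC
  composition and lengths for CDS, 5′UTR and 3′UTR, extracted
  strand-correctly from FASTA + GFF3.
* **Fold-change tables** — protein tables are filtered by the ≥3-of-4
  replicate reliability rule, single missing values imputed with the mean
  of the other three, samples median-normalized; DETs are called at
  FC > 2 (or < 1/2) with Benjamini–Hochberg q < 0.05, DEPs at two-sided
  t-test p < 0.01.
* **Correlation screen** — Pearson *r* of each feature against the protein
  fold change, two-tailed p with 0.05/0.01 stars.
* **Contribution decomposition** — a multivariate adaptive regression
  splines (MARS) fit: greedy forward selection of reflected hinge pairs
  max(0, x−t) / max(0, t−x), backward pruning by generalized
  cross-validation, GCV(k) = (RSS/n)/(1 − C(k)/n)² with
  C(k) = k + penalty·(k−1)/2. Per-feature importance from the pruning
  trace converts to percentage contributions that sum, with an
  "unexplained" remainder, to 100%. Ordinary least squares and
  cross-validated elastic net verify the signs of every selected effect.
* **Group statistics** — tie-corrected Kruskal–Wallis comparison of a
  codon's frequency across whole-genome / identified / up- / down-regulated
  protein groups (cutoffs 1.2 and 0.83 at q < 0.05).
* **Enrichment** — upper-tail hypergeometric tests of annotation terms with
  BH FDR and the count ≥ 7, q < 0.05 filter, including the AAG-rich gene
  set (AAG frequency > 0.08).

A synthetic-data generator (`simulation_spec()` / `simulate_dataset()`)
produces genome + annotation + expression tables with *planted* effects and
ground truth, so the whole pipeline is testable without any external data.

## Worked example

Simulated study conditions: 3000 genes, planted standardized effects of 0.5
(log2 transcript fold change) and 0.4 (codon AAG frequency) on the protein
log2 fold change, noise set for a planted R² of 0.6:

```r
library(codoncontrib)
spec <- simulation_spec(seed = 42)
sim  <- simulate_dataset(spec)
prot <- filter_and_impute_protein(sim$proteins)
fc   <- build_fc_table(sim$transcripts, prot, "20C", "30C")
fm   <- build_feature_matrix(sim$catalog, setNames(fc$transcript_fc, fc$gene_id))
res  <- associate(fm, fc, seed = 42)
print(res$contribution)
#> contribution_report: 58.2% explained, 41.8% unexplained
#>   transcript_fc      transcript    32.78%
#>   codon:AAG          codon         24.26%
#>   aa:C               amino_acid     0.20%
#>   ...
recovery_report(sim$truth, res$contribution, res$correlation, "30C")$checks
#>               check pass                          detail
#>    top_contributors TRUE         transcript_fc,codon:AAG
#>   correlation_signs TRUE                             1,1
#>  explained_variance TRUE estimated 58.2 vs realized 57.9
```

The model explains 58.2% of the protein variation (the generator realized
57.9% — recovered within a fraction of a percentage point), ranks the two
planted drivers first, and the correlation screen shows both with positive,
highly significant coefficients (e.g. `codon:AAG` r = 0.56\*\*). Note how
lysine (`aa:K`, r = 0.54\*\*) correlates almost as strongly as AAG in the
screen, yet the regression attributes the effect to the codon, not the
amino acid — the discrimination the decomposition exists to make.

The same stages run from a config file (`run_pipeline("run.yaml")`) or the
thin CLI in `inst/cli/codoncontrib`
(`simulate | features | foldchange | associate | groups | enrich | run`).

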