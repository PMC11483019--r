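# bilestate

Malignant cell states and gene-program covariation in biliary tract cancer
(BTC) single-cell RNA-seq.

Biliary tract cancers are molecularly heterogeneous and poorly characterized
at single-cell resolution. Given tumor-biopsy scRNA-seq cohorts sampled at
baseline (`pre`) and on treatment (`on`), this package implements the full
analysis chain needed to ask how malignant cell states and their
microenvironment shift under therapy:

* **QC → clustering → annotation** — standard droplet filters (≥50 genes,
  ≥200 counts, ≤25% mitochondrial per cell; genes in ≥3 cells), simulated-
  doublet removal, normalization to 1000 counts with log1p, binned-dispersion
  HVG selection, 40-component PCA, Leiden clustering (resolution 0.5), and
  marker-set cluster annotation.
* **Malignant-cell identification** — windowed copy-number profiles from
  expression relative to non-tumor reference cells, per-cluster discrete
  region states s ∈ {−1, −0.5, 0, +0.5, +1}, and the cluster-level
  **squared-deviation malignancy score**

  score(cluster) = Σ_regions s²,

  applied to every cell of the cluster; cells in any cluster with a
  non-neutral state profile are called malignant.
* **Consensus NMF** — repeated multiplicative-update factorizations
  ‖X − WH‖²_F over a rank grid (classically k = 5…101 step 3), cosine-density
  outlier filtering, k-means consensus spectra, NNLS usage refit, and a
  stability (silhouette) / error rank-selection table.
* **Tumor states** — malignant cells are classified as classical, basal,
  mesenchymal, neural-like, or endothelial-like by argmax program activity;
  cells with both mesenchymal and neural-like activity above a threshold are
  **intermediate**.
* **Covariation** — per sample and program, the 25/50/75/90/95th percentile
  of program activity within the program's cell type; program×program Pearson
  correlation with clustermap ordering; permutation p-values from shuffling
  cell–sample assignments (p = #{null r > observed r} / 1000).
* **Composition statistics** — per-sample cell-type/state proportions and
  two-sided Student t-tests (all-samples or paired) with Bonferroni
  correction, including the fraction-of-positive-tumor-cells comparison for a
  single gene (e.g. DKK1).

Patient data cannot ship with the package, so it includes a ground-truthed
**synthetic cohort generator** (`generate_cohort()`) that emulates the study's
structure — patient/timepoint design, malignant + five non-malignant cell
types, planted low-rank expression programs, chromosome-scale CNV fold
changes, doublets, mitochondrial variation — and every pipeline stage is
tested as a recovery problem against that truth.

## Worked example

The `analysis/` scripts run the whole chain on a synthetic cohort of 5
patients × {pre, on} × 300 cells, 2000 genes, 5 planted tumor programs, three
CNV segments, and 5% doublets:

```sh
Rscript analysis/01_simulate.R      # write the cohort (10x triplet layout)
Rscript analysis/02_qc_cluster.R    # QC, doublets, clustering, annotation
Rscript analysis/03_cnv_malignancy.R
Rscript analysis/04_cnmf_programs.R
Rscript analysis/05_tumor_states.R
Rscript analysis/06_covariation.R
Rscript analysis/07_abundance.R
```

Representative output (numbers printed by the scripts on this cohort):

```
== 02_qc_cluster ==
doublet filter: 436/2963 cells flagged
326 highly variable genes
10 clusters; major-type annotation agrees with truth for 99.4% of cells
== 03_cnv_malignancy ==
malignant calls: 750/2527 cells; AUROC 0.891; accuracy 0.917
== 04_cnmf_programs ==
k selection (stability / error):
  k=3  stability 0.751  error 844.5
  k=5  stability 0.972  error 829.2
  k=7  stability 0.559  error 827.8
chosen k: 5
== 05_tumor_states ==
state composition of malignant cells:
  basal 0.097   classical 0.241   endothelial-like 0.213
  intermediate 0.007   mesenchymal 0.199   neural-like 0.243
== 06_covariation ==
0 of 10 program pairs co-vary at p < 0.05 (75th percentile, 1000 shuffles)
== 07_abundance ==
pre vs on (paired-only):
  T      pre 0.109  on 0.138  t -3.30  p 0.030 (adj 0.180)
  tumor  pre 0.382  on 0.359  t +2.39  p 0.075 (adj 0.451)
fraction of G00463-positive tumor cells, pre 0.985 vs on 1.000: p = 0.162
```

Reading the numbers: annotation accuracy is the fraction of cells whose
marker-based cluster label matches the simulated type; the malignancy AUROC
measures how well the squared-deviation score ranks true malignant cells;
the k-selection table shows the stability/error trade-off that identifies the
planted number of programs; state composition is the share of malignant cells
per assigned state; the composition comparisons report t statistics and
Bonferroni-adjusted p-values for pre- versus on-treatment proportion shifts.
All tables land under `results/`.

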