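# mucosaAtlas

Region-resolved analysis of label-free stomach mucosa proteomes: from
protein × sample abundance matrices to a detection-frequency atlas,
per-protein reference intervals, outlier calling in tumor samples, and
outlier-driven tumor subtyping.

## The scientific problem

The gastric mucosa is sampled at seven anatomical regions — cardia (Ca),
fundus (Fu), lesser curvature (LC), greater curvature (GC), angular
incisure (AI), antrum (An) and pylorus (Py).  Given label-free proteomic
profiles of normal biopsies from these regions plus paired tumor (T) and
tumor-nearby-tissue (TNT) samples from cancer patients, the analysis asks:

* Which proteins form the mucosa **core proteome** (seen in all seven
  regions), and which are **region-specific** (detected in ≥ 75% of samples
  of 1–2 regions and ≤ 25% elsewhere)?
* Do the regions organize into the **proximal** {Ca, Fu, LC, GC} and
  **distal** {AI, An, Py} sections, and which proteins mark the sections
  (fourfold difference, Student's *t* p < 0.05)?
* What is the normal **reference interval** (RI) of each protein, and how
  many proteins exceed it in a query sample?  The RI upper limit is

  ```
  upper = P90 + 3 × (P90 − P10)
  ```

  with P10/P90 the 10th/90th percentiles of the protein's abundance across
  the normal cohort (zeros = not detected included).  A protein whose
  abundance in a query sample is *strictly above* `upper` is an **outlier**.
* Do outlier proteins define tumor **subtypes**?  Proteins detected in
  ≥ 20% of patients and called outliers in ≥ 75% of the detecting patients
  feed resampling consensus clustering (90% subsampling, 1 − Pearson
  distance, average linkage) over k = 2..10.

Abundances are iBAQ values normalized per sample to fraction-of-total
(FOT = iBAQ / Σ iBAQ) and scaled by 1e5 (iFOT).  Identifications are kept
only with ≥ 1 unique and ≥ 2 strict peptides and detection in ≥ 2 samples
of one region.

The package is aimed at proteomics analysts who want these steps as
tested, composable functions on Bioconductor containers (the central
`ProteomeMatrix` class extends `SummarizedExperiment`), together with a
synthetic cohort generator that plants all of the structure above with
known ground truth.

## Worked example

Simulate a reference cohort at the default study conditions (82 normal
samples over 7 regions, 2500 proteins spanning ~7 decades), preprocess,
build reference intervals, call outliers in a matched tumor cohort, and
subtype the patients:

```r
library(mucosaAtlas)

cfg <- cohortConfig(seed = 7)
ref <- simulateReferenceCohort(cfg)
pp  <- preprocessCohort(ref$matrix, ref$evidence, ref$metadata)
pp$ifot
#> ProteomeMatrix: 1653 proteins x 82 samples [scale: ifot]
#>   detected entries: 77.5%
#>   samples per region:  AI=15 An=10 Ca=12 Fu=12 GC=12 LC=11 Py=10

ri <- buildReferenceIntervals(pp$ifot, ref$metadata)
ri
#> ReferenceIntervalSet: 1653 proteins (1653 with a defined RI)
#>   built from 82 reference samples; min_ref = 10; zeros included
head(as.data.frame(riTable(ri)), 3)
#>   protein_id n_ref      p10          p90        upper defined
#> 1     P00001    82 48.51303 1.099519e+03 4.252536e+03    TRUE
#> 2     P00002    82  0.00000 2.117016e-02 8.468065e-02    TRUE
#> 3     P00006    82  0.00000 2.542666e-02 1.017066e-01    TRUE

tum <- simulateTumorCohort(cfg, ref$truth)
qt  <- computeIFOT(computeFOT(tum$tumor))
qt  <- qt[intersect(rownames(qt), pp$kept_proteins), ]
calls <- callOutliers(qt, ri)
calls
#> OutlierCalls: 58 samples x 1653 proteins
#>   per-sample outlier count: median 50 (range 42-58)

feats <- selectOutlierFeatures(calls, t(abundanceValues(qt) > 0))
res <- consensusCluster(log2(abundanceValues(qt)[feats, ] + 0.01),
                        k_range = 2:6, reps = 100, seed = 1)
res
#> SubtypeResult: 58 items, k evaluated in 2..6, chosen k = 3
#>   cluster sizes at chosen k:  1=19 2=19 3=20
```

Reading the output: 1653 of 2500 simulated proteins survive the
high-confidence filters; every protein gets a defined RI from the 82
reference samples.  For P00001 (an abundant protein) the normal range is
wide on the iFOT scale and the outlier threshold is `upper ≈ 4253`; for the
rarely detected P00002 both percentiles are near zero, so almost any solid
detection in a tumor is an outlier — exactly the behavior that makes the
zero-inclusive RI sensitive to ectopically expressed proteins.  Tumor
samples carry a median of 50 outlier proteins (their planted 40-protein
subtype signature plus background), and consensus clustering of the 69
selected outlier features recovers three subtypes, matching the planted
ground truth exactly (adjusted Rand index 1.0).

The whole chain, including region atlas statistics and TSV artifacts, is
also available as one call:

```r
runPipeline(list(), outdir = "mucosa_run", seed = 1)
# or from a shell:
#   Rscript inst/scripts/run_pipeline.R --config cfg.yaml --outdir out --seed 1
```

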