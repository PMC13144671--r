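# mced — multimodal cfDNA analysis for multi-cancer early detection

`mced` implements a multi-cancer early detection (MCED) pipeline over plasma
cell-free DNA (cfDNA), for computational biologists who want a fully testable,
end-to-end reference implementation of the methylation + copy-number +
fragmentomics + ensemble architecture used by modern blood-based screening
assays. Because real MCED cohorts are not publicly deposited, the package
ships a seeded synthetic cohort simulator with the statistical structure the
assay assumes, so every stage — marker discovery through ensemble
calibration — runs and is verified without external data.

## The model

For a plasma sample, tumor-derived fragments are a low-abundance admixture at
tumor fraction TF, so each data modality is modeled and scored as follows.

**Methylation (AMF).** At CpG site *j* with cytosine count *C<sub>j</sub>* and
thymine count *T<sub>j</sub>*, the methylation level is
β<sub>j</sub> = C<sub>j</sub>/(C<sub>j</sub>+T<sub>j</sub>). Sites are
filtered (healthy coverage ≥ 3×, ENCODE-style blacklist, autosomes only),
classified from healthy samples as unmethylated (bottom decile of mean β and
β < 0.5), methylated (top decile and β > 0.5) or neutral, and contiguous
same-status runs become regions R<sub>i</sub>, quantified per sample by the
average methylation fraction

&nbsp;&nbsp;&nbsp;&nbsp;AMF<sub>i</sub> = (1/|R<sub>i</sub>|) Σ<sub>j∈R<sub>i</sub></sub> C<sub>j</sub>/(C<sub>j</sub>+T<sub>j</sub>).

Differentially methylated regions come from Welch t-tests (BH-FDR < 0.05)
across tumor-vs-adjacent tissue, cancer-vs-other-cancers and
cfDNA-cancer-vs-healthy comparisons; final markers must be
direction-concordant between tissue and cfDNA where matched tissue exists.

**Copy number.** Bin counts are depth-normalized, divided by a healthy-median
reference and log2-transformed; an alteration is a bin strictly beyond
mean ± 2σ of the healthy reference. Bins altered in > α% of healthy controls
are excluded (guarding against clonal hematopoiesis); markers are
(bin, direction) pairs with healthy frequency < α% and > β% prevalence in at
least one cancer type (defaults α = 5, β = 20). A sample's CNV score is the
fraction of markers it detects.

**Fragmentomics.** FSR is the per-window ratio of short (80 < L < 150 bp) to
long (150 < L < 220 bp) fragments; FSD is the genome-wide proportion vector
over 5-bp bins spanning 80–220 bp (28 bins). Both are standardized against
training samples.

**Classifiers and the CSE ensemble.** Each feature trains a nine-class model
(healthy + 8 cancer types) chosen by fourfold cross-validated macro
one-vs-rest AUC; its cancer-signal score is 1 − P(healthy). The cancer
signature ensemble (CSE) logit-transforms the per-feature scores, adds age
and sex, and fits logistic regression; the decision threshold is calibrated
to 95% specificity on held-out healthy controls aged ≥ 50. Tissue of origin
(TOO) is the weighted average of the features' healthy-omitted conditional
probabilities; calls with top1 − top2 < 0.07 are flagged "in between".

## Worked example

```r
library(mced)
res <- run_pipeline(params = list(candidates = "glmnet_ridge"), seed = 1)
subset(res$evaluation$metrics, group == "overall")
```

On the default synthetic cohort (50 healthy + 160 cancer plasma samples,
20,000 CpG sites, 500 CNV bins, 100 fragment windows) this prints:

```
      metric   group    value  n     ci_lo     ci_hi
 sensitivity overall 0.953125 64 0.8710035 0.9839310
 specificity overall 1.000000 19 0.8318208 1.0000000
    too_top1 overall 0.812500 64 0.7002564 0.8893536
    too_top2 overall 0.890625 64 0.7910136 0.9459989
```

Sensitivity/specificity describe the binary cancer-signal call on the 40%
test split at the threshold calibrated during training; `too_top1`/`too_top2`
are tissue-of-origin accuracies over test cancer samples (top-2 counts the
truth appearing among the two highest-probability types). `res$evaluation$auc`
(here 0.995) is the ROC AUC of the continuous ensemble score, and
`res$predictions` holds the per-sample record: per-feature scores, ensemble
score and call, TOO top-1/top-2 with probabilities, and the ambiguity flag.
Note the small healthy test arm (n = 19) at this desk scale; the specificity
*calibration* property is tested at n ≥ 300 in `test-acceptance.R`.

Individual stages are plain functions: `simulate_cohort()`,
`filter_sites()`, `classify_cpg_status()`, `build_regions()`,
`compute_amf()`, `select_dmrs()`, `concordance_filter()`,
`normalize_bins()`, `call_alterations()`, `select_cnv_markers()`,
`cnv_csd_score()`, `compute_fsr()`, `compute_fsd()`, `select_best_model()`,
`fit_cse_csd()`, `predict_too()`, `evaluate_predictions()`.

## Command line

```sh
inst/scripts/mced simulate --out cohort/ --seed 7       # write a synthetic cohort
inst/scripts/mced run --out run1/ --seed 7              # full pipeline + artifacts
inst/scripts/mced qc --metrics qc.tsv --out gated.tsv   # QC gate
inst/scripts/mced split --sheet sheet.tsv --out s.tsv   # stratified 6:4 split
```

`run` writes sample sheet, marker tables, predictions, metrics, the serialized
ensemble model, and a manifest (seed, package version, input checksums).

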