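# cytopipe

Tools for classifying lung-cancer subtypes — adenocarcinoma,
neuroendocrine carcinoma and squamous cell carcinoma — from grayscale
single-cell microscopy images. The package is aimed at computational
pathology work where the raw clinical images cannot be shared: every stage
is testable against a seeded synthetic generator that emulates the
intensity structure of such images (near-white background, dark nuclei,
mid-grey fluid, impulse noise, illumination gradients) with a distinct
morphological motif per subtype.

The pipeline has four layers:

1. **Enhancement** — grayscale conversion (BT.601 luma), corner-aligned
   bilinear resizing to 224×224, contrast-limited adaptive histogram
   equalisation (per-tile histograms clipped at
   `clip × tile_pixels / 256`, excess redistributed, mappings
   `v → round(255·cdf(v))` bilinearly interpolated between tile centres),
   and 3×3 median denoising with edge replication.
2. **Feature processing** — dark pre-mapping (`v ≤ 60 → 0`, flagged), Otsu
   thresholding by exhaustive maximisation of the between-class variance
   `ω₀ω₁(μ₀ − μ₁)²` with smallest-maximiser tie-break, foreground
   binarisation (`v ≤ t`), removal of connected components below 30 px
   (holes never filled), three-way composition (dark → 0, background →
   255, else enhanced value), and midtone lightening
   `v → min(255, round(1.3·v))`.
3. **Dataset handling** — per-class sealing, stratified hold-out
   splitting, stratified k-fold assignment, and a seeded affine
   augmentation stack (rotation ±20°, shifts ±30%, shear ±0.2, zoom
   0.8–1.2, horizontal flip, 1/255 model-input rescale).
4. **Learning and evaluation** — a hybrid two-branch classifier (residual
   bottleneck branch + attention-gated encoder–decoder branch, features
   concatenated into a dense-512/batch-norm/dropout/softmax head, Adam,
   categorical cross-entropy), with confusion-matrix metrics
   (`P = Tp/(Tp+Fp)`, `R = Tp/(Tp+Fn)`, `F1 = 2PR/(P+R)`, accuracy =
   trace/total) and fold summaries (sample SD, `se = sd/√n`,
   `mean ± 1.96·se`).

The network engine is implemented directly in R (im2col convolutions on
BLAS with manual reverse-mode gradients); the default desk-scale
configuration trains on a single CPU.

## Worked example

Reproducing the evaluation arithmetic from a hold-out confusion matrix in
which two squamous-cell samples are misclassified as adenocarcinoma:

```r
library(cytopipe)

cm <- as_confusion_matrix(rbind(c(450, 0,   0),
                                c(0,   450, 0),
                                c(2,   0,   448)),
                          c("lung_aca", "lung_n", "lung_scc"))
metrics_from_confusion(cm)
#> Overall accuracy: 0.998519
#> # A tibble: 3 x 9
#>   class       tp    fp    fn    tn support precision recall    f1
#> 1 lung_aca   450     2     0   898     450     0.996  1     0.998
#> 2 lung_n     450     0     0   900     450     1      1     1
#> 3 lung_scc   448     0     2   900     450     1      0.996 0.998

summarize_folds(c(99.47, 99.73, 99.80, 99.60, 99.87))
#> folds: 5  mean 99.69  sd 0.16  se 0.0716  CI[99.55, 99.83]
```

The overall accuracy is 1348/1350 = 99.85%; per-class precision/recall
follow the one-vs-rest decomposition (e.g. adenocarcinoma precision
450/452 ≈ 0.9956). The fold summary uses the sample standard deviation and
a normal 95% interval.

Running the image stages on a synthetic cell image:

```r
img <- generate_image("adenocarcinoma", synth_config(), seed = 42)
enhanced <- median_denoise(apply_clahe(img))
feats <- extract_features(enhanced)
feats$otsu
#> Otsu threshold: 142 (peak between-class variance 5405.375)

quality_metrics(img, feats$premapped, feats$foreground, feats$dark_mask)
#> # A tibble: 2 x 4
#>   metric           before after rel_change
#> 1 snr_proxy          7.57 25.7       2.40
#> 2 midtone_contrast   3.56  5.45      0.530
```

The threshold separates tissue/fluid from the background whites; the SNR
proxy (`|mean(fg) − mean(bg)| / sd(bg)`) more than triples through the
enhancement chain on this image.

An end-to-end run (generate → preprocess → features → lighten → split →
k-fold → train → evaluate) is one call:

```r
report <- run_pipeline(pipeline_config(
  out_dir = "run",
  synth = synth_config(per_class_count = 20, image_size = c(64, 64)),
  split = split_config(per_class_cap = 20, k = 5),
  model = desk_model_config(),
  seed = 1))
```

or, from a shell, `Rscript inst/cli/cytopipe.R run --out-dir run
--per-class 20 --image-size 64 --seed 1`. Stage outputs keep the
conventional names (`_denoised` suffixes, a `final2` directory for
lightened images) and the run report records file counts and checksums.

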