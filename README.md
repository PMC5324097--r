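# nodetex

Texture analysis, noise enhancement and synthesis for classifying small
grayscale regions of interest — built for the setting of mediastinal
lymph nodes on chest CT, where the question is whether a small,
manually-marked rectangle (roughly 16 x 18 to 122 x 112 pixels) contains
malignant or benign tissue, and where no precise segmentation of the node
is available or wanted.

## What it computes

Two complementary texture descriptor families, plus two enhancements for
the small-sample regime:

* **GLCM descriptors.** The gray-level co-occurrence matrix counts
  ordered pixel pairs $(p, q)$ at a fixed offset (default: each pixel
  against its right-hand neighbour); normalized to a joint table
  $p_h(p,q)$ it yields either the classical four descriptors (contrast,
  correlation, energy, homogeneity) or a full 20-item set (entropy,
  sum/difference-marginal statistics, information measures of
  correlation, cluster shade/prominence, the inverse-difference family,
  ...).
* **Experimental semivariogram (SV).** The geostatistical curve
  $\gamma(h) = \sum (f(u)-f(v))^2 / (2M(h))$ over pixel pairs at lag
  $h$, pooled over the horizontal and vertical directions; the first 10
  lags are the feature vector.
* **Noise enhancement (nSV).** White Gaussian noise (zero mean, variance
  0.02 on the unit-normalized scale) is added before computing
  $\gamma(h)$ — a deliberate dithering step that can improve class
  separation.
* **Synthesis enhancement (sSV).** Small ROIs are enlarged by
  tolerance-based patch texture synthesis (10 x 10 patches, 6-pixel
  overlap, candidate tolerance 0.1, Gaussian-weighted SSD scoring), so
  the semivariogram can be computed at lags the original ROI cannot
  support: 20 lags on 200 x 200 (`sSV1`), 30 lags on 250 x 250 (`sSV2`).

The evaluation layer scores feature tables with a binomial GLM (logit
link), builds ROC curves with trapezoidal AUC, selects the operating
point where an iso-cost line of slope
$m = \frac{\phi(P|N)-\phi(N|N)}{\phi(N|P)-\phi(P|P)}\cdot\frac{N}{P}$
first touches the curve, forms pointwise bootstrap confidence bands by
vertical averaging, and runs stratified tenfold cross-validation with
linear SVM, Gaussian naive Bayes, and ridge-stabilized LDA.

A Gaussian-random-field cohort simulator (exponential covariance, known
analytic semivariogram $s(1-e^{-h/r})$) provides ground truth for every
stage; see the methods vignette (`vignettes/nodetex-methods.Rmd`).

## Worked example

```r
library(nodetex)

# two-class synthetic cohort: benign fields are smooth (range 6 px),
# malignant rough (range 1.5 px), node-sized rectangles
co  <- generate_cohort(20, seed = 42)

# semivariogram features of one benign sample (unit-normalized ROI)
round(extract_combo(co$samples[[1]]$image, "SV10",
                    image_id = "benign_001", seed = 42), 4)
#>  sv_h1  sv_h2  sv_h3  sv_h4  sv_h5  sv_h6  sv_h7  sv_h8  sv_h9 sv_h10
#> 0.0047 0.0083 0.0110 0.0129 0.0145 0.0158 0.0170 0.0180 0.0188 0.0194

# combined 20-descriptor GLCM + noise-enhanced semivariogram features
tab    <- build_feature_table(co, "GLCM20+nSV10", seed = 42, imc = "one")
scores <- fit_logistic_scores(tab)   # warns: classes are separable here
roc    <- roc_curve(scores, tab$label)
roc
#> <roc_curve: 41 vertices, AUC = 1.0000 (P = 20, N = 20)>

optimal_operating_point(roc)         # symmetric costs, balanced classes
#> <operating_point: threshold 0.9958, SEN 1.000, SPE 1.000, m = 1>

tenfold_cv(tab, "svm", seed = 42)
#> <cv_result svm: mean accuracy 100.0% over 10 folds>
```

The rising `sv_h*` values trace the spatial decorrelation of the field;
the smooth benign class sits well below the rough malignant class at
small lags, which is why even the 10-lag semivariogram alone separates
this cohort.  An AUC of 1.0 reflects the deliberately separable default
design, not expected clinical performance.

`inst/cli/nodetex.R` is a thin command-line front end
(`simulate`, `synthesize`, `extract`, `run-all`) over the same functions.

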