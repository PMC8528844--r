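# ki67window

Automated Ki67 scoring and paired-response statistics for endocrine-therapy
window trials in ER+ breast cancer.

In a presurgical window trial, patients receive a few weeks of endocrine
therapy (tamoxifen, an aromatase inhibitor, or fulvestrant) between biopsy
and surgery, and response is read out as the change in the **Ki67
proliferation index** — the percentage of tumor nuclei staining positive for
Ki67 by immunohistochemistry (IHC), scored in a 1 mm² hotspot. This package
is for computational pathologists and trial statisticians who need that
chain as tested, reusable code:

* an **automated IHC scorer**: 80 × 80 px sliding window at 10 px stride →
  per-window nucleus probability → probability map on the 10 px grid →
  Gaussian-filtered nucleus map → peak extraction and contouring →
  per-nucleus DAB positivity by colour deconvolution and brightness →
  ROI-level index `100 · n⁺ / n` and a ≥1000-cell hotspot search;
* **method-agreement statistics**: Spearman rank correlation (exact
  permutation null at small n) and the absolute-agreement intraclass
  correlation ICC(2,1) with F-based confidence interval;
* **window-trial statistics** on paired Ki67: log10(Ki67+1) transforms, the
  (post+1)/(pre+1) ratio convention, one-sided Wilcoxon signed-rank per
  arm, Mann–Whitney between pre- and postmenopausal tamoxifen, Kruskal–
  Wallis across postmenopausal arms, responder classification (strict
  decrease; equality its own category), per-arm percent-decrease effect
  sizes, and the inverse association between residual estradiol (above the
  44 pmol/L detection limit) and Ki67 decrease;
* **expression readouts**: knn-10 imputation, median probe→gene collapse,
  per-sample proliferation-signature scores, and an empirical-Bayes
  **moderated paired t-test** (variance shrinkage via closed-form moment
  matching; reduces exactly to the plain paired t when the prior is off);
* a **synthetic-data generator** (H-DAB slides with ground-truth nuclei,
  trial tables, expression matrices) so the entire chain is testable
  end to end with no external data.

## Worked example

```r
library(ki67window)

# train the patch classifier on four annotated synthetic slides
training <- lapply(1:4, function(i)
  generate_slide(slide_spec(positive_fraction = c(0.1, 0.3, 0.5, 0.2)[i],
                            seed = 100 + i)))
patches <- sample_training_patches(training, per_slide = 400,
                                   split_fraction = 0.8, seed = 11)
clf <- train_patch_classifier(patches$train, patches$val, seed = 2)
print(clf)
#> patch_classifier (backend: classical, n_train = 1280, n_val = 320)
#>   held-out accuracy: 0.9625

# score a 100 x 100 um ROI on a fresh slide with 30% true positivity
slide <- generate_slide(slide_spec(positive_fraction = 0.30, seed = 61))
score_roi(slide, roi = c(60, 60, 260, 260), clf)
#> Ki67 score: 34.1% (15 of 44 nuclei positive, 0.0100 mm^2 ROI)
ground_truth_index(slide$ground_truth, c(60, 60, 260, 260))
#> [1] 35.4

# simulate a window trial at the study sample sizes and analyse it
trial <- generate_trial_table(trial_sim_spec(seed = 31))
run_trial_analysis(trial)
#> Window-trial paired-response report
#> -----------------------------------
#>   tamoxifen_pre   n=29  Wilcoxon signed-rank (1-sided, post<pre) p=8.424e-06
#>   tamoxifen_post  n=14  Wilcoxon signed-rank (1-sided, post<pre) p=0.0005485
#>   anastrozole     n=15  Wilcoxon signed-rank (1-sided, post<pre) p=0.0003633
#>   fulvestrant     n=13  Wilcoxon signed-rank (1-sided, post<pre) p=0.0008308
#>   pre vs post tamoxifen ratios: MWU (1-sided) p=7.083e-06
#>   responders only:              MWU (1-sided) p=1.632e-05
#>   postmenopausal arms: Kruskal-Wallis (2-sided) p=0.4834
#>   effect sizes (% decrease, all patients):
#>     tamoxifen_pre    38.4% (SEM 4.9), responders only  44.8%
#>     tamoxifen_post   69.5% (SEM 2.8), responders only  69.5%
#>     anastrozole      66.1% (SEM 3.6), responders only  66.1%
#>     fulvestrant      55.4% (SEM 7.0), responders only  55.4%
#>   E2 gradient (n=29): Spearman rho=-0.379, 1-sided p=0.02162
#>   note: all p-values uncorrected; sidedness as labeled per test
```

The automated score tracks the ground truth within the ROI (34.1% vs
35.4%); the simulated trial reproduces the design's qualitative picture —
Ki67 falls in every arm, the decrease is larger after menopause on
tamoxifen, the postmenopausal arms are statistically indistinguishable, and
higher residual estradiol dampens the effect.

## The analysis workflow

The `analysis/` directory holds numbered drivers that run the whole study
on synthetic data, writing tables under `results/`:

| script | writes |
|---|---|
| `01_simulate.R` | slide panel + ground truth, trial table, expression matrix |
| `02_score.R` | classifier summary, per-ROI automated vs truth indices |
| `03_concordance.R` | Spearman + ICC(2,1) agreement report |
| `04_trial_stats.R` | full paired-response report (text + JSON) |
| `05_expression.R` | moderated-t, signature and between-arm tests |

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

## Documentation

The methods vignette (`vignettes/ki67-window-methods.Rmd`) documents the
stain model, every pipeline parameter with units and defaults, what the
synthetic generators do and do not emulate, the statistical conventions
(ratio parametrisations, test scales, censoring), and known limitations.
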