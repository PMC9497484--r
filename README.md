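# skewotsu

Automatic histogram thresholding for 8-bit grayscale images whose intensity
histograms are **skewed to the right** — the regime of MRI brain-tumor
slices and other biomedical images where multiplicative noise gives each
tissue class a lognormal, long-bright-tailed intensity distribution.

Otsu's classical criterion picks the threshold t\* maximizing the
between-class variance

    σ²_B(t) = Po(t)·(μo(t) − μT)² + Pb(t)·(μb(t) − μT)²,

which presumes roughly symmetric class modes. On right-skewed histograms
the bright class's linear-scale variance is inflated by its tail and the
maximizer drifts, leaking background into the mask. `skewotsu` implements,
over one shared cumulative-moment engine:

* **`otsu_gaussian`** — the classical criterion (rational form, with the
  explicit two-term form kept for cross-checking);
* **`otsu_lognormal`** — the same between-class variance computed on
  **log-mapped intensities** λ(i) = log(i+1): if the classes are
  lognormal they are Gaussian on the log scale, so the criterion is applied
  in the scale where its assumption holds;
* **`otsu_modified`** — the "substitute the lognormal mean into Otsu's
  rational form" baseline from the literature (algebraically equivalent to
  the log-space criterion as reconstructed here; see the vignette).

Around the objectives: a seeded generator of two-region 256×256 lognormal
mixture images with exact ground truth, supervised (Jaccard, F-score,
accuracy) and unsupervised (image uniformity, region contrast) evaluation,
and a tidyverse-style comparison pipeline (tibbles in/out, `tidy()`,
`glance()`, `autoplot()`).

## Worked example

```r
library(skewotsu)

ds  <- generate_dataset(6, "high_skew", seed = 42)   # skewed mixtures + truth
fit <- threshold_image(ds$image[[1]], "otsu_lognormal")
glance(fit)
#> # A tibble: 1 × 6
#>   method         t_star degenerate n_object n_background prop_object
#>   <chr>           <int> <lgl>         <int>        <int>       <dbl>
#> 1 otsu_lognormal     60 FALSE         29753        35783       0.454

cmp <- run_comparison(ds)      # 3 methods × 5 metrics per image
cmp
#> <skewotsu_comparison> 6 image(s), methods: otsu_gaussian, otsu_modified, otsu_lognormal
#> # A tibble: 3 × 8
#>   method      IU    RC jaccard fscore accuracy supervised_mean unsupervised_mean
#>   <chr>    <dbl> <dbl>   <dbl>  <dbl>    <dbl>           <dbl>             <dbl>
#> 1 otsu_ga… 0.906 0.572   0.514  0.679    0.792           0.662             0.739
#> 2 otsu_mo… 0.888 0.592   0.719  0.836    0.857           0.804             0.740
#> 3 otsu_lo… 0.888 0.592   0.719  0.836    0.857           0.804             0.740
#> increase rates vs otsu_gaussian (%):
#> # A tibble: 6 × 4
#>   method         family       average increase_rate
#>   <chr>          <chr>          <dbl>         <dbl>
#> 1 otsu_gaussian  supervised     0.662         0
#> 2 otsu_modified  supervised     0.804        21.5
#> 3 otsu_lognormal supervised     0.804        21.5
#> 4 otsu_gaussian  unsupervised   0.739         0
#> 5 otsu_modified  unsupervised   0.740         0.166
#> 6 otsu_lognormal unsupervised   0.740         0.166

best_method_select(run_comparison(ds,
  methods = c("otsu_gaussian", "otsu_lognormal")))
#> [1] "otsu_lognormal"
```

Reading the output: on these strongly right-skewed, overlapping mixtures
the log-domain objective places t\* near the boundary that minimizes pixel
misclassification, lifting mean Jaccard from 0.51 to 0.72 and pixel
accuracy from 0.79 to 0.86 over the classical criterion; the unsupervised
scores barely move because both segmentations produce internally fairly
uniform regions. `t_star = 60` for the first image is the gray level above
which pixels are called object (bright-object polarity; `invert = TRUE`
flips it).

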