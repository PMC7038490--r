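# cloudtongue

Fuzzy, sentence-level taste evaluation of Chinese liquor from electronic
tongue readings, using the normal cloud model.

## What problem this solves

An electronic tongue measures ten steady-state membrane potentials (mV) per
liquor sample — five taste channels (umami, salty, sour, astringent, bitter)
and five aftertaste channels. A classifier can label the sample with one of
the four flavor styles (*jiang*, *feng*, *nong*, *mild*), but a human taster
does more: they produce a graded verbal judgement such as *"This liquor is
fully mellow, elegant and delicate, coordination"*, drawing words from the
standardized liquor sensory lexicon (GB/T 33405-2016) with frequencies that
reflect panel consensus. `cloudtongue` reproduces that behaviour end to end:

1. **Synthetic data** — a calibrated generator emulating the 4 × 20 × 10
   electronic-tongue dataset (no raw instrument data are redistributable).
2. **PCA preprocessing** — the ten channels compress onto a 2-D taste plane;
   the first component carries ~94% of pooled variance.
3. **Flavor classification** — an RBF-kernel SVM whose cost `c` and kernel
   width `g` are tuned by a genetic algorithm (population 20, 5-fold
   cross-validation fitness, `c, g ∈ [2⁻¹⁰, 2¹⁰]`).
4. **Cloud model** — each flavor is a 2-D *normal cloud* concept with
   per-dimension characteristics (Ex, En, He): expectation, entropy
   (fuzziness scale) and hyper-entropy (randomness of the fuzziness).
   Backward generators estimate these from score clusters; forward
   generators emit random "droplets" with certainty degrees.
5. **Word regions** — panel word frequencies map to nested concentric
   ellipses (central region plus annuli) around the flavor's cloud centre,
   with semi-axes at multiples of En, capped at 3 En.
6. **Evaluation** — five droplets are drawn from the predicted flavor's
   cloud, each lands in a word region, and the de-duplicated words (centre
   to periphery) are composed into the output sentence. The sentence varies
   from run to run — like a human's phrasing — while respecting the panel's
   word statistics.

The methods vignette (`vignettes/cloudtongue-methods.Rmd`) documents the
model, the estimators, every numerical choice and the known limitations.

## Worked example

The full pipeline — generate data, split 14/6 per class, fit PCA, tune the
SVM by GA, classify held-out samples, build word regions from simulated
panel votes, and evaluate two held-out samples per flavor:

```r
library(cloudtongue)

data <- generate_taste_dataset(synthetic_config(), seed = 7)
head(data[, 1:6], 3)
#>   sample_id flavor     ch01     ch02      ch03     ch04
#> 1  jiang_01  jiang 26.50282 23.32715 -35.44133 18.57310
#> 2  jiang_02  jiang 23.80255 26.22595 -37.09748 18.69928
#> 3  jiang_03  jiang 24.11842 23.80559 -36.89616 20.21631

report <- run_pipeline(seed = 7)
#> Warning message:
#> sample variance below En^2; clamping He to 0
report
#> taste_report: test accuracy 100.0% (CV fitness 100.0%); PC1 0.9484, cumulative 0.9837
#>  sample_id predicted_flavor
#>    feng_07             feng
#>    feng_15             feng
#>   jiang_04            jiang
#>   jiang_18            jiang
#>    mild_14             mild
#>    mild_12             mild
#>    nong_18             nong
#>    nong_08             nong
#>                                                                                                    sentence
#>                                     This liquor is sweet and cool, mellow and elegant, all tastes harmonize
#>                                        This liquor is sweet and cool, all tastes harmonize, mellow fullness
#>                            This liquor is fully mellow, elegant and delicate, long aftertaste, coordination
#>                                This liquor is fully mellow, elegant and delicate, full bodied, coordination
#>  This liquor is pure fragrance, sweet and soft, long aftertaste, sweet and refreshing, natural coordination
#>                                        This liquor is sweet and soft, long aftertaste, natural coordination
#>                             This liquor is soft and sweet, sweet and refreshing, mellow, alcohol harmonious
#>                            This liquor is sweet and refreshing, mellow, alcohol harmonious, long aftertaste
```

The pieces are all usable on their own. The packaged jiang descriptor and
its published region multipliers:

```r
desc <- liquor_descriptors()$jiang
desc
#> cloud2d:
#>   PC1: Ex = 41.6501, En = 2.7506, He = 1.2743
#>   PC2: Ex = -23.6840, En = 2.3288, He = 1.1007

mult <- liquor_region_multipliers()$jiang
regions <- build_region_set_explicit(desc, mult$multipliers, mult$words)
regions
#> [Fully mellow] (x-41.6501)^2/2.8881^2 + (y+23.6840)^2/2.4452^2 <= 1
#> [Elegant and delicate] (x-41.6501)^2/4.1259^2 + (y+23.6840)^2/3.4932^2 <= 1 & (x-41.6501)^2/2.8881^2 + (y+23.6840)^2/2.4452^2 > 1
#> [Full bodied] (x-41.6501)^2/4.8411^2 + (y+23.6840)^2/4.0987^2 <= 1 & (x-41.6501)^2/4.1259^2 + (y+23.6840)^2/3.4932^2 > 1
#> [Long aftertaste] (x-41.6501)^2/6.1613^2 + (y+23.6840)^2/5.2165^2 <= 1 & (x-41.6501)^2/4.8411^2 + (y+23.6840)^2/4.0987^2 > 1
#> [Coordination] (x-41.6501)^2/8.2518^2 + (y+23.6840)^2/6.9864^2 <= 1 & (x-41.6501)^2/6.1613^2 + (y+23.6840)^2/5.2165^2 > 1
```

Drop five cloud droplets into those regions and compose the sentence:

```r
drops <- forward_cloud2d(desc, 5, seed = 3)
drops
#>         x1        x2        mu
#> 1 41.69603 -24.14826 0.9533435
#> 2 41.85321 -24.71675 0.6326935
#> 3 45.08968 -24.68249 0.4345177
#> 4 40.08699 -20.49234 0.2248597
#> 5 45.45232 -23.18524 0.4390798

idx <- locate_region(regions, as.matrix(drops[, c("x1", "x2")]))
idx
#> [1] 1 1 2 2 2

compose_sentence(regions$words[sort(unique(idx))])
#> [1] "This liquor is fully mellow, elegant and delicate"
```

Alternatively, derive the regions from panel word frequencies with the
quantile rule (`build_region_set()`), estimate a descriptor from data
(`backward_cloud2d()`), or check that a descriptor's certainty density
integrates to one (`total_contribution()`).

A small command-line front end ships at `inst/cli/cloudtongue.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/cloudtongue.R", package="cloudtongue"))') run --seed 7`)
with `simulate`, `regions` and `run` subcommands.

## Package layout

| Path | Contents |
| --- | --- |
| `R/cloud_core.R` | descriptors, backward/forward cloud generators, contribution integrals |
| `R/synthetic_data.R` | calibrated dataset generator, panel vote simulation |
| `R/preprocessing.R` | PCA fit/project/serialize |
| `R/flavor_classifier.R` | stratified folds/split, CV fitness, GA search, SVM train/predict |
| `R/lexicon_regions.R` | word frequency tables, quantile multipliers, region sets, droplet location |
| `R/evaluator.R` | sentence composition, per-sample evaluation, `run_pipeline()`, report writer |
| `R/fixtures.R` | packaged descriptors, lexicons, panel statistics, region multipliers |
| `inst/extdata/` | the fixtures as JSON |
| `inst/cli/` | command-line front end |
| `tests/testthat/` | oracle-based unit tests plus end-to-end acceptance tests |
| `scripts/acceptance.R` | standalone reproduction script (see above) |
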