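# phasedeath

Label-free discrimination of alive, apoptotic and necroptotic cells in
quantitative phase images from digital holographic microscopy (DHM).

DHM records, per pixel, the phase delay Δφ that light accumulates while
crossing a transparent cell. Phase delay relates to apparent specimen
height through

    Δφ = (2π / λ) (η_i − η_media) · h

with λ the illumination wavelength and η_i, η_media the refractive
indices of cell and medium. The resulting *optical height*
h = Δφ·λ / (2π·(η_i − η_media)) mixes thickness with refractive-index
contrast, and that mixture is informative: chromatin condensation in
apoptosis raises it, membrane pore formation in necroptosis lowers it.
`phasedeath` exploits this signal in a five-stage pipeline:

1. **Phase optics** — phase ↔ optical-height conversion; float-TIFF +
   JSON-sidecar capture I/O.
2. **Segmentation** — Otsu (or fixed) thresholding, 8-connectivity
   components, one 66×66 crop per component with area strictly inside
   (80, 600) px and a crop box fully inside the field.
3. **Label purification** — a supervised anomaly-detection (SAD) filter:
   a linear SVM over crop embeddings, trained on 200 alive + 100 + 100
   dead reference crops, discards crops whose Alive/Death prediction
   contradicts their capture's condition or whose score does not exceed
   T = 0.01.
4. **Classification** — class balancing to the smallest group, stratified
   80/20 split, and a CNN with the transfer-learning head surgery:
   backbone (VGG-19 arrangement, or a desk-scale small CNN) →
   FC-64 → ReLU → FC-3 → softmax over (alive, apoptosis, necroptosis).
5. **Evaluation** — per-class accuracy, confusion matrix, one-vs-rest
   ROC with trapezoidal AUC.

A seeded synthetic-capture generator with planted class morphologies
(spread irregular alive cells; shrunken, blebbed, optically taller
apoptotic cells; swollen, smooth, optically flatter necroptotic domes)
makes the entire pipeline runnable and testable without microscope data.

## A worked example

```r
library(phasedeath)

result <- run_training_pipeline(pipeline_config(seed = 1))
result$log
#> # A tibble: 4 × 4
#>   stage         n_in n_kept n_discarded
#>   <chr>        <int>  <int>       <int>
#> 1 segmentation   736    720          16
#> 2 sad_filter     720    562         158
#> 3 balance        562    483          79
#> 4 split_train    483    387          96

holdout <- run_holdout_evaluation(result)
holdout$report
#> <eval_report>
#>   alive        n =   169  accuracy = 0.911  AUC = 0.982
#>   apoptosis    n =   192  accuracy = 0.953  AUC = 0.998
#>   necroptosis  n =   203  accuracy = 0.946  AUC = 0.986
#>   overall accuracy = 0.938
```

The stage log mirrors the pipeline bookkeeping: at every stage
kept + discarded equals the input. The holdout report is computed on
captures from seed streams never used in training (enforced by capture-id
disjointness); each planted class is recovered well above 85% at the
package's desk-scale defaults. `tidy()`, `glance()` and `autoplot()`
methods are available for the report, the classifier and the SAD filter;
`autoplot(holdout$report)` draws the three one-vs-rest ROC curves.

A thin command-line wrapper ships in `inst/cli/phasedeath`
(`generate`, `crop`, `sad-train`, `sad-apply`, `train`, `evaluate`,
`run-all`), each command taking `--config`, `--seed`, `--out`.

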