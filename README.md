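# rst2g

Breast-tumor segmentation in dynamic contrast-enhanced MRI (DCE-MRI) from
pre-contrast, post-contrast and residual (post − pre) volumes.

DCE-MRI captures the kinetics of a gadolinium contrast agent: tumors enhance
strongly after injection, so the voxel-wise residual image concentrates the
signal that separates lesion from parenchyma. `rst2g` implements a
segmentation network that exploits this explicitly. Per 2D slice it encodes
the three channels with a **weight-sharing hybrid encoder** (convolutional
DownBlocks for local texture, bottleneck transformer blocks with multi-head
self-attention, softmax(QKᵀ/√d<sub>k</sub>)V, for global context), fuses
them at every scale with **residual-guided multi-scale refinement**
(modality-specific convolutions → channel-wise MLP → sigmoid spatial
attention, F<sub>out</sub> = F<sub>fused</sub> ⊙ σ(Conv₁ₓ₁(F<sub>fused</sub>))),
enhances the bottleneck with a **spatiotemporal graph module** (dense graph
attention α<sub>ij</sub> = softmax LeakyReLU(aᵀ[Wh<sub>i</sub>‖Wh<sub>j</sub>])
over spatial nodes per modality, batch-wise slice recalibration, and
inter-temporal fusion across modalities), and decodes with a U-Net-style
chain of bilinear upsampling and fused skips. Training minimises

> L = L<sub>Dice</sub> + λ·L<sub>BCE</sub> + β·L<sub>Boundary</sub>,  λ = 0.5, β = 0.2,

where the boundary term is the mean L1 difference of the two directional
3×3 Sobel gradient maps. Evaluation reports the Dice similarity coefficient
(DSC), Jaccard index (JI) and relative volume difference (RVD), per patient
and as cohort mean ± SD.

The package is self-contained: a synthetic DCE phantom generator (smooth
textured background, contrast-enhancing ellipsoidal tumor, additive
acquisition noise) makes every stage — training, cross-validation,
prediction, ablation, Grad-CAM — exercisable without downloading any
imaging collection. The network runs on a small reverse-mode autodiff
engine on dense R arrays with compiled (Rcpp/RcppArmadillo) convolution and
batch-norm kernels; no external deep-learning framework is required.

## Worked example

Train the small CPU configuration on a 10-phantom cohort with a
patient-level stratified split and evaluate on the held-out patients
(runs in about 1–2 minutes on one core):

```r
library(rst2g)

cohort <- generate_cohort(10, seed = 123, shape = c(8L, 32L, 32L))
split  <- split_patients(cohort, k = 5, test_frac = 0.3, seed = 7)
ids    <- vapply(cohort, function(s) s$pre$patient_id, "")

fit <- train_model(rst2g_model(rst2g_tiny_config(seed = 42)),
                   studies_by_id(cohort, setdiff(ids, split$test_ids)),
                   train_config(epochs = 15L, seed = 1L))

ev <- evaluate_model(fit$model, studies_by_id(cohort, split$test_ids))
ev$per_study
#>   patient_id       dsc        ji         rvd
#> 1       P002 0.9636364 0.9298246 -0.02395210
#> 2       P003 0.9591398 0.9214876 -0.07851240
#> 3       P005 0.9530201 0.9102564  0.09859155
#> 4       P006 0.9032258 0.8235294  0.18309859
ev$summary
#>   metric       mean         sd
#> 1    dsc 0.94475552 0.02802626
#> 2     ji 0.89627450 0.04915502
#> 3    rvd 0.04480641 0.11825513
```

Each row is one held-out patient: a DSC of 0.96 means the predicted and true
tumor masks overlap almost completely; an RVD of −0.024 means the predicted
volume underestimates the true tumor volume by 2.4 %. The summary is the
cohort mean ± SD of each metric. `predict_volume()` returns the stitched
binary mask for a study, `grad_cam()` the per-slice localisation heatmap,
and `run_ablation()` retrains the four structural variants (without local
convs, without transformer blocks, without multi-scale refinement, without
the graph module) under identical seeds.

A command-line front end wrapping the same functions is installed at
`inst/cli/rst2g.R`:

```sh
Rscript inst/cli/rst2g.R phantom --out cohort_dir --n 10 --seed 3 --shape 8,32,32
Rscript inst/cli/rst2g.R train --manifest cohort_dir/manifest.csv --out run --config cfg.yaml
Rscript inst/cli/rst2g.R evaluate --manifest cohort_dir/manifest.csv \
    --checkpoint run/checkpoint.rds --out metrics.csv
```

## Scope

The methods vignette (`vignettes/rst2g-methods.Rmd`) documents the model,
every tunable parameter, the design decisions taken where the architecture
left choices open, what the phantom generator does and does not emulate, and
known limitations. Registration, bias-field correction, DICOM parsing and
cohort download tooling are out of scope; NIfTI is the on-disk format.
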