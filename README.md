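# mfcrad

Multi-feature-combined (MFC) modeling of tumor local failure from
pre-treatment CT. The package implements, end to end and in plain R (with
a small C++ core):

* **handcrafted radiomics** — 105 features of the GTV (13 shape, 18
  intensity, 20 histogram, 22 GLCM, 16 GLRLM, 16 GLSZM) under
  fixed-bin-number (32) discretization, with 3D texture matrices over the
  13 unique directions of the 26-neighbourhood;
* **deep features** — an 8×8×8 cm³ VOI around the tumor encoded by a
  frozen five-block 3D U-Net encoder (two 3×3×3 convolutions + ReLU per
  block, 2×2×2 max pooling, channels 32→512) and global average pooling
  into a 512-vector; weights loadable from an archive or seeded at random;
* **fusion and preprocessing** — concatenation of handcrafted + deep +
  clinical blocks (621 columns for a surgery-style cohort, 623 with SBRT
  treatment fields), per-fold multicollinearity reduction (connected
  components of the |r| > 0.95 graph, min-univariate-p representative),
  training-statistics z-scoring, and Gaussian-noise oversampling with
  class balancing;
* **four model variants** — PI (clinical only), R (radiomics only), DL
  (frozen encoder + sigmoid head trained with Adam on binary
  cross-entropy), MFC (all blocks) — over three classifier backends
  (L2 logistic via L-BFGS, RBF SVM with Platt scores, probability random
  forest);
* **validation** — leave-one-out with pooled scoring, and Monte-Carlo
  random validation with stratified 70/30 splits, vertically averaged ROC
  bands, and paired t-test model comparison;
* **synthetic phantom cohorts** — generator reproducing the structure of
  the two study cohorts (83 subjects / 7 local failures, surgery; 84 / 9,
  SBRT; tumor sizes 0.6–6 cc) with a configurable planted image–outcome
  effect, so the whole pipeline runs and is tested without any patient
  data.

AUC is computed as the trapezoidal integral of the tie-grouped ROC, which
equals the concordance probability P(s⁺ > s⁻) + ½ P(s⁺ = s⁻); stratified
splits use round-half-to-even, the convention that reproduces the
published training-fold compositions (53 + 5 of 83/7; 52 + 6 of 84/9).

## Worked example

```r
library(mfcrad)

# a surgery-structured phantom cohort with a planted +60 HU effect in
# the 7 event-positive tumors
cc <- cohort_config("surgery", effect_mean_hu = 60, effect_texture = 1.5,
                    seed = 0)
weights <- init_encoder_weights(seed = 0)   # random-weight encoder
ds <- synthesize_dataset(cc, weights)       # 83 x 621 feature table
dim(ds$table)
#> [1]  83 621

fus <- fusion_config()                      # |r|>0.95, oversample 4x
for (v in c("PI", "R", "MFC")) {
  r <- run_mcrv(ds$table, ds$labels,
                model_variant(v, classifier_spec("forest")),
                n_folds = 20, seed = 0, config = fus)
  print(r)
}
#> <eval_result> PI / mcrv, 20 folds
#>   AUC 0.549 +/- 0.215  sens 0.000  spec 0.943  acc 0.868
#> <eval_result> R / mcrv, 20 folds
#>   AUC 1.000 +/- 0.000  sens 0.800  spec 1.000  acc 0.984
#> <eval_result> MFC / mcrv, 20 folds
#>   AUC 1.000 +/- 0.000  sens 0.425  spec 1.000  acc 0.954
```

The clinical-only model hovers at chance (no demographic–label link is
planted), while the radiomics and combined models recover the planted
effect — the qualitative ordering the pipeline is designed to exhibit.
Each printed line is the mean ± SD over the 20 Monte-Carlo folds, with
confusion metrics at a 0.5 score threshold.

A single phantom and its feature vector:

```r
ph <- generate_phantom(c(128, 128, 128), tumor_volume_cc = 1.75, seed = 1)
fv <- extract_handcrafted(ph$volume, ph$mask)
length(fv)          #> 105
fv["shape__volume_mm3"]
#> shape__volume_mm3
#>              1752
deep <- deep_features(ph$volume, ph$mask, weights)
length(deep)        #> 512
```

A command-line front end over the same functions ships in
`inst/cli/mfcrad.R` (subcommands `synth`, `radiomics`, `deepfeat`,
`evaluate`, `all`), and `run_pipeline()` executes the whole
synthesize → extract → fuse → evaluate chain from a YAML config.

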