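# vmatqa

Unsupervised anomaly detection for volumetric modulated arc therapy
(VMAT) treatment plans — an automated physics plan review aid.

A VMAT plan is delivered over arcs of control points (CPs), each holding a
gantry angle, the positions of 40 pairs of multi-leaf-collimator (MLC)
leaves, and a per-CP meterset $D_k$ (MU). `vmatqa` digitizes every CP
into a binary aperture map

$$A_k(i,j) = 1 \iff (i,j) \in \text{open region at CP } k$$

and an intensity (fluence) map $I_k = D_k A_k$, then trains a
**multi-task convolutional autoencoder** on regular plans only: an
encoder (four stride-2 conv blocks + a linear bottleneck $h$) feeding
two decoders that reconstruct the aperture $A'_k$ (binary cross-entropy
loss $L_A$) and the normalized dose $D'_k$ (squared-error loss
$L_D$), minimizing $L_R = \lambda L_A + L_D$ with Adam (lr 1e-3).
A plan is scored by reconstruction distances

* $d_I = \frac{1}{KMN}\sum_k \lVert I_k - D'_k A'_k \rVert^2$,
* $d_A$ (aperture BCE) and $d_D$ (dose MSE),

and classified anomalous when its score strictly exceeds a threshold
$\alpha$ calibrated either at zero false-negative rate on labelled
scores or as a label-free quantile of regular scores. Vanilla,
contractive and variational autoencoder baselines, a physically
constrained synthetic plan simulator with six labelled fault kinds, plan
JSON I/O, machine-constraint validation (leaf gap / travel / speed), and
a five-fold cross-validated evaluation pipeline (tie-aware AUC,
accuracy, precision, FPR, F1) are included. The neural networks are
implemented inside the package (RcppArmadillo conv primitives + an R
training loop); no deep-learning framework is required.

## Worked example

```r
library(vmatqa)

# a small labelled cohort: two-arc 90-CP plans, 3 injected faults
cfg   <- sim_config(n_regular = 12, n_anomalous = 3, seed = 7)
plans <- make_dataset(cfg)
validate_plan(plans[[1]])          # 0 rows: simulator obeys the machine
grid  <- build_grid(cfg$machine, 1.25)
tens  <- featurize_dataset(plans, grid, c(64, 64))

fit <- vmat_ae(tens[1:10], kind = "multitask", epochs = 2, seed = 1)
print(fit)
#> multitask autoencoder: input 64x64, latent 32, 1800 training CPs
#>   trained 2 epoch(s); final L_R = 0.54233

scores <- predict(fit, tens[11:15], type = "scores")
scores$true <- vapply(plans[11:15], function(p) p$label, "")
scores
#>     plan_id       d_I       d_A      d_D      true
#> 1  reg_0011 0.8712613 0.5045520 4.536873   regular
#> 2  reg_0012 0.8696774 0.4997305 2.708059   regular
#> 3 anom_0001 0.4995707 0.4731847 3.987886 anomalous
#> 4 anom_0002 0.4759188 0.4797019 4.916035 anomalous
#> 5 anom_0003 0.9893141 0.4810458 6.159161 anomalous

alpha <- calibrate_threshold(scores$d_I, scores$true,
                             threshold_policy("oracle_fnr0"))
classify(scores$d_I, alpha)        # zero false negatives by construction
#> [1] "anomalous" "anomalous" "anomalous" "anomalous" "anomalous"
```

`d_I` is the per-pixel mean squared intensity error on the MU scale. The
10x meterset spike (`anom_0003`) scores highest, but the two collapsed
apertures score *below* the regular plans — reconstruction error is
one-sided, and faults that remove intensity can hide from it (the
vignette's limitations section analyses this). The zero-FNR threshold
consequently drops below every anomaly and flags all five plans,
illustrating the false-positive price of a never-miss rule.
`run_experiment()` drives
the full comparison — four model kinds, three distances, five-fold
cross-validation, score/metric tables and ROC/box-plot figures — from one
config into one artifact directory, and
`inst/cli/vmatqa.R` exposes `simulate / featurize / train / score /
evaluate / run-all` subcommands for shell use.

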