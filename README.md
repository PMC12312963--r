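# pairreg

Oversmoothing mitigation for E(3)-equivariant graph neural networks, in R.

Scalar molecular properties are invariant under rigid motions of the atom
coordinates; equivariant graph networks (EGNNs) encode that symmetry by
updating node scalars only from squared inter-atomic distances and moving
coordinates only along pairwise difference vectors.  Deep stacks of such
layers *oversmooth*: node features converge toward indistinguishability,
which shows up as a shrinking Dirichlet energy across layers and a loss of
predictive power.  `pairreg` implements an equivariant graph convolutional
layer (EGCL) for fully connected molecular graphs plus the **PairReg**
mechanism against oversmoothing:

- a **concatenation residual** on node features,
  `h ← φ_r([h_prev ‖ h_new])`, with `φ_r` a linear map `ℝ^{2f} → ℝ^f`;
- **midpoint averaging** of coordinates inside each layer,
  `x ← (x_prev + x_new)/2`;
- a **coordinate-regression penalty** in the final loss,
  `L = MAE + λ · mean‖x_final − x_0‖`, the mean per-atom Euclidean
  displacement between the stack's output coordinates and the input
  geometry.

One layer computes, for every directed edge (i, j) of the fully connected
graph:

    m_ij = φ_e(h_i, h_j, ‖x_i − x_j‖²)
    e_ij = σ(w·m_ij + b)
    m_i  = Σ_{j≠i} e_ij m_ij
    x_i' = x_i + C Σ_{j≠i} (x_i − x_j) φ_x(m_ij)
    h_i' = φ_h(h_i, m_i)

The package is aimed at method developers studying oversmoothing in
geometric message passing: it ships the layer and mechanism, a hand-derived
exact backward pass (verified against finite differences), Adam training
with a warmup-plus-cosine schedule, Dirichlet-energy and symmetry
diagnostics, a fully synthetic molecular benchmark with an analytically
rigid-motion-invariant target, XYZ file I/O and a small CLI — no external
datasets or GPU required.

## Worked example

Train the full mechanism on a synthetic benchmark and inspect the
diagnostics:

```r
library(pairreg)

ds    <- generateDataset(synthConfig(nMolecules = 140, seed = 42))
train <- datasetSplit(ds, "train")
val   <- datasetSplit(ds, "val")

cfg <- modelConfig(nLayers = 9, fHidden = 8, mWidth = 8,
                   mode = pairRegMode("full"), seed = 42)
ctl <- trainControl(epochs = 80, batchSize = 32, warmupEpochs = 20,
                    peakLR = 5e-3, seed = 42)
fit <- trainModel(train, cfg, ctl, valGraphs = val)
fit
#> PairRegFit: L9-f8-m8-full-sum-seed42
#>   80 epochs; final train loss 0.33539, val MAE 1.184082

meanPredictorMAE(train, val)
#> [1] 2.829343
```

The trained 9-layer model reaches a validation MAE of **1.184** on the
noisy pairwise-potential target, versus **2.829** for the
predict-the-training-mean baseline.  The diagnostics report confirms the
symmetry contracts at machine precision:

```r
diagnoseModel(val, fit$params, cfg, nTrials = 10, seed = 1)
#> DiagnosticsReport (L9-f8-m8-full-sum-seed42)
#>   layerwise Dirichlet energies:
#>     input    1.8114
#>     ...
#>     layer 9  0.880809
#>   invariance deviation:    1.11e-15
#>   equivariance deviation:  8.88e-15
#>   permutation deviation:   2.66e-15
```

The ablation presets `pairRegMode("full" | "coord" | "node" | "plain")`
switch the residual and the coordinate path independently; `"plain"` is the
unmodified EGCL baseline.

A thin CLI wraps the same functions
(`inst/exec/pairreg generate|train|evaluate|diagnose`), reading YAML run
configurations and writing dataset containers, model archives, metrics CSVs
and diagnostics reports.

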