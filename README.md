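# rpscore

Deep-learning scoring of RNA-protein docking decoys in R.

Rigid-body docking of an RNA onto a protein yields thousands of candidate
poses ("decoys"); a scoring function must rank the near-native ones first.
`rpscore` implements the full pipeline for a learned scoring function of
this kind, for structural bioinformaticians who want a transparent,
dependency-light reference implementation:

* **Structures** — a PDB parser for RNA-protein complexes (altloc
  resolution, hetero/water removal, hydrogen flagging), atom typing from
  tab-separated tables of per-atom masses and partial charges (85 canonical
  RNA entries; 167 canonical protein entries), and interface extraction at a
  6 Å heavy-atom cutoff.
* **Featurization** — per-unit local coordinate frames
  (x = r<sub>N/CB</sub> − r<sub>C1'/CA</sub>,
  y = ½(r<sub>O5'/O</sub> + r<sub>C5'/C</sub>) − r<sub>C1'/CA</sub>,
  z = x × y, orthonormalized right-handed) and 32 Å / 1 Å voxel grids with
  occupancy, mass and charge channels, stacked into a
  3 × L × 32 × 32 × 32 tensor (L = 128). Grids are exactly invariant under
  global rigid motion — no rotational augmentation needed.
* **Networks** — a sequence-spatial ("4D") convolutional scorer with the
  layer schedule channels [64, 128, 256, 512, 512], sequence strides
  [2, 2, 2, 1, 1], spatial max-pooling and a final global spatial average
  (flattened representation: 512 × 16 = **8192**), plus a per-unit 3D-CNN
  baseline (channel doubling 64 → **1024** while 32³ pools to 1³, mask-aware
  mean over units). Convolution, normalization, pooling and backprop are
  implemented in base R (im2col + matrix multiply) and verified against
  numerical gradients; `trace_shapes()` computes every intermediate shape
  symbolically.
* **Training** — interface-RMSD regression (or native/non-native
  classification) under mean squared error with mini-batch gradient descent
  (plain SGD, momentum, or Adam), plateau stopping, deterministic seeding
  and bit-reproducible checkpoints.
* **Decoy generation** — synthetic toy complexes and rigid-body decoy sets
  with exact, binned ligand RMSDs, standing in for an external docking
  pipeline so everything runs offline.
* **Evaluation** — RMSD, Kabsch superposition (proper rotations only),
  CAPRI-style interface RMSD (I_rmsd: native-defined interface, protein
  superposition, all heavy interface atoms), success\@N at the 4.0 Å
  threshold (closed interval), and a simplified hydrogen-bond detector
  (donor–acceptor ≤ 3.35 Å, hydrogen–acceptor ≤ 2.7 Å).

See `vignettes/scoring-methods.Rmd` for the model, its assumptions, and the
design decisions.

## Worked example

Build a toy complex, generate rigid-body decoys with known interface RMSDs,
overfit a reduced-size scorer (L = 8, 8³ grids) and rank the poses:

```r
library(rpscore)

native <- generate_toy_complex(seed = 1, n_nt = 6, n_aa = 8)
dset   <- generate_decoy_set(native, decoy_spec(
  n_decoys = 7, rmsd_bins = list(c(0, 4), c(4, 12)), quotas = c(3, 4),
  seed = 7))

labeled <- make_labels(
  c(list(native = native), lapply(dset$decoys, `[[`, "structure")),
  native, scheme = "irmsd_regression", L = 8, grid_dim = 8)

set.seed(1)
model <- build_4dcnn(network_config(conv_channels = c(8, 16, 32, 32, 32),
                                    L = 8, grid_dim = 8))
fit <- train(model, labeled,
             training_config(learning_rate = 3e-3, max_steps = 300,
                             optimizer = "adam", seed = 1,
                             plateau_window = Inf))
score_decoys(fit$model, labeled)
```

Output (the `score` column approximates each pose's interface RMSD in Å;
lower is better, and the native is ranked first):

```
   decoy_id    score rank        # true I_rmsd
1    native 2.441312    1        #  0.00
2 decoy_006 2.802009    2        #  1.67
3 decoy_007 3.847084    3        #  3.62
4 decoy_005 5.459506    4        #  5.13
5 decoy_004 5.465732    5        #  5.20
6 decoy_001 6.271842    6        #  5.72
7 decoy_003 8.413179    7        #  8.54
8 decoy_002 9.644683    8        # 13.76
```

With this ranking, `success_rate(..., N = 1)` is 1: the best-scored pose is
native-like (I_rmsd ≤ 4.0 Å). A command-line surface wraps the same steps:

```sh
Rscript -e 'rpscore::rpscore_cli()' decoys    --out decoyset --seed 1
Rscript -e 'rpscore::rpscore_cli()' featurize --out caches decoyset/*.pdb
```

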