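---
title: "Scoring RNA-protein docking decoys with sequence-spatial convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring RNA-protein docking decoys with sequence-spatial convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpscore)
```

## The problem

Rigid-body docking of an RNA onto a protein produces thousands of candidate
poses ("decoys") of which only a handful resemble the experimentally
determined complex. A scoring function ranks decoys by predicted
native-likeness; the community convention calls a pose native-like when its
interface RMSD (I~rmsd~) to the native complex is at most 4.0 Å, measured
after superposing the protein partners. `rpscore` implements a learned
scoring function for this task: the interface is converted into a stack of
per-residue voxel grids and scored by a convolutional network that mixes
information along both the spatial axes within each grid and the sequence
axis across grids.

## Representation

**Interface.** A nucleotide or residue belongs to the interface when any of
its heavy atoms lies within 6 Å (closed interval) of a heavy atom of the
partner molecule. Membership is decided per unit, not per atom, because all
downstream features are per-unit grids. Hydrogens never participate in
distance tests or featurization: most X-ray models lack them, and excluding
them keeps results deterministic across deposition conventions.

**Local frames.** Each interface unit gets a right-handed orthonormal frame
from four anchor atoms. With origin at C1′ (nucleotides) or CA (residues):

$$\mathbf{x} = \mathbf{r}_{N/CB} - \mathbf{r}_{C1'/CA}, \qquad
  \mathbf{y} = \tfrac{1}{2}(\mathbf{r}_{O5'/O} + \mathbf{r}_{C5'/C}) - \mathbf{r}_{C1'/CA},$$
$$\mathbf{z} = \mathbf{x} \times \mathbf{y}, \qquad
  \mathbf{X} = \mathbf{x}/\lVert\mathbf{x}\rVert, \quad
  \mathbf{Z} = \mathbf{z}/\lVert\mathbf{z}\rVert, \quad
  \mathbf{Y} = \mathbf{Z} \times \mathbf{X}.$$

The glycosidic nitrogen is N9 for purines and N1 for pyrimidines. Glycine
has no CB; a virtual CB is constructed from N, CA and C with the standard
ideal-tetrahedral coefficients rather than discarding glycines, which are
common at interfaces. Collinear anchors (a vanishing $\mathbf{x}$ or
$\mathbf{x}\times\mathbf{y}$) are a hard error; units that fail are dropped
from the tensor with a warning.

Because every coordinate entering the grid is expressed in these frames,
the representation is exactly invariant under global rigid motion of the
complex — no rotational data augmentation is needed, and the test suite
asserts bit-identical grids after random rigid motions.

**Voxel grids.** Each unit's frame carries a 32 Å cube of 1 Å voxels
(32 × 32 × 32; extent and bin count are stated, the 1 Å edge is their
quotient). Every *typed* heavy atom of the whole complex — both molecules,
which is what lets a grid encode intermolecular contacts — is binned at
`floor(c + 16)` per axis (half-open bins; the +16 Å face is excluded).
Three channels accumulate occupancy count, mass (Da) and partial charge (e).
There is no Gaussian smearing: accumulation is a pure count/sum, so channel
totals are conserved and checked against brute-force containment in tests.

**Atom typing.** Masses and charges come from two tab-separated tables
(residue code, atom name → type id, mass, charge) shipped under
`inst/extdata/`. The canonical RNA table has exactly 85 entries (four
ribonucleotides with full 5′-phosphate backbones: 12 backbone atoms each,
plus 10/11/8/8 base atoms for A/G/C/U). The canonical protein table
enumerates 167 heavy atoms (backbone N, CA, C, O plus standard side chains).
The published description counts 225 protein types, which cannot be
reproduced by canonical heavy-atom enumeration; the reference table was not
available, so only the 85-entry RNA count is asserted. Masses are IUPAC
standard atomic weights; charges are AMBER-style approximations, and the
files are suffixed `_synthetic` to make their stand-in status explicit. The
table file is the single source of truth: pass your own path to
`atom_type_table()` to replace it. Unknown atoms are skipped with a warning
by default (`unknown_policy = "fail"` raises instead), so engineered
residues do not abort scoring.

**Tensor.** Grids are stacked RNA-first (by chain, then author numbering),
then protein, zero-padded to L = 128 slices with a 0/1 mask. If more than L
units are featurizable, the L units closest to the partner molecule are
kept. Padding slices are all-zero and are not masked inside convolutions:
zero is the natural "no unit" encoding for count/mass/charge channels.

## Architecture

The input is a `3 × L × 32 × 32 × 32` tensor. The scoring network has five
convolution blocks and one linear layer. Each block applies a genuine
4-axis kernel (3 along the sequence, 3 × 3 × 3 spatially; same-padding;
stride only on the sequence axis) realized as im2col plus one matrix
multiplication, followed by optional normalization, a rectified-linear
activation, and 2 × 2 × 2 spatial max-pooling (blocks 1–4). Block 5 replaces
pooling with a global spatial average. Channels are
`[64, 128, 256, 512, 512]` and sequence strides `[2, 2, 2, 1, 1]`, giving
the shape progression

| block | conv output | after pooling |
|-------|----------------------|---------------|
| 1 | 64 × 64 × 32³ | 64 × 64 × 16³ |
| 2 | 128 × 32 × 16³ | 128 × 32 × 8³ |
| 3 | 256 × 16 × 8³ | 256 × 16 × 4³ |
| 4 | 512 × 16 × 4³ | 512 × 16 × 2³ |
| 5 | 512 × 16 × 2³ | 512 × 16 (global average) |

so the flattened representation has 512 × 16 = 8192 components, mapped to a
scalar score by one linear layer. `trace_shapes()` computes this table
symbolically and is checked against real forward passes at reduced size.
A note on wording: descriptions of this design sometimes count "six layers
each with a convolution"; with a five-entry channel list the only reading
that reproduces every printed shape is five convolution blocks plus a final
fully connected layer, which is what is built here. Likewise a
"non-overlapping window of size 3" conflicts with the printed strides; the
strides win because only kernel 3 / padding 1 / stride `[2,2,2,1,1]` yields
128 → 64 → 32 → 16 → 16 → 16.

The **3D baseline** processes each unit's grid independently (3 × 3 × 3
convolutions, channel doubling from 64 to 1024 while pooling halves 32³ down
to 1³), averages the per-unit 1024-vectors under the mask, and applies one
linear layer. Because of the mean pooling its score is invariant to unit
order, which the tests assert; the sequence-aware network is not, by design.

**Normalization.** Batch statistics are undefined for a single position, so
blocks whose conv output is one (sequence × spatial) cell skip the norm
layer — this only occurs at reduced test sizes. With the stated batch size
of 1, classical running-statistics evaluation is inconsistent with
training-time normalization (training normalizes each sample by its own
statistics); in practice this destroyed scoring discrimination. The default
`norm_mode = "instance"` therefore uses current-sample statistics in both
modes; `"batch"` restores running-statistics evaluation for anyone who wants
the textbook behaviour.

**Initialization.** Seeded fan-in (He) scaling for weights, zero biases; an
all-zero input therefore scores exactly the head bias when normalization is
off, which is tested.

## Training

Decoys are labelled by their interface RMSD to the native
(`irmsd_regression`, the default — it gives a continuous native-likeness
signal and the native's label is analytically 0) or by the 4.0 Å indicator
(`native_binary`). The objective is mean squared error, optimized by
mini-batch gradient descent at the stated defaults (learning rate 1e-4,
batch size 1, up to 20000 steps) with plateau-based early stopping (relative
window-mean change below 1e-4). Backpropagation is hand-derived per layer
and verified against numerical gradients at relative error ~1e-11.

Plain SGD (optionally with momentum) is the default optimizer. For the
tiny overfitting runs used in tests (8 poses, 300 steps), plain SGD only
fits the label mean: after global average pooling the discriminative
component of the representation is small against the constant component, and
the resulting ill-conditioning exceeds what a few hundred first-order steps
can handle. `optimizer = "adam"` solves these runs (loss falls to <5% of its
initial value and the native ranks first); the test and acceptance runs use
Adam at learning rate 3e-3. Nothing about the fixture — its size, seeds,
step budget or thresholds — was adjusted to achieve this; the optimizer was
treated as the free design choice it is.

Checkpoints bundle kind, configuration and all parameters plus
normalization state; save → load → score is bit-identical. The checkpoint
with the lowest full-dataset evaluation loss is tagged "selected",
mirroring the practice of picking an intermediate-step model.

## Synthetic data: what it emulates and what it does not

`generate_toy_complex()` builds an idealized A-form-like RNA strand (bases
cycling A/G/C/U, full phosphate backbones) against an extended peptide
(ALA/GLY/SER/VAL), places them at a 4 Å closest approach (within the 3–5 Å
window typical of biological contacts), and adds ±0.05 Å of seeded jitter.
`generate_decoy_set()` then rejection-samples rigid-body perturbations of
the RNA — axis uniform on the sphere, angle uniform up to 60°, translation
uniform in a 12 Å ball — into explicit ligand-RMSD bins (default half the
decoys at ≤4 Å, half in 4–12 Å), recording exact transforms and RMSDs.

This replaces an external FFT-docking pipeline whose published recipe
(10000 docked decoys per complex, top 500 by RMSD) requires tools and
databases outside this package. Rigid perturbation with explicit RMSD bins
guarantees near-native coverage at tiny n, which "top-k by RMSD" cannot at
toy scale. The stand-in preserves what the scoring method needs — pose
diversity with exact labels — but does not emulate: docked poses' surface
complementarity (perturbed poses may clash or separate; there is no physics,
no clash relaxation), conformational (non-rigid) differences, or realistic
decoy score landscapes. One consequence is handled explicitly: a strongly
perturbed pose can have *no* contact within 6 Å, which real docked poses
essentially never do. `featurize_structure()` then falls back to the units
at the closest approach (cutoff widened to the minimum intermolecular
distance + 1 Å, with a warning) so every pose remains scoreable;
`assemble_tensor()` itself still treats an empty selection as an error.

A green tiny-overfit test therefore establishes that the representation
carries pose information and that the network and optimizer can exploit it —
not that the defaults would reach any particular benchmark success rate,
which would require the full training corpus and decoy generator.

## Evaluation

`rmsd()` is the plain paired-coordinate root-mean-square deviation, no
superposition. `superpose()` is the least-squares (Kabsch) fit via SVD with
the determinant correction, so reflections are never returned; which protein
atoms are fitted is configurable (`heavy`, the default, or `backbone`) since
the reference description does not say. `interface_rmsd()` defines interface
units on the *native* only (so the metric compares like with like across
decoys), superposes the decoy protein onto the native protein, applies that
transform to the whole decoy and takes the RMSD over all heavy atoms of the
native-interface units on both sides — all-atom rather than backbone-only,
consistent with an "all atoms" RMSD definition. `success_rate()` counts a
complex as predicted when any of its N best-scored decoys has I~rmsd~ ≤
4.0 Å (closed interval, asserted at the boundary).

The hydrogen-bond detector implements only the two printed distance cutoffs
(donor–acceptor ≤ 3.35 Å; hydrogen–acceptor ≤ 2.7 Å when hydrogens are
present, with attachment inferred at ≤ 1.2 Å) over simplified per-residue
donor/acceptor tables; no angular criteria. It is a screening tool, not a
replacement for a full geometry-aware assigner.

## Numerical choices and degenerate inputs

* Distance boundaries are closed (≤ 6.0 Å interface, ≤ 4.0 Å success).
* Voxel binning is half-open per axis; an atom exactly on the +16 Å face is
  outside, on the −16 Å face inside.
* Score ties are broken by decoy id, so rankings are reproducible.
* Orthonormality and handedness of frames are asserted at 1e-9; superposition
  orthogonality likewise. I~rmsd~ rigid-motion invariance is asserted at
  1e-6 Å (two SVDs apart).
* Degenerate inputs raise typed errors: missing anchors
  (`rpscore_frame_error`), collinear anchors (`rpscore_degenerate_frame`),
  collinear superposition input, empty native interface, atom-correspondence
  failures (naming the missing atoms), and checkpoint/tensor shape
  mismatches (naming expected vs got).
* All randomness (generator jitter, transform sampling, weight
  initialization, batch sampling) flows from explicit integer seeds; every
  pipeline stage is bit-reproducible at a fixed seed.

## Known limitations

* The canonical protein table (167 entries) cannot reproduce the published
  225-type count; the discrepancy is documented rather than papered over.
* Shipped partial charges are approximate stand-ins, not a validated force
  field; swap in your own table for production work.
* Training at the published scale (20000 steps on hundreds of complexes with
  500 decoys each) is out of scope on CPU; the training loop is validated by
  overfitting tiny synthetic sets.
* The pure-R network is intended for desk-scale verification, not
  throughput; a full-size forward pass is exercised symbolically
  (`trace_shapes()`), at reduced width in tests.
* mmCIF input, structure repair, modified residues beyond the tables, and
  composite CAPRI quality classes (fnat, DockQ) are out of scope.
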