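---
title: "Predicting local real-space chemical descriptors with localaim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting local real-space chemical descriptors with localaim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Real-space partitioning methods divide a molecule into atomic basins and
re-express every molecular observable as a sum of one-body (per-atom) and
two-body (per-pair) contributions: electron populations `N_A` and charges
`q_A = Z_A - N_A`, localization indices `lambda(A) = N_A - var_A`,
delocalization indices `delta(A, B) = -2 cov_AB` (a real-space bond
order), and an energy decomposition into intra-atomic self-energies and
pairwise interaction energies,

```
N = sum_A lambda(A) + sum_{A<B} delta(A, B)
E = sum_A E_intra^A + sum_{A<B} E_inter^{A,B}
E_intra^A  = T^A + Vee^A + VNe^A
E_inter^AB = Vee^AB + VNN^AB + VNe^AB + VeN^AB
```

These descriptors are chemically interpretable but expensive: they
require six-dimensional numerical integration over basin pairs.
`localaim` learns them directly from geometry with a neural network whose
architecture keeps the *local* structure of the theory: the usual pooling
step that collapses per-atom outputs into one molecular number is
removed, so the model predicts the per-atom and per-pair values
themselves, and molecular quantities are recovered by summation — which
simultaneously provides interpretability (every group-level statement
decomposes into atomic terms) and a free consistency check (the sum
rules above are known exactly for neutral molecules).

## Model

**Representation.** An element embedding followed by `n_interactions`
continuous-filter convolution blocks maps atomic numbers and coordinates
to an M x n matrix of atom environment vectors (the AE tensor). Each
block performs the residual update
`x_i <- x_i + W_out(sum_{j != i} W_in(x_j) * F(r_ij))` where the filter
`F` is a two-layer shifted-softplus network on a Gaussian radial
expansion of the interatomic distance, multiplied by a smooth cosine
cutoff that is exactly zero beyond `r_cut`. Geometry enters only through
distances, so the representation is invariant under rigid motions and
equivariant under atom relabeling.

**Readout.** One-body properties route each AE row to a head; two-body
properties concatenate `[AE_i, AE_j, r_ij]` (length `2n + 1`; the
explicit distance is included because most pair properties are dominated
by it). Four modes: one universal head (`AIMwise-1P`/`AIMwise-2P`), one
head per element (`ElementalAIMwise`, K = T heads), or one head per
unordered element pair (`ElementalPairAIMwise`, K = T(T+1)/2 heads),
with pairs routed by a symmetric injective integer identifier
(`pair_type_id(Zi, Zj) = b(b-1)/2 + a` with `a <= b`).

**Pair symmetrization.** A head is always evaluated on both
concatenation orders and the two outputs averaged. This makes the pair
prediction *exactly* symmetric under `i <-> j` for any weights; the
alternative (feeding a canonically ordered concatenation) was rejected
because it cannot disambiguate same-element pairs.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n` (feature width) | 64 | – | keeps the 2P descriptor (2n+1) moderate |
| `n_interactions` | 3 | – | standard depth for small molecules |
| `r_cut` | 5.0 | Angstrom | covers the whole benchmark molecules; smaller values trade accuracy for transferability |
| `n_rbf` | 20 | – | ~0.26 A center spacing on [0, r_cut] |
| head layers | 32, 16 | – | small shifted-softplus MLP per head |
| `w_local`, `w_global` | 1, 0.1 | – | loss tradeoff, see below |
| optimizer | Adam, lr 1e-3 | – | fixed; batch 64 molecules, 60 epochs, patience 30 |

All of these are package-level engineering defaults: they are sized for
single-CPU training on the bundled benchmark and are recorded in the
training log.

**Global-to-local tradeoff.** The loss is
`w_local * mean((yhat - y)^2) + w_global * mean_molecules(g_m^2)` where
`g_m` is the residual of the reconstructed molecular quantity (total
charge vs 0 for `Q`; total electron count vs `sum(Z)` for `N_A`). With
`w_global = 0` it reduces exactly to the local loss. The molecular term
is label-free (it uses only known totals of neutral systems) and pushes
the model toward predictions whose sums respect the physics; properties
without a known molecular target (e.g. `delta` trained alone) must set
`w_global = 0` explicitly.

**Uncertainty.** For electron metrics the same sum rules give a
label-free reliability score per molecule: `|sum Q_hat|` (charge route)
or `|sum lambda_hat + sum delta_hat - sum Z|`. The acceptance suite
verifies that this score rank-correlates positively with the true
held-out error.

## The surrogate benchmark world

Reference QTAIM/IQA labels require quantum-chemical computation that is
out of scope here, so the package ships a generator of synthetic
molecules whose labels have the same *structure* as the real
descriptors and are exactly closed under the sum rules:

* **Geometries**: 4–9 atoms from a CHON pool (H/C/N/O at
  0.5/0.3/0.1/0.1), rejection-sampled in a cubic box of side
  `3 M^(1/3)` Angstrom with a 1.5 Angstrom minimum separation. A
  water-like H/O preset mirrors a cluster-energetics setting.
* **Charges**: exact electronegativity equalization — minimize
  `sum(chi_i q_i + eta_i q_i^2/2) + sum_{i<j} q_i q_j J(r_ij)` subject
  to `sum q = 0`, solved as a linear system. The Coulomb kernel is
  screened (Klopman–Ohno, `J = 1/sqrt(r^2 + 1)`): with a bare `1/r`
  kernel the equalization problem over-polarizes at bonding distances
  (charges above one electron, negative localization indices), the same
  pathology that motivates screening in practical QEq models.
* **Electron structure**: bond orders
  `delta_ij = s_i s_j exp(-(r_ij - r0_ij)/kappa)` (`r0_ij` the sum of
  covalent radii, `kappa` = 0.5 Angstrom, clipped to [0, 3] e),
  `N_A = Z_A - q_A`, `lambda_A = N_A - (1/2) sum_B delta_AB`. The
  electron-count sum rule holds by construction; parameters are chosen
  so `lambda >= 0` always (a violation is an error, never clipped).
* **Energies**: `E_inter = q_i q_j / r + a_ij exp(-2.2 r)` a.u. plus
  quadratic atomic self-energies; the exact additive total is stored in
  the record before any optional label noise, so the sum-rule residual
  of noisy labels is itself known. Default label noise is zero.
* **Trajectories**: a rigid CO2-like guest scripted against a static
  host with two amine-like groups. "Approach" events drive both the
  group–group delocalization (maximum) and the center-of-mass distance
  (minimum); "rotation" events keep the center of mass fixed up to a
  slow monotone drift while the guest tilts one terminal atom toward the
  group — an orientation-only contact that only the electronic metric
  can see. Ground truth: the closest-approach frame for approach
  events, the scripted orientation apex for rotation events.

What a green test does and does not establish: the surrogate labels are
smooth, low-dimensional functions of geometry (pair labels essentially
depend on `(Z_i, Z_j, r)`), far easier than DFT-level targets; passing
the recovery criteria shows the architecture, training loop and
bookkeeping are correct, not that the accuracy would transfer to real
quantum-chemical data. Conformational correlations, electronic
many-body effects and label noise of real reference data are not
emulated (noise can be switched on but defaults to zero).

## Numerical choices

* **Shifted softplus** `ln(0.5 e^x + 0.5)` everywhere, evaluated in a
  stable max/log1p form; its derivative is the logistic sigmoid.
* **Initialization**: seeded uniform fan-in; the representation seed
  also seeds the heads, so a model build is a pure function of its
  configuration.
* **Exact invariances vs floating point**: BLAS matrix kernels give
  results that depend on row position at the last-ulp level, which would
  silently break the advertised "exact" permutation consistency. The
  prediction path therefore evaluates single molecules in a canonical
  atom order (sorted by element, then by each atom's sorted distance
  profile), orients each pair descriptor canonically (lexicographic
  comparison of the two AE vectors) and sorts head inputs by content.
  Training skips this (it needs no bitwise guarantees) for speed.
* **Aggregation order**: neighbor messages are summed in a canonical
  (target, distance, element) order so the same physical molecule gives
  the same bits regardless of input labeling.
* **Event detection**: prominence-based strict local extrema on
  bin-averaged series (bin 20 fs, prominence 10% of the series range,
  minimum separation 50 fs, all adjustable); merging keeps the more
  prominent event, ties to the earlier one. Matching is greedy
  one-to-one nearest-time within ±10 fs. Detection on bin-averaged
  rather than raw series is a deliberate choice; both are reported by
  the CLI.
* **Degenerate inputs**: single atoms have no pairs (empty 2P arrays are
  valid); zero group delocalization yields an empty contribution table
  with a flag rather than an error; plateaus produce no events (strict
  extrema only).

## Known limitations

* Gas-phase, neutral, closed-shell systems only; no periodic boundary
  conditions, no three-body descriptors, no multi-property heads.
* The training loop is plain R (vectorized over precomputed molecule
  batches); it is sized for the bundled benchmark (minutes), not for
  production-scale datasets.
* Minibatches are a fixed seeded partition rather than reshuffled every
  epoch; this favors bit-reproducibility over a marginal optimization
  benefit.
* The closed-form diatomic charge used as an oracle has denominator
  `eta_1 + eta_2 - 2 J(r)`; with a bare Coulomb kernel this can vanish
  at short range — another reason the screened kernel is the default.

## A worked example

```{r, eval = FALSE}
library(localaim)

records <- generate_dataset(2000, surrogate_params(), seed = 42)
model <- train_local_model(records,
                           train_config("Q", "ElementalAIMwise", seed = 1),
                           rep_config(seed = 1))
evaluate(model, attr(model, "split")$test)
```

The acceptance criteria (sum-rule closure at 1e-10, exact invariances,
charge recovery to 0.02 e, delta recovery to 0.05 e, positive
uncertainty–error rank correlation, and end-to-end binding-event
detection within ±10 fs) are executed by
`tests/testthat/test-acceptance.R`; every number quoted above is
computed there, not here.
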