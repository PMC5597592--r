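---
title: "Comparing lipid conformational ensembles across resolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lipid conformational ensembles across resolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Atomistic (AA) and coarse-grained (CG) force fields describe the same lipid
at different resolutions: a CG bead lumps roughly four heavy atoms into one
interaction site. Whether a CG model is a faithful stand-in for an AA one is
a quantitative question with two parts: *which conformational motions
survive the loss of resolution at all* (a property of the atom-to-bead
mapping, independent of any force field), and *how similarly the two models
sample and traverse the surviving motions* (a property of the simulations).
`lipidens` implements the single-molecule analysis chain for both parts.

The analysis unit is the pooled single-molecule ensemble: every copy of the
lipid in every frame contributes one conformation, giving `K = N_L * T`
conformations of `N_p` particles. All statistics below operate on that pool.

## The analysis chain

**Superposition and the common reference.** Every analysis is preceded by
non-mass-weighted least-squares (Kabsch) superposition, with a reflection
guard so chirality is never mirrored. The reference is the fixed point of
iterated averaging: align to an arbitrary seed conformation, average,
re-align to the average, and repeat. We iterate until the average moves by
less than `conv_tol` (default 1e-8 Å, typically under a dozen passes)
rather than stopping after the minimal two passes, because the iteration
converges only linearly: at lipid-like mode amplitudes (leading variance
~9 Å² on an ~11-particle molecule) we measure a convergence rate of roughly
1/6 per pass, so two passes leave an O(1e-2 Å) dependence on the seed
conformation while the converged fixed point is seed-independent to ~1e-10 Å.
The two-pass variant remains available (`iterate_to_convergence = FALSE`).
Covariance matrices are frame-dependent, so the pipeline builds one
reference per representation from the first simulation in the roster and
aligns every later simulation to it; the bead-space reference is the mapped
AA reference.

**PCA.** The positional covariance `M` of the aligned pool (coordinates
flattened particle-major, divisor `K` rather than `K - 1`, so trace
identities and the projection-variance = eigenvalue identity are exact) is
eigendecomposed into orthonormal modes `e_k` with variances `E_k` (Å²),
sorted descending. Eigenvector sign is fixed by making the
largest-magnitude component positive; within a degenerate eigenvalue block
the resulting order is arbitrary and documented as such. For cross-model
comparison, eigenvalues can be normalized by the particle count, and joint
bases are built by pooling equally sized aligned ensembles — unequal frame
counts are an error, never a silent reweighting.

**Mapping algebra.** A mapping scheme is an `m x n` row-stochastic matrix
`w`: bead coordinates are `C = wA`, and displacement vectors map
componentwise per axis. Rows are normalized to sum to one on load; convex
weights are what guarantees (by Jensen's inequality) the bound on the
conservation ratio

    alpha = RMSD_cg / RMSD_aa <= 1,

the fraction of a collective motion's (weighted) RMSD that survives
coarse-graining. `alpha = 0` exactly on the mapping's kernel — the
intra-bead relative motions a CG model cannot represent. Uniform
hypothetical n:1 mappings (consecutive equal-weight blocks, last bead
absorbing any remainder) provide a resolution ladder; for nested uniform
ladders mean `alpha` over leading modes is provably non-increasing.
Two comparison routes exist between resolutions — map the trajectory then
run PCA, or run PCA then map the eigenvectors — and `map_covariance`
(`(w (x) I3) M (w (x) I3)^T`) is the exact bridge between them. Mapped
eigenvectors are generally *not* orthogonal; nothing in the package assumes
they are.

**Ensemble statistics.** Projection histograms (default bin width 0.1 Å;
bins aligned on multiples of the width so symmetric samples give symmetric
histograms) are Boltzmann-inverted to effective potentials
`E(x) = -kB T log P(x)`, reported in kBT or kJ/mol; empty bins are masked
`NA`, never ±Inf. Radial distribution functions come in an intermolecular
flavour (minimum-image distances, ideal-gas shell normalization so
`g(r) -> 1`, `r_max` capped at half the smallest box edge) and an
intramolecular flavour (same-molecule pair distances, unit-integral
density); default RDF bin width 0.2 Å. Neither bin width is prescribed by
the method; both are package defaults.

**Dynamics statistics.** `RMSD(tau)` averages the frame-pair RMSD over time
origins within each molecule copy and then over copies, with pairwise
superposition per frame pair (so diffusion does not contribute) unless
disabled. The normalized curve `NRMSD = RMSD / RMSD_eq` is fitted with the
power law `c1 * tau^c2` by ordinary least squares in log-log space,
restricted to `NRMSD < 0.7`; the fit region rule is part of the contract
and appending out-of-region points does not change the fit.
Projection autocorrelations are mean-removed and variance-normalized per
copy and averaged over copies (per-copy normalization prevents
high-variance copies from dominating); the per-lag sums are divided by the
number of valid origins `T - tau`, which makes `R(0) = 1` exact and matches
the time-average definition at every lag. The characteristic time is the
first crossing of `e^-2` (starting value taken as 1.0), linearly
interpolated between bracketing lags, or linearly extrapolated from the
last two computed lags when no crossing occurred — which two points anchor
the extrapolation is not prescribed by the method; we use the last two and
record `crossing_method`. A non-decaying autocorrelation yields `NA` with a
warning, never a silent number. Speedups between simulations are
eigenvalue-weighted geometric means of per-mode characteristic-time ratios,
`R(i,j) = exp(sum_k w_k log(tau_k^i / tau_k^j))` with `w_k = E_k / sum E`,
so `R(i,j) R(j,i) = 1` exactly. Unresolved modes are a hard error by
default; an `exclude` policy drops them and renormalizes the weights with a
warning.

## The synthetic world

The generator emulates what the analysis needs from pooled single-lipid
ensembles and nothing more: a deterministic two-tailed pseudo-lipid
topology (3 head + 2 x 4 tail particles by default, mirror-symmetric
tails), a few dominant orthonormal collective modes with prescribed
variances, stationary Ornstein-Uhlenbeck amplitude dynamics per mode (exact
discretization, so the analytic autocorrelation `exp(-tau/tau_OU)` holds at
every lag and the `e^-2` time is exactly `2 tau_OU`), isotropic noise in
the orthogonal complement, optional per-frame rigid motion per copy, and
`N_L` statistically independent copies.

Default parameters state the validation world once: planted variances
`(9, 4, 2, 1, 0.5)` Å² (a few dominant modes over a 0.05 Å² noise floor,
mirroring the dominant-few-modes structure of real lipid ensembles, where
four components carry about half the variance), relaxation times
`(50, 40, 30, 20, 10)` frames, `N_L = 16`, `T = 20000`. Planted modes are
drawn orthogonal to the six rigid-body directions of the base structure —
the physically correct statement of "internal collective mode"; without it
a random 33-dimensional vector carries ~18% rigid-body content that the
alignment stage removes, and recovered eigenvalues would be biased by
construction rather than by sampling. One master seed fans out to
deterministic per-copy substreams.

What the generator does **not** emulate — and therefore what a green test
does not establish: inter-molecular correlations (real PC1 densities can be
multi-modal through chain contacts with neighbours; a Gaussian-mixture
offset on mode 1 is available to exercise non-Gaussian density code, but it
is a caricature), solvent, any force field, bilayer packing, and
thermodynamics. Recovery tests certify the estimators, not the physics.

## Numerical choices and degenerate inputs

- Internal unit is Å everywhere; GRO nanometres are converted on read.
- Indices are 0-based in the data model, 1-based only at R's subscript and
  file-format boundaries.
- Pooling order is copy-major and fixed, so PCA is bit-reproducible and
  pipeline reruns produce byte-identical CSVs.
- Covariance eigenvalues marginally negative (above `-1e-8 * lambda_1`) are
  clamped to zero; anything more negative is an error.
- Kernel membership tolerance is 1e-10 relative.
- Collinear fit selections, zero displacement vectors, zero-variance
  series, empty selections and truncated files are errors with named
  context, not NaN factories.
- Binary XTC/DCD readers are not bundled (no R reader exists in the
  supported dependency set); multi-model PDB and a documented plain-text
  frame format cover trajectory exchange, and the synthetic generator emits
  GRO + text so synthetic data flows through the same readers as real data.
- The CLI exposes `run` (full pipeline from a YAML config) and `synth`
  (write a synthetic system); the remaining stages are exported functions
  rather than subcommands.

## Known limitations

- Cross-simulation correspondence is positional: comparing different
  molecules or atom orders is out of scope by design.
- The per-molecule unwrap heuristic assumes molecules smaller than half the
  box; there is no general PBC treatment.
- The shipped DOPC-style mapping file is illustrative (equal weights,
  schematic atom names), not a canonical published mapping.
- Autocorrelation characteristic times inherit the estimator noise of the
  ACF tail; at `T = 1e5` frames and `tau_OU <= 50` the recovery error is
  within 10% (this is tested), but much slower modes need proportionally
  longer series.
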