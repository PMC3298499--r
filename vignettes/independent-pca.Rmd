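---
title: "Independent PCA: model, algorithms and simulation benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Independent PCA: model, algorithms and simulation benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipca)
```

## The model

PCA summarises a centered samples-by-variables matrix $X$ ($n \times p$)
through its SVD, $X = U D V^\top$: the columns of $V$ are loading vectors,
and the principal components $U D$ are the projections of the samples onto
them. In omics data only a few variables genuinely drive a biological
process, so a *noiseless* loading vector should look super-Gaussian — a few
large weights, many near-zero ones. Estimation noise pushes loading vectors
toward Gaussianity instead.

IPCA denoises the loading vectors rather than the data or the scores. The
first $m$ loading columns $\tilde V$ are standardized and handed to
fixed-point FastICA as $m$ signals of length $p$; FastICA returns
independent loading vectors $S = W \tilde V^\top$ whose non-Gaussianity is
maximal under the chosen contrast. The independent principal components are
the projections $\tilde U = X S^\top$, and components are ordered by the
excess kurtosis of their loading vectors,
$\kappa = \mathrm{E}\{s^4\} - 3$ for a standardized signal. A sudden drop
in the kurtosis sequence marks the components that carry no non-Gaussian
structure; `kurtosis_drop()` reports it and `plot_kurtosis()` draws it.

The sparse variant (sIPCA) soft-thresholds each ordered independent
loading, $\hat s_k = \mathrm{sign}(s_k)(|s_k| - \gamma)_+$, with the
per-component threshold $\gamma_j$ induced from the user-facing *degree of
sparsity* `keepX` (the number of variables kept) as the
(`keepX`+1)-th largest absolute weight. Scores are then recomputed on the
sparse loadings, so noisy variables are removed from the components
themselves. Selections are exact (`keepX[j]` non-zeros) and nested as
`keepX` decreases.

## Algorithms and numerical choices

**FastICA** (`fast_ica()`) uses the logcosh contrast by default (`pow3`
available), symmetric decorrelation — so the unmixing matrix stays
orthogonal at every iteration and no component is privileged by extraction
order — and a seeded random orthogonal initialisation. Convergence is
`max | |diag(W_{new} W_{old}^\top)| - 1 | < tol` with defaults
`tol = 1e-6`, `max_iter = 1000`. Inputs are exactly re-whitened internally
(population moments); this guarantees the advertised invariants (source
rows with zero mean, unit variance, zero correlation) to float precision,
which merely approximately-white inputs cannot. Non-convergence is a
warning plus a flag, not an error: for Gaussian inputs the ICA model is
unidentifiable and the iteration may legitimately wander. `n_restarts`
reruns with consecutive seeds, aligns the runs by absolute correlation and
returns the most internally independent one (ties to the lowest seed);
because symmetric FastICA returns exactly decorrelated sources this
selection is nearly always the tie-break, and the default is a single run.

**Whitening scale.** The whitened PC matrix used by classical ICA is
$\sqrt{n-1}\,U$: for a centered matrix each column of $U$ has zero mean and
unit norm, so this scaling — not $n-1$ itself — gives unit sample variance.

**Classical ICA** (`ica_fit()`) whitens `n_whiten` PCs, unmixes them, and
orders ICs by their own kurtosis. For comparison against loading-based
methods each IC is mapped to the variable-space direction whose projection
generates it: since $\mathrm{IC}_j = X V_m D_m^{-1} w_j^\top \sqrt{n-1}$,
that direction is the unit-normalized $V_m D_m^{-1} w_j^\top$. This is the
exact analogue of "PC $j$ is generated by loading $v_j$" and of IPCA's
$\tilde U = X S^\top$. The $D^{-1}$ weighting amplifies noise directions,
which is precisely why high-dimensional ICA loading directions are
near-orthogonal to the planted eigenvectors in the benchmark below —
choosing instead $V_m D_m w_j^\top$ (the regression of the data on the IC)
produces moderate angles and does not reproduce the benchmark's
characteristic near-90° row.

**Sparse PCA** (`spca_fit()`) is sequential regularized rank-1 SVD with
soft-thresholding: alternate $u = Xv/\|Xv\|$ and
$v = \mathrm{soft}(X^\top u, \gamma(\texttt{keepX}))$, the threshold
refreshed every iteration from the order statistics so each iterate has
exactly `keepX` non-zeros; converge on the relative change of the loading
direction (`tol = 1e-6`, sign-invariant); deflate by projecting out the
score direction, $X \leftarrow X - u(u^\top X)$. Columns are standardized
to unit variance by default (`scale = TRUE`), the convention of the
reference implementations of this method family; IPCA and sIPCA operate on
centered, unscaled data. With `keepX = p` the method reproduces plain PCA
loadings.

**Sign convention.** Every reported loading column has its largest-magnitude
entry positive, removing SVD/ICA sign indeterminacy so outputs are
reproducible across runs.

**Ties.** `keepx_to_gamma()` breaks ties in absolute weight by keeping the
lower variable index. Under an exact tie the shrunken value of a kept entry
can be zero while the entry is still counted as selected; for continuous
data this is a measure-zero event.

## The simulation benchmark

`sim_design()` fixes the study conditions: $n = 50$ samples, $p = 500$
variables, covariance $\Sigma = VCV^\top$ with planted leading
eigenvectors $v_1, v_2$ (eigenvalues $c_1 = 400$, $c_2 = 300$) and all
remaining eigenvalues 1. Four regimes for the planted vectors:

* **gaussian** — i.i.d. $N(0,1)$ entries;
* **super_gaussian** — Laplace$(0, 25)$ on a 50-variable support
  (indices 1–50 for $v_1$, 301–350 for $v_2$), $U(0,1)$ elsewhere;
* **sparse_gaussian** / **sparse_super_gaussian** — $N(0,1)$ or
  Laplace$(0, 25)$ on the support, exactly zero elsewhere.

"Laplace(0, 25)" is read as location 0, scale $b = 25$; kurtosis is
scale-invariant, and any scale well above the $U(0,1)$ background gives the
same mixture behaviour, so results are insensitive to this reading. The
remaining eigenvectors are drawn with $U(0,1)$ entries and orthonormalized.
Because all trailing eigenvalues equal 1,
$\Sigma = I + (c_1 - 1) v_1 v_1^\top + (c_2 - 1) v_2 v_2^\top$ exactly —
the trailing eigenvectors cancel out of the covariance. `sim_dataset()`
exploits the same identity for $\Sigma^{1/2}$ to sample each dataset in
$O(np)$; `build_covariance()` still materializes the full $V$ (Householder
QR, which yields the same nested subspaces as Gram–Schmidt with better
numerical behaviour, signs fixed so the planted directions are preserved)
and the tests assert both the full spectrum and the rank-2 identity.

`run_replicates()` is the evaluation harness. Per replicate it samples a
dataset, fits the requested methods (sharing one SVD), and records:

* **angles** between planted eigenvector $j$ and the method's $j$-th
  loading vector, *matched by index* after each method's own ordering —
  variance order for PCA, kurtosis order for ICA/IPCA. Medians across
  replicates are reported.
* **loading kurtosis** of the first `ncomp_kurtosis` (default 5)
  components; means are reported. ICA whitens on the same number of
  components, consistent with reporting five of its loading vectors.
* **identification rates** for the sparse methods, with the two fitted
  components assigned to the two planted eigenvectors *by best fit*
  (smallest total angle). The planted eigenvalues 400 and 300 are close
  enough that at $n = 50$ their sample order swaps in roughly 16% of
  replicates; scoring by extraction index would make the rate distribution
  bimodal (standard deviations of 25–40 percentage points), whereas
  support recovery is a property of whichever component captures the
  process. Best-fit assignment restores unimodal rates with standard
  deviations of 4–9 points, matching how the selections behave per
  component. Angles deliberately keep index matching: the median is robust
  to the swaps, and the index convention is the one under which PCA's
  angle medians take their standard benchmark values.

FastICA inside the harness runs with `tol = 1e-4`, `max_iter = 200` and a
single restart — the simulation-scale settings of the method of record;
aggregation over thousands of replicates already averages out the
algorithm's stochasticity. All randomness derives from one master seed
(replicate $i$ uses stream `seed + i`), so reports are bit-reproducible.

## What the generator does and does not emulate

The generator produces multivariate-normal data whose *loading structure*
is non-Gaussian — it is the eigenvectors, not the samples, that are
Laplace-like. That isolates exactly the property IPCA targets and makes
recovery quantifiable against known ground truth. It does not emulate
heavy-tailed sample distributions, count noise, batch effects, variable
correlation beyond the two planted directions, or $n \gg p$ designs:
passing the benchmark shows the loading-denoising machinery works, not
that IPCA is preferable on any particular real dataset. For real data the
kurtosis-drop diagnostic and the Davies–Bouldin index
(`davies_bouldin()`, Euclidean distances over the chosen 2–3 components;
lower is better) are the intended guides.

## Problem sizes used in the shipped checks

The packaged tests reproduce the benchmark at 300 replicates per case,
where the Monte-Carlo error of the reported medians/means is a fraction of
the stated tolerances; `scripts/acceptance.R` reruns all four cases at the
full 5000 replicates. These sizes are the package's own choice of desk
scale: a full run completes in minutes on one core thanks to the rank-2
sampler and the shared per-replicate SVD.

## Known limitations

* In the Gaussian-eigenvector regime, ICA on loading vectors is
  unidentifiable; IPCA's first loading angle is large (the method fails,
  as it should). The *degree* of failure depends on the FastICA variant:
  this implementation and the current method-of-record implementation both
  give median angles near 45–55°, noticeably below older reports of ~70°.
  The kurtosis sequence in this regime (≈ 0.5, 0.2, 0.0, −0.2, −0.4) is
  reproduced almost exactly, so the discrepancy is confined to the
  unidentifiable rotation itself.
* A correctly converged rSVD-soft sparse PCA keeps its second component
  well separated after projection deflation: its dimension-2
  identification rates come out near the dimension-1 rates (~83–88%),
  not degraded to ~68–72% as historically reported for early
  implementations of this family. The qualitative claim that sIPCA beats
  sPCA on the second dimension is therefore not observed with this
  implementation; both recover the second process comparably well.
* Kurtosis-based ordering is sensitive to outliers in loading estimates;
  with several components of similar kurtosis the ordering between them is
  effectively arbitrary.
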