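---
title: "Detecting bifurcations in expression trajectories from covariance eigenstructure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bifurcations in expression trajectories from covariance eigenstructure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifurscan)
```

## The model behind the method

A differentiating cell population measured at one developmental moment can
be treated as a set of statistical replicates of the same underlying
dynamical system, fluctuating around a stable transcriptomic state. Two
assumptions make this tractable: the molecular dynamics are stochastic and
Markovian, and they run much faster (seconds–minutes) than changes in cell
fate (hours–days). Linearizing around the fixed point, the deviation
`X = G - g*` of the cell-by-gene matrix from its fixed point follows an
Ornstein–Uhlenbeck process governed by the Jacobian `J`, and its stationary
gene–gene covariance `C` solves the continuous-time Lyapunov equation

    J C + C J' + Q = 0,

with `Q` the noise covariance. Writing `C` in the Jacobian eigenbasis shows
that each covariance component scales like `-1 / (lambda_k + lambda_l)`. As
the leading Jacobian eigenvalue `lambda_d` approaches zero — the definition
of an approaching bifurcation — the `(d, d)` term dominates:

* the principal covariance eigenvalue `omega_1` diverges like
  `-1 / (2 lambda_d)`;
* the principal covariance eigenvector `s_1` converges, up to sign, to the
  Jacobian eigenvector of the slow mode — the *direction* of the
  bifurcation;
* pairwise Pearson correlations `R_ij` with nonzero loadings on `s_1`
  expand toward ±1.

All three statements are observable from expression data alone, with no
access to the generative model. `omega_1` and `s_1` come from a reduced SVD
of the centered matrix (`covariance_eig()`), never from forming the
gene-by-gene covariance.

Finite cell numbers regularize the divergence: `omega_1` stays finite but
is maximal, and the eigenvector correspondence is closest, at the
bifurcation. The analysis presumes cells are sampled near steady state;
strongly transient data void the equivalence.

## The simulated regulatory network

`grn_network()` / `grn_simulate()` implement the validation testbed: two
mutually inhibiting driver genes

    dg1/dt = -k_d g1 + m1 / (1 + g2^2)
    dg2/dt = -k_d g2 + m2 / (1 + g1^2)

plus `n_genes - 2` responders, each tied to one driver `d(i)` through an
interpolated activating/inhibiting Hill term with coupling
`alpha_i` in [0, 1]:

    dg_i/dt = -k_i g_i + m_d(i) (alpha_i g_d^2 + (1 - alpha_i)) / (1 + g_d^2).

The Hill exponent is 2. That choice is forced by two requirements we treat
as calibration anchors rather than free parameters: with `m1 = m2 = 1` the
symmetric state loses stability in a pitchfork exactly at `k_d = 0.5`
(`grn_critical()`, criterion `"eigenvalue"`), and with `m2 = 3`, `k_d = 1`
the saddle-node pair is balanced — symmetric double well, maximal
bimodality — exactly at `m1 = 3` (criterion `"balance"`). The second anchor
deserves a note: the balanced point is *not* an eigenvalue crossing. The
saddle-node turning points of this network sit near `m1 = 2.70` and
`m1 = 3.54`; what is special about `m1 = 3` is the symmetry of the two
wells, which is what makes the steady-state distribution bimodal and
`omega_1` maximal there. `grn_critical()` therefore exposes the two
criteria separately instead of pretending one bisection covers both.

Stochasticity is chemical-Langevin-like: each Euler step draws
`g(t + dt) ~ Normal(g + dt * drift, sigma)` clamped at zero, with
`sigma^2 = dt * (synthesis + degradation) / s` — variance proportional to
total reaction flux, one global noise scale `1/s` (default 0.05). The
corresponding Lyapunov noise intensity is the diagonal
`Q = (synthesis + degradation) / s` (`grn_noise_covariance()`), which is
what makes the simulator and the analytic machinery mutually consistent:
long-run single-cell fluctuations match `solve_lyapunov()` predictions
within sampling error (this is a tested invariant).

Defaults mirror the study conditions: 102 genes, 100 cells, `dt = 0.01`,
couplings drawn uniformly on [0, 1] (seeded), balanced driver assignment.
One deliberate scale-down: equilibration uses `n_steps = 2e4` (200 time
units) rather than the original `1e7`. The relaxation time is about
`1/k_d = 1` time unit, so 200 units is deep equilibration for every
statistic we compute; the full length remains reachable through the
parameter. Responder degradation rates are not printed anywhere we could
anchor to, so `k_i = 1`.

```{r pitchfork}
net <- grn_network(n_genes = 2, m1 = 1, m2 = 1)
grn_critical(net, "k_d", bracket = c(0.24, 5))$critical_value
```

## The Lyapunov solver

`solve_lyapunov()` uses Bartels–Stewart: a real Schur factorization of `J`
followed by blockwise back-substitution. The obvious alternative — solving
in the Jacobian eigenbasis, exactly as the theory is derived — fails
numerically in the one place we care about most: as `k_d` approaches 0.5
from above, the fast driver eigenvalue `-(k_d + c)` approaches −1 and
collides with the 100-fold responder eigenvalue, so the eigenvector basis
becomes nearly defective while the Schur basis stays orthogonal. The
brute-force Kronecker vectorization `(I ⊗ J + J ⊗ I) vec(C) = -vec(Q)`
serves as the independent oracle in the tests (dimension ≤ 10, agreement
to 1e-8).

```{r dominance}
net102 <- grn_network(n_genes = 102, m1 = 1, m2 = 1, seed = 5)
stability_scan(net102, "k_d", c(1, 0.8, 0.6, 0.52))
```

`omega_1` grows and the distance between the principal covariance
eigenvector and the slow Jacobian mode shrinks monotonically as the
pitchfork is approached — the eigenvector equivalence at work.

## The trajectory scan

`scan_trajectory()` is the pipeline for data: row-normalize cells, bin
along pseudotime, compute `omega_1` per bin, compare against a null, and
classify.

**Normalization.** Unit row sum by default; `"median-count"` and `"none"`
are available. For simulator output, where magnitudes are meaningful,
`"none"` is appropriate.

**Binning.** Cells sorted by pseudotime (ties broken by stable input
order) into bins of `bin_size` starting every
`round(bin_size * (1 - overlap))` cells; the last bin absorbs trailing
cells. 61,310 ranked cells with `bin_size = 1000` and 50% overlap give 121
bins with a 1310-cell tail — the layout used for real trajectories of this
size. Bin labels are 1-based.

**Null.** Within each bin, every gene column is permuted independently
across cells (20 replicates by default): per-gene marginals are preserved
exactly, gene–gene correlations are destroyed. The per-bin z-score
`(omega_1 - null_mean) / null_sd` is the detection statistic. Both data
and null curves are additionally reported min-shifted to zero, which is
how such curves are usually displayed.

**Classification** (`classify_transitions()`). Three signatures:

* *one-to-one spike* — isolated local maximum with `z >= 5` returning
  below `z = 2` within 5 bins on both sides; the saddle-node/maturation
  signature, where bimodality exists only at the transition moment;
* *one-to-many onset* — first bin of a run of ≥ 10 bins with `z >= 2` and
  nonnegative trend; the pitchfork/decision signature, where branch
  separation grows continuously from the root (so `omega_1` ramps rather
  than peaks, and only begins to rise at the bifurcation);
* *step-like* — a change-point between two flat plateaus at different
  levels, the signature of a noise-induced transition between coexisting
  states rather than a bifurcation. Checked only when no spike explains
  the curve, and suppressing onset calls when found (a step's upper
  plateau trivially satisfies the onset run criteria).

The thresholds are not taken from any published analysis — the original
identification was partly visual — so they are explicit, configurable
arguments, and the scan output always carries the raw z-scores alongside
the classification. The defaults were chosen once against the package's
own synthetic fixtures: planted saddle-node transitions at 10× effect are
detected and localized within ±2 bins, while correlation-free data stays
clean, both in ≥ 95% of seeded runs (tested).

**DNB.** For benchmarking, `dnb_order_parameter()` implements the standard
dynamical-network-biomarker composite
`I = SD_avg(DNB) × |PCC|_within / (|PCC|_cross + eps)` with `eps = 1e-6`
guarding the denominator. Unlike `omega_1`, it requires choosing the
biomarker gene set; with an informed set (drivers plus strongly coupled
responders, `|alpha - 0.5| > 0.25`) its maximum coincides with the
`omega_1` maximum on the simulated sweep, while random sets carry no
signal — which is precisely the argument for the eigenvalue statistic.

## Eigenvector analytics

Because `s_1` *is* the bifurcation direction at a transition,
`eigvec_series()` and friends turn it into an interpretable object:

* `eigvec_correlation_map()` — bin-by-bin Pearson correlations of the
  loading profiles; epochs sharing a direction appear as blocks, and block
  boundaries mark transitions. Raw (signed) loadings are correlated by
  default; absolute loadings are an option since sign conventions carry no
  mechanism.
* `project_cells()` / `projection_distribution()` — cells' coordinates
  along a direction; at a one-to-one transition the projection
  distribution widens and becomes bimodal. Bimodality is declared by a
  1-D two-vs-one-component Gaussian mixture comparison with
  `ΔBIC > 10` (a conventional strong-evidence cut; the original call was
  visual).
* `category_weights()` — per gene set, the mean *absolute* loading of its
  members (`W_c = mean |s_g|`). Absolute values because a direction's
  mechanism is sign-symmetric; a signed mean is available. Gene sets come
  from GMT files (`read_gene_sets()`).
* `fit_mixture_split()` / `propagate_labels()` — a two-component Gaussian
  mixture fitted in the bin's top-10 principal subspace with
  diagonal-family covariances (fitting in full gene dimension would be
  singular at these cell counts; the diagonal family, with the best member
  chosen by BIC, is far more robust to bad EM starts than a single
  flexible model). The fitted model then labels every cell in the
  trajectory, giving per-bin cluster compositions and per-cluster
  `omega_1` curves — the tool for separating pitchfork branches, where the
  pooled curve hides the per-branch signature.

## What the synthetic data does and does not show

Two generators stand in for real data. The GRN simulator produces the full
nonlinear phenomenology — bimodal steady states, correlation expansion,
driver–responder coupling recovery. `generate_fixture()` is simpler and
fully controlled: per-bin Gaussians with a planted rank-1 covariance
component along a known direction, whose magnitude follows the transition
class (delta, ramp, level shift, or absent). Planted ground truth makes
localization and calibration quantitative.

Neither generator reproduces the awkward parts of real single-cell data:
counts are not integer or sparse, there is no depth variation, no
dropout, no pseudotime estimation error, and genes outside the planted
structure are independent. Passing tests therefore demonstrate that the
statistics and the detection logic do what the theory says under the
model's assumptions — not that any particular real dataset will be as
clean. Results on real trajectories known to us were obtained at ~1000
cells per bin and tens of thousands of cells; the package's checks run at
desk scale (hundreds to thousands of cells, tens of genes), which the
fixture calibration reflects.

## Numerical choices, in one place

* Covariance uses the unbiased `n - 1` divisor.
* Eigen/singular vectors are sign-fixed (largest-magnitude loading
  positive); every comparison that matters is sign-invariant anyway
  (`eigvec_alignment()` minimizes over the sign).
* Zero-variance genes stay in matrices but are excluded (and counted) in
  correlation statistics; all-zero cells are a hard error in
  normalization.
* Fixed points come from 1-D reduction of the driver core plus bisection;
  at the pitchfork itself the reduced residual has a triple root, so the
  location is resolved only to about the cube root of the solver
  tolerance (the eigenvalue there is still resolved sharply).
* Bisection in `grn_critical()` stops at `|indicator| < 1e-8` or interval
  exhaustion; the k_d threshold lands within ~2e-8 of 1/2.
* Euler integration clamps at zero after sampling; with noise 0 the
  simulator is exactly deterministic and converges to the stable fixed
  point.
* Test problem sizes: unit tests use a 30-gene network with 4000-step
  equilibration and fixtures of 600–3000 cells; the acceptance checks run
  the full 102-gene, 100-cell, 2e4-step study conditions.

## Known limitations

* Pseudotime is consumed, never inferred; garbage ordering in, garbage
  trajectory out.
* The one-to-many (ramp) signature is intrinsically harder to separate
  from its null than a spike, mirroring how such transitions behave in
  real trajectories; the classifier exposes raw z-scores so borderline
  calls can be audited.
* The Jacobian is never inferred from data — the eigenvector equivalence
  identifies the slow direction, not the full regulatory matrix.
* `grn_critical(criterion = "balance")` requires a bracket inside the
  multistable window; the tracked asymmetry is discontinuous at the
  saddle-node boundaries.
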