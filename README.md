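# bifurscan

Detecting and characterizing bifurcations in high-dimensional expression
trajectories from the eigenstructure of the gene–gene covariance matrix.

## The problem

Single-cell transcriptomics shows differentiation as an apparently smooth
path through a myriad-dimensional gene space, yet the underlying biology is
a low-dimensional story of stable cell states that appear, split, and
vanish — bifurcations of a dynamical system. `bifurscan` is for
computational biologists and quantitative developmental biologists who
have a pseudotime-ordered cell × gene matrix and want to know *when* a
trajectory loses stability, *what kind* of transition it is (a one-to-one
maturation jump, a one-to-many decision, or a mere noise-induced state
hop), and *along which direction in gene space* it happens.

## The statistic at its core

Cells sampled at one developmental moment are statistical replicates
fluctuating around a stable state. If the molecular dynamics are Markovian
and fast relative to fate changes, the deviation matrix follows an
Ornstein–Uhlenbeck process and its stationary covariance `C` solves the
continuous-time Lyapunov equation

```
J C + C Jᵀ + Q = 0
```

with `J` the Jacobian of the (unknown) dynamics and `Q` the noise
covariance. Expanding `C` in the Jacobian eigenbasis, each component
scales as −1/(λ_k + λ_l). At a bifurcation the leading eigenvalue
λ_d → 0⁻, so:

* **ω₁**, the principal covariance eigenvalue, diverges like −1/(2 λ_d) —
  it spikes at a saddle-node and ramps from the root of a pitchfork;
* **ŝ₁**, the principal covariance eigenvector, equals the bifurcation
  direction (the slow Jacobian eigenvector) up to sign;
* pairwise Pearson correlations `R_ij` with nonzero loadings on ŝ₁ expand
  toward ±1.

All three are computable from data alone via a reduced SVD — no model
fitting, no gene preselection. The package implements this analysis
pipeline (binning, per-bin ω₁ with a gene-permutation null, transition
classification, eigenvector analytics, Gaussian-mixture branch splitting),
together with the stochastic two-driver toggle-switch regulatory network
used to validate it, its exact fixed-point/Jacobian/critical-parameter
machinery, and a Bartels–Stewart Lyapunov solver.

## Worked example

Plant a saddle-node-like transition in a synthetic trajectory, scan it,
and classify what was found:

```r
library(bifurscan)

fx <- generate_fixture(n_cells = 2000, n_genes = 30, n_groups = 20,
                       class = "one-to-one", effect = 10, seed = 3)
scan <- scan_trajectory(fx, bin_size = 100, overlap = 0.5,
                        normalize = "none", n_reps = 20, seed = 7)
scan
#> # A tibble: 39 × 9
#>     bin n_cells mean_pseudotime omega1 omega1_shifted null_mean null_sd
#>   <int>   <int>           <dbl>  <dbl>          <dbl>     <dbl>   <dbl>
#> 1     1     100           0.025   2.03          0          2.27  0.0917
#> 2     2     100           0.05    2.55          0.520      2.41  0.0974
#> 3     3     100           0.075   2.39          0.357      2.38  0.166
#> 4     4     100           0.1     2.28          0.243      2.27  0.120
#> 5     5     100           0.125   2.32          0.287      2.31  0.0962
#> # ℹ 34 more rows
#> # ℹ 2 more variables: null_mean_shifted <dbl>, z <dbl>

classify_transitions(scan)
#> # A tibble: 1 × 5
#>     bin class                z window_start window_end
#>   <int> <chr>            <dbl>        <int>      <int>
#> 1    19 one-to-one spike  131.           14         24
```

Away from the transition, ω₁ tracks the gene-shuffled null (z ≈ 0: the
bin-to-bin wiggles are what no gene–gene correlation looks like). At bin
19 — exactly where the rank-1 component was planted — ω₁ exceeds the null
by 131 standard deviations and returns to baseline within the window: the
one-to-one (saddle-node) signature. `eigvec_series()` then recovers the
planted direction, and `autoplot(scan)` draws the curve with its null
ribbon.

The driver core's exact critical point, found by bisection on the largest
Jacobian eigenvalue of the tracked symmetric state:

```r
grn_critical(grn_network(n_genes = 2, m1 = 1, m2 = 1),
             "k_d", bracket = c(0.24, 5))
#> <grn_critical> eigenvalue criterion: k_d = 0.49999998 (25 bisection steps)
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `sweep`, `critical`, `scan`, `eigvec`, `gmm`, `fixture`) ships
as a thin launcher:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bifurscan.R", package = "bifurscan"))')" \
    scan --matrix matrix.tsv --pseudotime pt.tsv --bin-size 1000 \
    --out scan.tsv --report report.json
```

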