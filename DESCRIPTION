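Package: bifurscan
Title: Bifurcation Detection in High-Dimensional Expression Trajectories
    via Covariance Eigenstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes bifurcations in pseudotime-ordered
    expression data from the eigenstructure of the gene-gene covariance
    matrix. Near a bifurcation the stationary covariance of a noisy dynamical
    system, given by the continuous-time Lyapunov equation, diverges along
    the slowest Jacobian eigenvector; the principal covariance eigenvalue
    therefore spikes (one-to-one transitions) or ramps (one-to-many
    decisions) and the principal covariance eigenvector equals the
    bifurcation direction up to sign. The package provides a stochastic
    two-driver toggle-switch gene-regulatory-network simulator with
    fixed-point, Jacobian and critical-parameter analysis; a Lyapunov-
    equation solver and covariance eigendecomposition utilities; a
    pseudotime binning and scanning pipeline with a gene-permutation null,
    transition classification and the dynamical-network-biomarker index;
    eigenvector analytics (correlation maps, projections, gene-set weights,
    Gaussian-mixture splitting); and readers/writers for MatrixMarket,
    dense TSV, pseudotime tables and GMT gene sets, plus a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
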