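Package: linkinf
Title: Fisher's Infinitesimal Model with Genetic Linkage on a Circular Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic and Monte-Carlo machinery for directional selection in
    Fisher's infinitesimal model when the infinitely many loci lie on a single
    continuous circular chromosome. Implements the Fourier-space variance
    recursion for the selection-recombination cycle (selection reset of the
    genetic-value mode followed by a heavy-tailed diffusion over modes), its
    numerical iteration with analytic tail closure and FFT convolution, the
    exact no-linkage multi-Gaussian baseline (Bulmer covariances and release of
    genetic variance), a seeded forward gamete simulator with the two-crossover
    recombination operator, scaling-law analysis of the aging decay of the
    genetic variance, and a command-line interface for reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    MASS,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
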