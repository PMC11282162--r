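Package: qnetdist
Title: Hierarchical ECDF Distances Between Stochastic Queuing Models and
    Sparse Time-Series Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparison of stochastic model outputs with
    sparse, unpaired, time-evolving experimental samples.  Provides a
    discrete-event simulator of a closed queuing network describing
    insulin-regulated GLUT4 vesicle recycling (endosome store,
    finite-capacity FIFO microtubules, insulin-gated fusion sites, plasma
    membrane), in-silico protocols for transition and uptake experiments,
    two-sample ECDF point metrics (Kolmogorov-Smirnov, Wasserstein-1,
    Kuiper, Cramer-von Mises, Anderson-Darling, signed and squared area),
    a three-level hierarchical distance aggregating point metrics over
    time courses and experiments, synthetic-data generation with relative
    Gaussian or uniform noise, re-sampling robustness studies, and
    distance-landscape mapping over parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
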