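Package: spurnet
Title: Finite-Sample Effects and Tailored Null Models for Interaction Networks
    Derived from Multivariate Time Series
Version: 0.1.0
Authors@R:
    person("spurnet", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Derives unweighted interaction networks from multivariate time
    series by thresholding pairwise signal interdependence (absolute
    correlation and maximum absolute cross-correlation), computes the usual
    small-world statistics (clustering coefficient, average shortest path
    length with the finite-path convention, connected components, degree
    distributions), and exposes the spurious network properties induced by
    finite series length and low-frequency content.  Provides the analytic
    finite-sample theory (effective length, asymptotic edge density),
    Monte-Carlo estimators of edge density and clustering for independent
    processes, and two tailored random-network null ensembles (mean-spectrum
    filtered noise and per-channel IAAFT surrogates) for normalizing
    time-resolved network analyses of multichannel recordings.  A
    synthetic-data module generates white noise, moving-average filtered
    noise, spectrum-filtered noise and a seizure-like multichannel emulator
    with scheduled band powers and cross-channel coupling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
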