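Package: hetmicro
Title: Heterogeneous Layer 2/3 Cortical Microcircuit Simulation and
    Processing Capacity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates a data-constrained spiking model of a layer
    2/3 cortical microcircuit with three neuron classes (excitatory pyramidal
    cells, fast-spiking and non-fast-spiking interneurons) and nine
    conductance-based synapse types (AMPA, NMDA with magnesium block, GABA-A,
    GABA-B). Neuronal, synaptic and structural heterogeneity can be toggled
    independently: parameter distributions for single-cell physiology,
    lognormal synaptic weights and delays, skewed degree distributions and
    pre/postsynaptic weight correlations. Includes an analysis stack for
    population activity (spike-train statistics, excitation/inhibition
    balance, intrinsic timescales, effective membrane time constants, rate
    transfer functions) and for reservoir-computing style information
    processing capacity (linear memory curves and total capacity over
    products of Legendre polynomials of the delayed input).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
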