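Package: adaptfrac
Title: Multi-Timescale Neural Adaptation, Fractional Dynamics, and Field-Potential Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models linking spike-frequency adaptation and short-term synaptic
    depression to fractional dynamics and to the shape of LFP/EEG power
    spectral densities. Provides closed-form high-pass/low-pass filter
    cascades for adaptation, fractional-order operators and constant-phase
    fits that map adaptation timescales to a fractional differentiator, a
    conductance-based Hodgkin-Huxley neuron with slow AHP currents driven by
    exponentially filtered noise, two-timescale depressing synapses, and a
    feedforward population whose summed filtered synaptic output serves as an
    LFP proxy analyzed with Welch spectral estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
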