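Package: mnm
Title: Mechanistic Neural Mass Models Derived from Conductance-Based Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mechanistic neural mass models whose firing-rate response,
    depolarization-block transition and extracellular-potassium sensitivity are
    parametrized from Hodgkin-Huxley-type single-neuron models rather than assumed
    sigmoidal. Includes the Wang-Buzsaki interneuron and a single-compartment
    accommodating excitatory neuron derived from the Pinsky-Rinzel pyramidal cell;
    fixed-point and Jacobian eigenvalue analysis of the firing-onset and
    depolarization-block bifurcation boundaries as functions of the potassium Nernst
    potential; polynomial parametrization of the boundaries and of the time-averaged
    firing rate, membrane potential and transmembrane potassium flux; alpha-function
    synaptic dynamics; integration of a coupled excitatory-inhibitory mass network
    with hysteresis detection; and analytic regime boundaries (not-firing, firing,
    bistable, runaway excitation, depolarization block) in injected-current,
    potassium and coupling space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
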