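Package: tmesim
Title: Hybrid Agent-Based Simulation of Tumour-Immune Dynamics and Combination Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale hybrid simulator of the tumour microenvironment: a 3D
    on-lattice agent-based model of cancer cells, immune effector cells and
    immune suppressor cells, coupled to an explicit finite-difference oxygen
    reaction-diffusion field and deterministic pharmacology modules (PD1
    antibody receptor occupancy, modified linear-quadratic radiotherapy with
    oxygen modification, K/PD docetaxel chemotherapy with resistance, and an
    Emax DNA-damage-response inhibitor). Stochastic cell events are driven by
    an exact Gillespie algorithm whose propensities follow population counts
    and cumulative-kill counters; mono- and combination-therapy regimens
    (Q3W, weekly, fractionated) are compiled into dose schedules. Outputs are
    cell-count and cell-cycle-phase time series, event logs, rate traces and
    spatial snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
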