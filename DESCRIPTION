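Package: puffr
Title: Hybrid Stochastic-Deterministic Simulation of IP3-Driven Calcium Puffs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates localized calcium release events (puffs) from clusters
    of IP3 receptors in discretized 2D/3D cell geometries. IP3 and calcium
    concentration fields evolve deterministically (diffusion with no-flux
    boundaries, photorelease source terms, SERCA uptake and ER leak) while
    cluster gating follows a four-state stochastic scheme with an
    IP3-dependent opening propensity. Provides first-puff latency statistics
    (mean and minimal first-puff latencies, interevent intervals, exponential
    fits), a buffered effective-diffusion calculator, calibration of the
    photorelease rate from latency targets, and grid-search estimation of the
    effective IP3 diffusion coefficient from latency-versus-distance data,
    together with synthetic-data generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
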