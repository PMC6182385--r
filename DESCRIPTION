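Package: frrfit
Title: Single-Turnover Fluorescence Analysis for Fast Repetition Rate
    Fluorometry
Version: 0.1.0
Authors@R:
    person("frrfit", "maintainers", email = "frrfit@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and nonlinear least-squares fitting of
    fast repetition rate fluorometry (FRRf) single-turnover chlorophyll
    fluorescence transients from photosystem II (PSII). Estimates minimal
    and maximal fluorescence (F0, FM), the effective absorption cross
    section for PSII photochemistry (sigma_PSII), excitonic connectivity
    (rho) and biexponential QA- reoxidation lifetimes (tau1, tau2) from
    flashlet-train induction and relaxation curves; derives photochemical
    quenching (qP), the quantum-yield partition Y(PSII) + Y(NPQ) + Y(NO) = 1
    and absolute electron transport rates per PSII; assembles non-sequential
    rapid light curves and induction-recovery experiments from paired
    in-light and post-illumination dark measurements; and ships a seeded
    synthetic-experiment generator that emulates rapid photoacclimation
    dynamics (time-dependent Y(NPQ) induction, sigma_PSII' decline, tau1
    acceleration) so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
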