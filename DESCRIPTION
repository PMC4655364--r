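Package: relaxfit
Title: Backbone NMR Spin-Relaxation, Model-Free and CPMG Dispersion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for protein backbone 15N relaxation analysis:
    mono-exponential fitting of R1/R2 intensity decays and steady-state
    heteronuclear NOE ratios, Lipari-Szabo model-free analysis with
    isotropic or axially symmetric rotational diffusion (staged M1-M5
    model selection with Monte Carlo errors), Carr-Purcell-Meiboom-Gill
    (CPMG) relaxation dispersion analysis with a numerical Bloch-McConnell
    two-state propagator and the Carver-Richards closed form (per-residue
    and clustered global fits at two static fields), and pH-titration
    chemical-shift-perturbation tracking with peak-status bookkeeping.
    Includes seeded synthetic-data generators that emulate the
    experimental designs the fitters assume, for end-to-end parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
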