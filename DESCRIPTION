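Package: hipfxsim
Title: In-Silico Hip-Fracture Risk and Hip-Protector Trials from Surrogate Fall Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the probability of hip fracture given a fall
    (P_Fx) for virtual subjects and for running in-silico randomized trials of
    hip protectors. A Gaussian-process surrogate with an uncertainty-targeting
    acquisition rule reconstructs a subject's critical-velocity curve (the
    minimum impact speed producing a 10 mm fracture length at each fall angle)
    from a small budget of fall-simulation calls; a probabilistic
    fall-configuration model (angle-segment masses, truncated-normal impact
    speed, hip-impact scaling) converts the curve into P_Fx with and without a
    hip protector; cohort-level statistics cover relative risk, compliance
    adjustment, risk classification against FRAX, agreement and
    reclassification metrics, odds ratios and power-based sample size. A
    parametric synthetic cohort and fracture-length oracle stand in for
    finite-element fall simulations so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
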