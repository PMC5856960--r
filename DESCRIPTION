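Package: caahemo
Title: Reduced-Order Hemodynamics of Coronary Artery Aneurysms in Kawasaki Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational analysis of coronary artery aneurysm (CAA)
    hemodynamics in Kawasaki disease. Provides parametric aneurysm morphing of
    centerline-parameterized vessel lumens, a closed-loop lumped-parameter
    network (LPN) of the left heart, systemic circulation and coronary outlet
    beds with intramyocardial pressure coupling, deterministic tuning of the
    LPN to clinical targets, and shear-based thrombotic-risk metrics computed
    from the pulsatile coronary flow under a quasi-steady Poiseuille closure:
    time-averaged wall shear stress (TAWSS), low-WSS surface-area fractions,
    oscillatory shear index (OSI) and a volume-turnover residence-time
    surrogate. Includes a synthetic-data module that generates the virtual
    aneurysm cohort, plausible clinical targets and fixture flow waveforms, and
    a config-driven pipeline that reproduces the cohort experiment and its
    aspect-ratio versus wall-shear-stress trend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
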