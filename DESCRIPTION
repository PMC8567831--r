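Package: fnmorph
Title: Mesoscopic Morphospace and Configural Breadth of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how functional brain networks reconfigure across cognitive
    states. Each a-priori community of a weighted functional connectome is modelled
    as the transient set of an absorbing (terminating) Markov chain, yielding two
    mesoscopic coordinates: trapping efficiency (the L2 norm of the mean time to
    absorption over the community's total exiting strength) and exit entropy (the
    normalized Shannon entropy of the preferential exit distribution). Per-subject
    task coordinates span a 2D morphospace in which functional reconfiguration is
    the area of the task convex hull and functional preconfiguration is the distance
    from the resting-state point to the task centroid. Includes one-way intraclass
    correlation sensitivity analyses with permutation nulls, iterative multilinear
    models of behavior with cross-validated specificity, a synthetic cohort
    generator with planted subject- and task-level effects, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
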