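Package: whorlpos
Title: Positioning of the Lateral-Organ Initiation Zone at the Shoot Tip
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Steady-state reaction-diffusion model of apical (HD-ZIP III) and
    basal (KANADI) expression domains patterned by an exponential precursor
    gradient on the one-dimensional distance-from-tip axis, with extraction of
    the H-K interface position and the permissive trough for primordium
    initiation. Includes closed-form positioning theory for source-diffusion-
    decay gradients (decay constant, dosage factor), whorl geometry converting
    interface position and inter-cotyledon spacing into cotyledon number,
    morphometric regressions on embryo measurement tables, a seeded synthetic
    embryo-population generator, and a catalog of perturbation scenarios
    covering the documented HD-ZIP III/KANADI experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
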