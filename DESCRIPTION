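Package: cibalance
Title: Cortical Balance Analysis for Sequential Bilateral Cochlear Implantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses auditory-evoked EEG recorded from users of
    sequential bilateral cochlear implants. Provides a synthetic multichannel
    evoked-potential generator with known ground truth (cortical sources,
    implant stimulus artifact, sensor noise), the standard sensor-space
    pipeline (band-pass filtering, epoch rejection, common average reference,
    global field power, component detection), an artifact-suppressing
    minimum-variance beamformer on an analytic three-shell spherical head
    model with pseudo-Z activation maps and an omnibus significance threshold,
    normalized hemispheric balance indices (cortical lateralization, cortical
    representation of input, bilateral enhancement, normalized bilateral
    speech benefit), and longitudinal linear mixed models with estimated
    marginal means and Tukey-corrected contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    optparse,
    pbkrtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
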