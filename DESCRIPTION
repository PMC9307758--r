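Package: ctanomaly
Title: Generative Anomaly Detection and Worklist Triage for Head CT
Version: 0.1.0
Authors@R:
    person("CT Anomaly Contributors", email = "ctanomaly@example.org",
           role = c("aut", "cre"))
Description: Unsupervised emergency triage of non-contrast head CT scans with
    a style-based deep generative model trained only on normal images.
    Provides a seeded synthetic head-CT phantom generator with injectable
    lesions, a scale-configurable style-based generator/encoder/discriminator
    with two-phase adversarial training, GAN inversion with Gaussianized
    latent-space regularization and masked noise optimization, a
    slice-order-normalized anomaly score, ROC/Youden threshold tuning with
    bootstrap confidence intervals, and a randomized-crossover worklist
    triage simulation with radiological time metrics (wait time, turnaround
    time, reading time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
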