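Package: adaptmol
Title: Few-Shot Generative Domain Adaptation for Molecular Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Latent-space molecule generation under few-shot supervision.
    A Wasserstein GAN with gradient penalty is pre-trained on latent vectors
    of a large molecule pool, then adapted to a small set of reference drugs
    by training only a lightweight affine "molecule adaptor" on the
    generator's input noise (plus the last layers of the critic). The
    adapted model generates molecules with desired structures (aromatic
    ring counts, halogenation) or properties (QED, penalized logP), which
    are scored with Tanimoto-fingerprint diversity, uniqueness and quality
    metrics. Ships a deterministic descriptor-based latent codec and a
    synthetic molecule library so the full pipeline runs and is testable
    without external model weights or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
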