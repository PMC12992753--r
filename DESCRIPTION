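Package: mptlineup
Title: Multinomial Processing Tree Models for Eyewitness Lineup Responses and Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A multinomial processing tree (MPT) modelling engine with
    maximum-likelihood fitting by G-squared minimization, nested
    likelihood-ratio tests, order-constraint (shrinkage)
    reparameterization, and parameter-recovery simulation. On top of the
    engine, the package provides the two-high-threshold (2HT) eyewitness
    identification model and its extension to confidence ratings, the
    lineup confidence model, in which low, moderate and high confidence
    are measured conditionally on the latent process (detection, biased
    suspect selection, guessing-based selection, guessing-based
    rejection) that generated a lineup response. A bundled frequency
    table from a large post-identification feedback experiment allows the
    complete model-based analysis to be reproduced from the package
    alone. Models can be exchanged with other MPT software via the EQN
    text format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
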