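Package: lesionsim
Title: Lesion Simulation and Resilience Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds binarized functional connectivity graphs from regional
    BOLD time series across a proportional-density sweep, quantifies network
    resilience as global efficiency after simulated attacks (serial random,
    serial degree-targeted, and clinically representative lesion node sets),
    and runs longitudinal group inference (linear mixed models with
    Satterthwaite degrees of freedom, paired and two-sample t tests with
    Benjamini-Hochberg correction, and the wiring-cost versus resilience
    rank correlation). Includes a synthetic-cohort generator with planted
    longitudinal effects so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
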