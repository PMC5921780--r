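Package: MoranMicrobiome
Title: Neutral Short-Term Microbiome Dynamics Under a Moran Host Genealogy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based forward-time simulator of host-associated microbiome
    dynamics within a single host generation. A Moran birth-death process over
    a constant host population is coupled to neutral microbe recruitment from
    parents and from a local environment assembled from fixed and pooled
    components, with host subpopulation (deme) structure and binomial host
    migration. Includes a truncated multivariate-normal initializer for
    realistic starting communities, Shannon and Bray-Curtis alpha/beta/gamma
    diversity partitioning, and replicate and parameter-sweep drivers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, MASS, yaml, jsonlite
Suggests: testthat (>= 3.0.0), vegan, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
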