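Package: silacdyn
Title: Pulsed-SILAC Proteome Dynamics: Turnover Rates, Incorporation
    Kinetics and Temporal Profile Clustering
Version: 0.1.0
Authors@R:
    person("PCT", "Pipeline Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for pulse-SILAC (stable isotope labeling by
    amino acids in cell culture) proteome dynamics experiments, from
    MaxQuant-style protein-groups quantification tables to heavy-label
    incorporation kinetics. Implements quality filtering of protein groups,
    union of biological replicates with confidence classes, temporal binning
    and within-bin quartile ranking, closed-form through-origin estimation of
    first-order protein turnover rates and half-lives from H/L ratio time
    courses, hierarchical (Ward) clustering of complete incorporation
    profiles with time-to-50%-incorporation, heavy-channel iBAQ absolute
    quantification backed by an in-silico Lys-C digest, Fisher exact
    over/underrepresentation tests with Benjamini-Hochberg false discovery
    rate control, and a synthetic-data generator with known ground truth
    emulating near-arrested (persistence) and rapidly resuming
    (resuscitation) labeling regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
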