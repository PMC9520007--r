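Package: scpdyn
Title: Subcellular Process Networks and Vesicle-Transport Dynamics of
    Neurite Outgrowth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for identifying subcellular-process (SCP)
    networks that drive receptor-stimulated neurite outgrowth.  Provides a
    leveled cell-biology ontology container with horizontal (same-level)
    SCP interactions, differential expression and proteomics filtering
    rules, standard and dynamic (combination-based) Fisher enrichment with
    SCP-network construction, quantification and statistics for neurite
    outgrowth fluorescence intensity profiles (including Dixon's Q outlier
    screening), a compartmental ordinary differential equation model of
    vesicle transport during outgrowth together with its analytical
    steady-flux solution and feasibility scan, and seedable synthetic-data
    generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    fgsea,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
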