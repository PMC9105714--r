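Package: gagstack
Title: Dye Stacking and Glycosaminoglycan Contact Analysis for Coarse Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the association of the cationic phenothiazine
    dye methylene blue (MB) with glycosaminoglycan (GAG) decasaccharides from
    multi-frame coordinate trajectories. Provides coarse geometric models of
    seven GAG sulfation presets (heparin, desulfated heparin, chondroitin
    4-/6-sulfate and three heparan sulfates), a synthetic trajectory generator
    with scripted ground truth and a rigid-body Metropolis Monte Carlo mode,
    detection of pi-pi stacks with parallel/antiparallel orientation
    classification, anionic-site contact fractions at a distance cutoff,
    the sulfation-dependence statistic D = n_MB * t / n_SO3, and MM-GBSA
    energy-component bookkeeping (frame filtering, per-drug normalization,
    additivity checks) with a transparent surrogate pair-energy scorer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    igraph,
    readr,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d,
    withr
Config/testthat/edition: 3
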