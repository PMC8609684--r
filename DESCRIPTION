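Package: stereovasc
Title: Design-Based Stereology of Brain Microvascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for design-based stereology of
    brain microvascular networks. Generates layered reference volumes and
    seeded random capillary networks with exactly known ground truth
    (including a transgenic amyloid-pathology phenotype with reduced dentate
    gyrus capillary length and thin hair-like vessels near plaques), sections
    them virtually with systematic-uniform-random sampling, and places the
    classical stereological probes: Cavalieri point grids for volume, optical
    disectors with guard zones for Euler-number capillary counting, and
    isotropic sphere probes (space balls) for length. Turns probe counts into
    totals, densities, mean capillary length, Krogh-type diffusion distances
    and Gundersen coefficients of error, and reproduces the nonparametric
    between-/within-group comparison protocol (exact Mann-Whitney, Friedman
    with Wilcoxon signed-rank post-hocs, Spearman correlation) used in
    stereological cohort studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
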