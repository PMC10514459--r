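Package: foundersim
Title: Forward Simulation of Island Founder Events and Genome-Erosion Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based, age-structured (non-Wright-Fisher) forward
    genetic simulation of island founding, bottleneck and recovery scenarios
    with explicit diploid genomes, a gamma distribution of fitness effects and
    dominance tied to selection strength, together with the population-genomic
    statistics used to study genome erosion in small populations: runs of
    homozygosity (PLINK-parameterised sliding-window detection and F_ROH),
    direct heterozygosity, a recombination-clock dating of inbreeding events,
    realized and masked genetic load, per-impact-category deleterious variant
    counts, and the R_xy derived-allele-frequency statistic with intergenic
    standardisation and block-jackknife variance. Includes a synthetic-data
    generator producing annotated multi-population VCF fixtures with planted
    homozygous tracts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
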