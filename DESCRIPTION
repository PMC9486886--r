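Package: polypaint
Title: Allele-Dosage Chromosome Painting and Reproduction Simulation for
    Polyploid Hybrid Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the parental composition of chromosomes in triploid
    hybrids of the Carassius (goldfish/gibel carp) complex from
    lineage-diagnostic SNPs: filtering of effective loci, windowed
    allele-frequency dosage genotyping, recombination-breakpoint detection,
    parental chromosome-set attribution across generations, and native
    identity-by-state similarity. Includes a forward simulator of the
    reproduction system (amphitetraploid meiosis with 1-2 crossovers per
    bivalent, sexual fertilization, ameiotic gynogenesis with unreduced
    eggs) and of short-read allele counts with depth, base error and
    reference-mapping bias, so every inference stage is verifiable against
    simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
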