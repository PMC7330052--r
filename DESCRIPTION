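Package: tetragamete
Title: Inheritance Analysis of Diploid Gametes from Tetraploid Meiosis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse the meiotic behaviour of an allotetraploid
    (doubled-diploid) parent from the allele doses observed in its triploid
    progeny. Diagnostic-SNP dose matrices (0/1/2 doses of one ancestral
    allele) are converted to diploid-gamete genotypes, from which the package
    estimates parental heterozygosity restitution, preferential pairing,
    the tetrasomic fraction and double reduction by maximum likelihood,
    tests markers for segregation distortion, profiles interspecific
    recombination via graphical genotypes, builds a simplified tetraploid
    linkage map (pairwise recombination fractions under random pairing,
    LOD grouping, MDS ordering, Kosambi distances, Marey diagnostics), and
    clusters gametes with neighbor-joining trees. A tetraploid meiosis
    simulator for duplex x nulliplex crosses provides synthetic gamete,
    dose and two-channel fluorescence data for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
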