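Package: ChimeraPopGen
Title: Population Genetics of Chimeric, Mixoploid Algal Blades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of multi-allele
    microsatellite genotypes from chimeric, mixoploid gametophytic blades
    (Bangiaceae-type life cycles), where allele dosage and the ploidy of
    the genotyped tissue are unknown. Genotypes are recoded under assumed
    ploidy levels (2x, 4x, 8x) by seeded within-individual allele
    subsampling; allele frequencies are estimated by an EM maximum
    likelihood correction for unknown dosage; gene diversity, effective
    number of alleles, Nei's Gst, Jost's D, principal components, and a
    four-level hierarchical AMOVA (F_IT, F_IS, F_SC, F_CT) are computed
    under each assumed ploidy and compared. Includes a forward simulator
    of chimeric blade genotypes and maternally inherited cpDNA with known
    structure truth, Evanno delta-K model selection on clustering run
    logs, and cpDNA haplotype collapsing with minimum-spanning mutation
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
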