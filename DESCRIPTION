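Package: popmeth
Title: Population Diversity Scans and Allele-Specific Methylation Analysis
    for Candidate Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Joint genetic and epigenetic analysis of a candidate locus:
    nucleotide diversity, Watterson's theta and haplotype diversity from
    aligned haplotype panels; Tajima's D, Fu and Li's D*/F* and Fay and Wu's
    H neutrality tests; Hudson's Fst, net-distance breed trees and sliding
    window diversity/differentiation scans with a Z-test outlier screen;
    per-CpG bisulfite and MeDIP methylation quantification with group
    comparisons; chi-square differential-methylation-site calling; and
    allele-specific methylation region detection from phased bisulfite
    reads.  Includes coalescent, Balding-Nichols and bisulfite-read
    simulators with known truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    vcfR,
    yaml
Suggests: jsonlite, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
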