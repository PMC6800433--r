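Package: autozyg
Title: Runs of Homozygosity, Inbreeding-Tract Dating and Local Ancestry
    from Diploid Consensus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genomic inbreeding analysis from per-individual
    diploid consensus sequences encoded with IUPAC ambiguity codes.
    Computes windowed and genome-wide heterozygosity, segments genomes
    into runs of homozygosity (ROH) with a two-state hidden Markov model
    with Poisson emissions and callable-site exposures, dates ROH tracts
    in generations via g = 100/(2rL), quantifies pairwise IBD-ROH
    sharing, classifies tract ancestry in admixed genomes with a
    three-state HMM over ancestry-diagnostic sites, and dates
    mitochondrial splits with a molecular clock. Includes a pedigree
    simulator with crossovers at a stated cM/Mb rate that emits
    ground-truth autozygosity and ancestry tracts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
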