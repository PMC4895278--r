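Package: asequant
Title: Allele-Specific Isoform Expression from RNA-Seq with Diploid
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simultaneous estimation of isoform abundances and
    allele-specific expression (ASE) from RNA-Seq reads aligned to a
    personal diploid (paternal plus maternal) transcriptome.  A Bayesian
    generative model treats the isoform choice, haplotype choice and
    start position of every read as latent variables and fits Dirichlet
    and Beta posteriors by variational coordinate ascent, so that the
    paternal/maternal ratio of each isoform is Laplace-smoothed by its
    Beta prior instead of being read off raw heterozygous-SNP counts.
    Includes a quality-score dependent read likelihood with indel
    support, a best-alignment baseline comparator, ASE calling with the
    usual 0.75/0.25 thresholds, and a paired-end read simulator with a
    toy seed-and-extend aligner for end-to-end validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    graphics,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
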