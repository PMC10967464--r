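Package: haploscan
Title: Bulked Segregant Mapping from Pooled Sequencing of Haploid Drones
Version: 0.1.0
Authors@R:
    person("Robin", "Hartley", email = "robin.hartley@example.org",
           role = c("aut", "cre"))
Description: Maps a Mendelian locus from pooled whole-genome resequencing of
    phenotype-sorted haploid honeybee drones. Implements a per-SNP Euclidean
    distance statistic between the nucleotide-frequency vectors of a mutant and
    a wild-type pool, a power transform and locally weighted (Lowess) smoothing
    of the genome-wide scan, quantile thresholding and candidate-region
    calling, variant-consequence annotation against gene models, per-individual
    allele-frequency filters for candidate genes, coding-consequence prediction
    for indels (frameshift and premature stop detection with protein-domain
    overlap), and the contingency-table statistics used to score cross
    segregation and RNA-interference phenotype outcomes. Ships a forward
    simulator of a haplodiploid single-queen cross (recombinant haploid
    gametes, phenotype pooling, finite-depth pooled sequencing with base-call
    error) that writes VCF/GFF3/FASTA/TSV truth sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
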