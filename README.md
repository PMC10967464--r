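# haploscan

Bulked segregant mapping from pooled sequencing of haploid honeybee drones.

## The problem

Honeybee drones are haploid — every drone is one recombinant gamete of its
queen — so a Mendelian locus can be mapped with a single heterozygous queen:
sort her drone offspring by phenotype into a mutant and a wild-type pool,
resequence each pool, and look for the genomic region where the pools'
allele frequencies diverge. At a marker with recombination fraction *r* to
the causal locus the mutant pool carries the causal-phase allele at expected
frequency 1 − *r* and the wild-type pool at *r*; unlinked markers sit at ½
in both pools.

haploscan implements the full analysis for this design, aimed at anyone
doing bulked segregant analysis (BSA) in haplodiploids or similar
single-parent pooled crosses:

* **Scan** — per-SNP Euclidean distance between the pools' nucleotide
  frequency 4-vectors,

  ED = √[(A_m−A_w)² + (C_m−C_w)² + (G_m−G_w)² + (T_m−T_w)²] ∈ [0, √2],

  raised to the 4th power, Lowess-smoothed per chromosome, thresholded at
  the genome-wide top-0.5% quantile of raw ED, with candidate regions
  called as above-threshold runs.
* **Filter** — GATK-style QD/FS/MQ hard filter; variant classification
  against GFF3 gene models (synonymous / nonsynonymous / stopgain /
  splicing / intronic / flanking / intergenic); candidate genes =
  nonsynonymous SNPs above threshold inside a region; then a
  per-individual filter keeping genes fixed in every mutant drone and
  carried by <10% of wild types.
* **Consequence** — apply SNVs/indels to a spliced CDS, translate, detect
  frameshifts and premature stops, report truncation and protein-domain
  disruption.
* **Statistics** — Pearson chi-square (no continuity correction) with
  pairwise post hoc tests, 1:1 segregation checks, rate summaries and
  2^−ΔCt relative expression with one-way ANOVA.
* **Simulate** — a forward generator of the whole experiment (recombinant
  gametes via the Haldane map function, phenotype pooling, Poisson-depth
  pooled sequencing with miscalls) that writes ground-truthed
  VCF/GFF3/FASTA/TSV inputs for end-to-end validation.

## Worked example

Simulate a cross on a realistic geometry (11 chromosomes, causal locus mid
chromosome 11), scan it, and call regions:

```r
library(haploscan)
map <- default_marker_map(n_chrom = 11, chrom_length = 20e6, spacing = 1e4)
cfg <- cross_config(causal_chrom = "chr11", causal_pos = 1e7, seed = 7)
sim <- simulate_cross(cfg, map)
scan <- ed_scan(sim$counts)             # ED, ED^4, Lowess, 99.5% threshold
regions <- call_regions(scan, min_snps = 10)
```

```
threshold: 1.1314
  region_id chrom   start      end n_snps peak_position
1  region_1 chr11 9600000 10730000    114      10340000
region length (Mb): 1.13
```

The single candidate region sits on chr11 and contains the true causal
position (10 Mb); the threshold is the interpolated 99.5% quantile of raw
per-SNP ED. The same objects feed `annotate_variants()` /
`candidate_snp_filter()` when gene models and a genome are available
(`emit_truth_and_files()` writes a toy GFF3/FASTA for a full dry run).

Scoring an RNAi phenotype table (counts: adults with color change vs
unchanged, per injection treatment):

```r
t4 <- matrix(c(45, 13, 12, 28, 2, 43), nrow = 3, byrow = TRUE,
             dimnames = list(c("SiYell", "NC", "Water"), c("variant", "unchanged")))
pearson_chi_square(t4)   # chi-square = 58.838, df = 2, p = 1.67e-13
posthoc_pairwise(t4)
```

```
             pair statistic df            p   p_adjusted
1    SiYell vs NC  22.03015  1 2.684005e-06 8.052016e-06
2 SiYell vs Water  54.64151  1 1.446479e-13 4.339437e-13
3     NC vs Water  10.05254  1 1.521382e-03 4.564147e-03
```

And the coding consequence of a 2-bp deletion in a CDS that overlaps a
protein domain:

```r
cds <- "ATGAAAGCTAGCGGATGA"                       # MKASG*
mut <- apply_variant_to_cds(cds, 7, "GC", "")     # delete bases 7-8
classify_consequence(cds, as.character(mut), domain_intervals("MRJP-like", 2, 5))
```

```
coding consequence: frameshift | stop: premature (TAG at codon 3)
protein: 5 aa -> 2 aa
disrupted domains: MRJP-like
```

A 2-base deletion shifts the frame, creates a TAG stop at codon 3, truncates
the 5-residue protein to 2 residues and disrupts the downstream domain.

## Command line

```sh
exec/haploscan simulate --config cross.yaml --out-dir sim/ --seed 5
exec/haploscan edscan --vcf sim/cross.vcf --out-prefix sim/scan --min-snps 10
exec/haploscan stats chisq --table color.tsv --posthoc
exec/haploscan stats segregation --a 75 --b 25 --ratio 1:1
```

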