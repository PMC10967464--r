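---
title: "Methods: Euclidean-distance bulked segregant mapping from haploid drone pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Euclidean-distance bulked segregant mapping from haploid drone pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The mapping problem

haploscan maps a Mendelian locus segregating in honeybee drones. Drones are
haploid: each one is a single recombinant gamete of its queen, so a cross
needs only one heterozygous queen. Offspring drones are sorted by phenotype
into a mutant and a wild-type pool, each pool is resequenced, and the causal
locus reveals itself as the genomic region where the two pools' allele
frequencies diverge most.

At a marker with recombination fraction $r$ to the causal locus, the mutant
pool carries the causal-phase allele with expected frequency $1-r$ and the
wild-type pool with frequency $r$; unlinked markers sit at $1/2$ in both
pools. Linkage decay around the causal locus therefore produces a peak in any
statistic that contrasts the pools' frequencies.

## The scan statistic

For each biallelic SNP the two pools' read counts are converted to
nucleotide-frequency 4-vectors and compared by the Euclidean distance

$$\mathrm{ED} = \sqrt{(A_m - A_w)^2 + (C_m - C_w)^2 + (G_m - G_w)^2 + (T_m - T_w)^2},$$

which is 0 for identical pools and $\sqrt{2}$ for pools fixed for different
alleles. At an ideal marker (infinite depth, no error) the expectation is
$\sqrt{2}\,|1 - 2r|$. The scan pipeline is:

1. **Hard filter** (`hard_filter`): sites with QD < 4.0, FS > 60.0 or
   MQ < 40.0 are removed before anything else, mirroring common GATK
   practice. Missing annotations cannot fail their clause.
2. **Power transform** (`power_transform`, default $k = 4$): raising ED to
   the fourth power amplifies near-fixed differences and suppresses
   background noise. The transform is order-preserving, so it changes no
   ranking, only contrast.
3. **Smoothing** (`lowess_fit`): classic locally weighted regression per
   chromosome — tricube weights over the $\lceil \mathrm{span}\cdot n\rceil$
   nearest neighbours, a weighted least-squares line evaluated at each point,
   and bisquare robustness re-weighting. The *powered* values are smoothed
   (the powered scan is the curve on which regions are drawn); note that
   smoothing-then-powering and powering-then-smoothing are *not* equivalent,
   and the package deliberately does the latter.
4. **Threshold** (`quantile_threshold`): the genome-wide 99.5% quantile of
   the *raw* per-SNP ED, interpolated between order statistics (R's type 7).
   The 0.5% tail is sensitive to the quantile convention, which is why the
   convention is fixed and documented. The smoothed curve is compared against
   the threshold raised to the same power $k$ — for pointwise powers the two
   comparison scales are equivalent.
5. **Region calling** (`call_regions`): maximal runs of consecutive SNPs
   whose smoothed powered statistic *strictly* exceeds the powered threshold;
   runs with fewer than `min_snps` members are dropped and regions are
   ranked by their peak smoothed value.

### Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `k` (power) | 4 | — | standard contrast boost for ED scans |
| `q` (quantile) | 0.995 | — | "top 0.5%" rule |
| `span` | 0.1 | fraction of chromosome SNPs | wide enough to kill single-SNP spikes, narrow enough to keep a megabase-scale peak |
| `robust_iters` | 2 | passes | Cleveland's usual default |
| `min_snps` | 10 | SNPs | suppresses single-SNP regions; contiguity is implied by "peak region" but no minimum is standard |
| `upstream_bp` | 1000 | bp | ANNOVAR's flank default |
| `splice_bp` | 2 | bp | canonical donor/acceptor dinucleotide |

Ties at the threshold are excluded (strictly-greater); zero-depth and
indel records never enter the scan, and multiallelic SNP records are
excluded by default (`keep_multiallelic = FALSE`) to match the biallelic-SNP
framing, although the four-base ED could score them. Physical position is
the smoothing abscissa by default; `x_index = TRUE` switches to SNP index
for strongly non-uniform marker grids.

## Candidate genes

Two successive filters narrow the region to genes:

1. `candidate_snp_filter`: keep SNPs with raw ED above the threshold, inside
   a called region, and classified exonic-nonsynonymous against the gene
   models; their genes are the candidates. Classification substitutes the
   reference codon (strand-aware) and compares amino acids; precedence is
   exonic/splicing over intronic over upstream/downstream over intergenic,
   and across transcripts the most severe class wins
   (stopgain > nonsynonymous > splicing > synonymous > intronic >
   upstream/downstream).
2. `gene_frequency_filter`: using per-individual haploid genotypes, a gene
   survives when its defining variants are carried by *every* non-missing
   mutant-pool individual (the "= 1" clause is decided on carrier counts,
   never by floating-point comparison) and by fewer than 10% of wild-type
   individuals — tolerating phenotyping contamination such as one mislabeled
   drone in fifteen (frequency 0.067).

The "mutant allele" of a variant is the allele fixed in the mutant pool when
one exists, else the non-reference allele.

## Coding consequences

`classify_consequence` compares an original and a mutated spliced CDS. A net
length change not divisible by 3 is a frameshift. A stop codon with further
codons after it in the mutated CDS is a premature stop; the terminal codon
of an in-frame-shortened CDS is the ordinary terminator (defining
prematureness by raw stop-codon index would mislabel every in-frame codon
deletion, so the index is compared against the mutated sequence's own
length). Translation uses the standard nuclear code; `N` translates to `X`.
Protein domains, supplied as amino-acid intervals, are reported *disrupted*
when truncated or when a frameshift alters residues inside them; in-frame
missense changes inside a domain are reported separately as domain variants,
since their impact is qualitatively different from truncation.

Variants may be given in CDS-relative or genomic coordinates; genomic
coordinates are mapped through the gene model strand-aware, with alleles
reverse-complemented for minus-strand genes.

## Cross and RNAi statistics

`pearson_chi_square` is the plain $\sum (O-E)^2/E$ statistic without
continuity correction — the uncorrected form is required to reproduce
published 2×2 post hoc values, and `posthoc_pairwise` tests each pair of
treatment rows as its own 2×C table (plain subsets, which reproduce the
published pairwise statistics; partitioned chi-squares do not). Raw p values
are reported alongside Bonferroni-adjusted ones, since the multiplicity
handling behind published values is typically unstated. `segregation_test`
checks a two-class ratio (1:1 for drones of a heterozygous queen) with a
1-df goodness-of-fit chi-square. `relative_expression` implements
$2^{-\Delta C_t}$ normalisation with multiple reference genes combined by
the arithmetic mean of their cycles (equivalent to a geometric mean on the
linear scale) followed by one-way ANOVA; percentage summaries round half-up
to one decimal, matching how such tables are printed.

## The simulator: what it emulates, and what it does not

`simulate_cross` is a forward generator of the experiment:

* **Gametes.** The queen has two haplotypes. Each drone is a Markov walk
  along the marker grid, switching haplotype between adjacent markers with
  the Haldane recombination fraction of their genetic distance. No crossover
  interference.
* **Genetic map.** None is published for this design, so physical distance
  converts at a flat 20 cM/Mb by default — honeybees recombine at an
  unusually high rate — with per-chromosome override.
* **Markers.** One biallelic SNP per 10 kb by default; ref/alt bases are
  assigned from a supplied genome or at random.
* **Pools.** Drones are phenotyped by their causal-locus allele and pooled
  15 + 15 by default. `phenotyping_error` (default 0) flips assignments at
  random; the fixed-contamination pattern — exactly one
  causal-allele carrier among fifteen wild types, carrier frequency 0.067 —
  is available deterministically via `n_mislabeled_wt = 1`.
* **Sequencing.** Depth per site per pool is Poisson with mean 30 (the
  experiment's real depth is unpublished; 30× is a routine pooled-reseq
  choice, exposed in the configuration). Each read samples a pool member
  uniformly and miscalls with probability `error_rate` (default 0.001),
  uniformly over the other three bases. Reads are independent across sites:
  there is no read-length linkage, which is adequate for a per-site
  statistic but understates local noise correlation.
* **Outputs.** VCF 4.2 with per-pool AD/DP plus a four-base `BC` FORMAT
  field so counts round-trip exactly; per-individual haploid genotype
  matrix; analytic truth table; optional toy GFF3/FASTA whose gene models
  translate cleanly and whose designated gene contains the causal variant in
  its CDS. Identical seeds give byte-identical files.

The generator does *not* emulate: read-level artifacts (FASTQ, mapping,
duplicates), indel realignment, segregating indels, diploid workers,
multi-queen designs, or variant-caller noise (the QD/FS/MQ annotations on
simulated VCFs are drawn from benign ranges purely so the hard-filter path
is exercised). A green simulation test therefore establishes the
statistical logic of the pipeline, not robustness to alignment artifacts.

## A structural limit of the desk-scale recovery test

One acceptance criterion fixes a scaled-down world — 3 chromosomes × 10 Mb,
one SNP per 10 kb, 20 cM/Mb — and asks the top-ranked region to contain the
causal locus in ≥ 18/20 replicates. That world cannot pass, for a geometric
reason worth recording. At 20 cM/Mb and 10 kb spacing, roughly 30 markers
lie in perfect LD with the causal locus across 30 drones and score exactly
$\sqrt 2$; but the genome has only 3000 markers, so the top-0.5% quantile
has 15 slots and the raw-ED threshold saturates at $\sqrt 2$ itself. The
smoothed ED$^4$ curve is (essentially) bounded by $\sqrt2^4 = 4 =$
threshold$^4$ and can never strictly exceed it: no region is ever called.
The full-scale experiment does not have this problem because its candidate
region is ~0.4% of a ~228 Mb genome — below the 0.5% tail — which is why
its published threshold (1.074) sits well under $\sqrt 2$. The package keeps
the criterion faithfully implemented and red, and demonstrates end-to-end
recovery instead at a realistic geometry (11 chromosomes, causal chromosome
a small fraction of the genome) in the regular test suite. The practical
lesson carries over to real designs: the quantile threshold is only
meaningful when the expected linked region is a small fraction of the
scanned genome.

## Numerical and interface choices

* Internal coordinates are 1-based inclusive (VCF/GFF convention); BED
  conversion happens only at the output boundary.
* The threshold quantile is computed after the hard filter (the order is
  unstated in common practice; computing it on clean sites is recorded in
  the run log).
* Exonic positions outside any CDS (untranslated exon regions) fall back to
  the intronic class; the class vocabulary is deliberately the standard
  seven-way annotation split and does not include UTR classes.
* Pools sequenced as per-individual libraries are supported by passing
  several sample names per pool to `read_pool_vcf`, which sums their allele
  depths.
* Degenerate inputs error early and loudly: empty scans, zero marginals in
  contingency tables, all-missing genotype pools, spans yielding fewer than
  two neighbours, ref-allele mismatches against the genome.

## Known limitations

* The ED scan assumes exactly two queen haplotypes; introgressed or
  multi-queen colonies violate the $1-r$ decay model.
* Lowess smoothing of a hard-bounded statistic biases peak heights downward;
  threshold saturation (above) is the extreme case.
* Consequence prediction covers coding effects only — no splice-regulatory,
  UTR, NMD or structural reasoning; domain coordinates must be supplied by
  the user.
* qPCR normalisation assumes perfect amplification efficiency (the textbook
  $2^{-\Delta C_t}$ model) and no efficiency correction from standard
  curves.
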