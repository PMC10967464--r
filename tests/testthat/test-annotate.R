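# the worked CDS is ATG AAA GCT AGC GGA TGA -> M K A S G *
# plus-strand gene gP: exon1 = genomic 21..29 (CDS 1..9), exon2 = 41..49

test_that("codon substitution separates synonymous / nonsynonymous / stopgain", {
  fix <- fixture_reference()
  # codon 2 AAA: third base at genomic 26; AAA->AAG is still Lys
  syn <- classify_site("chrF", 26, "A", "G", fix$models, fix$genome)
  expect_identical(syn$site_class, "exonic-synonymous")
  expect_identical(syn$aa_change, "K2K")
  # first base of codon 2 at genomic 24: AAA->GAA  Lys->Glu
  nonsyn <- classify_site("chrF", 24, "A", "G", fix$models, fix$genome)
  expect_identical(nonsyn$site_class, "exonic-nonsynonymous")
  expect_identical(nonsyn$aa_change, "K2E")
  expect_identical(nonsyn$gene_id, "gP")
  # codon 2 AAA->TAA: premature stop
  stopg <- classify_site("chrF", 24, "A", "T", fix$models, fix$genome)
  expect_identical(stopg$site_class, "exonic-stopgain")
  # ref disagreeing with the genome is a consistency error
  expect_error(classify_site("chrF", 24, "C", "G", fix$models, fix$genome),
               "disagrees")
})

test_that("minus-strand codons are read on the reverse complement", {
  fix <- fixture_reference()
  # gM CDS base 4 (codon 2 first base, A) sits at genomic 46 on chrR;
  # genomic T->C means CDS A->G: AAA->GAA, Lys->Glu
  gref <- as.character(Biostrings::subseq(fix$genome[["chrR"]], 46, 46))
  expect_identical(gref, "T")
  res <- classify_site("chrR", 46, "T", "C", fix$models, fix$genome)
  expect_identical(res$site_class, "exonic-nonsynonymous")
  expect_identical(res$aa_change, "K2E")
  expect_identical(res$gene_id, "gM")
})

test_that("positional classes follow the documented precedence and windows", {
  fix <- fixture_reference()
  cls <- function(pos, ...) classify_site("chrF", pos, "C", "A", fix$models,
                                          fix$genome, ...)$site_class
  expect_identical(cls(31), "splicing")    # 2 bp into the intron (exon ends 29)
  expect_identical(cls(30), "splicing")
  expect_identical(cls(35), "intronic")    # mid-intron
  expect_identical(cls(39), "splicing")    # 2 bp before exon 2 (starts 41)
  expect_identical(cls(15), "upstream")    # 6 bp 5' of the gene span
  expect_identical(cls(60), "downstream")  # 11 bp 3' of the gene span
  expect_identical(cls(60, upstream_bp = 5), "intergenic")  # outside the flank
  expect_identical(cls(35, splice_bp = 0), "intronic")
  res <- classify_site("chrF", 15, "C", "A", fix$models, fix$genome)
  expect_identical(res$gene_id, "gP")
  inter <- classify_site("chrX", 15, "C", "A", fix$models, fix$genome)
  expect_identical(inter$site_class, "intergenic")
  expect_true(is.na(inter$gene_id))
})

test_that("every variant gets exactly one class and classes partition a fixture", {
  fix <- fixture_reference()
  pos <- 1:120
  ann <- annotate_variants(
    data.frame(chrom = "chrF", pos = pos,
               ref = vapply(pos, function(p)
                 as.character(Biostrings::subseq(fix$genome[["chrF"]], p, p)),
                 character(1)),
               alt = "A", stringsAsFactors = FALSE),
    fix$models, fix$genome)
  ann$alt[ann$ref == "A"] <- "G"   # keep ref != alt irrelevant here; re-run those
  expect_identical(nrow(ann), 120L)
  expect_true(all(ann$site_class %in% c("exonic-synonymous",
                                        "exonic-nonsynonymous",
                                        "exonic-stopgain", "splicing",
                                        "intronic", "upstream", "downstream",
                                        "intergenic")))
  expect_identical(sum(table(ann$site_class)), 120L)
  expect_true(all(is.na(ann$gene_id[ann$site_class == "intergenic"])))
  expect_true(all(!is.na(ann$gene_id[ann$site_class != "intergenic"])))
})

test_that("classify_site agrees with a whole-protein brute-force oracle", {
  map <- tiny_map(n_chrom = 1, chrom_length = 5e4, spacing = 5e3)
  cfg <- cross_config(causal_chrom = "chr1", causal_pos = 2.5e4, seed = 11)
  set.seed(11)
  ref <- toy_reference(map, cfg, genes_per_chrom = 3)
  genome <- ref$genome
  models <- ref$models
  cds_pos_all <- unlist(lapply(models, function(m)
    unlist(lapply(seq_len(nrow(m$cds)), function(i) m$cds$start[i]:m$cds$end[i]))))
  set.seed(12)
  test_pos <- sample(cds_pos_all, 200, replace = TRUE)
  for (p in test_pos) {
    gref <- as.character(Biostrings::subseq(genome[["chr1"]], p, p))
    galt <- sample(setdiff(c("A", "C", "G", "T"), gref), 1)
    got <- classify_site("chr1", p, gref, galt, models, genome)
    # oracle: mutate the genome, retranslate the whole CDS, compare proteins
    m <- models[[paste0(got$gene_id, ".t1")]]
    g2 <- genome
    chr <- g2[["chr1"]]
    Biostrings::subseq(chr, p, p) <- Biostrings::DNAString(galt)
    g2[["chr1"]] <- chr
    p_ref <- translate_cds(cds_sequence(m, genome))
    p_alt <- translate_cds(cds_sequence(m, g2))
    want <- if (identical(p_alt$peptide, p_ref$peptide) &&
                identical(p_alt$stop_index, p_ref$stop_index)) "exonic-synonymous"
      else if (!is.na(p_alt$stop_index) &&
               (is.na(p_ref$stop_index) || p_alt$stop_index < p_ref$stop_index))
        "exonic-stopgain"
      else "exonic-nonsynonymous"
    expect_identical(got$site_class, want)
  }
})

test_that("candidate SNP filter keeps exactly the planted qualifying SNPs", {
  # 8 above-threshold SNPs; 5 qualify (nonsynonymous AND inside a region),
  # spread over 3 genes
  pos <- seq(100, 1300, by = 100)           # 13 SNPs
  ed <- c(0.2, 0.3, 1.2, 1.3, 1.25, 1.21, 1.28, 1.22, 1.26, 1.24, 0.2, 1.3, 0.1)
  scan <- fake_scan("c1", pos, smoothed = ed^4, threshold = 1, k = 4, ed = ed)
  regions <- data.frame(chrom = "c1", start = 250, end = 1050)
  cls <- rep("intronic", 13)
  cls[c(3, 4, 6, 8, 10)] <- "exonic-nonsynonymous"  # qualifying
  cls[5] <- "exonic-synonymous"                      # in region, above thr
  cls[12] <- "exonic-nonsynonymous"                  # above thr, outside region
  gene <- rep(NA_character_, 13)
  gene[c(3, 4)] <- "gA"
  gene[c(5, 6)] <- "gB"
  gene[c(8, 10)] <- "gC"
  gene[12] <- "gD"
  ann <- data.frame(snp_id = paste0("c1_", pos), site_class = cls,
                    gene_id = gene, aa_change = NA, stringsAsFactors = FALSE)
  res <- candidate_snp_filter(scan, regions, ann)
  expect_identical(nrow(res$snps), 5L)
  expect_identical(sort(res$genes), c("gA", "gB", "gC"))
  expect_true(all(res$snps$ed > 1))

  # conjunctive filters are monotone: dropping a rule never shrinks the output
  ann_all_nonsyn <- ann
  ann_all_nonsyn$site_class <- "exonic-nonsynonymous"
  expect_gte(nrow(candidate_snp_filter(scan, regions, ann_all_nonsyn)$snps),
             nrow(res$snps))
  wide <- data.frame(chrom = "c1", start = 0, end = 1e9)
  expect_gte(nrow(candidate_snp_filter(scan, wide, ann)$snps), nrow(res$snps))
})

test_that("per-individual allele frequencies follow the carrier/called ratio", {
  calls <- matrix(NA_integer_, 2, 30,
                  dimnames = list(c("v1", "v2"),
                                  c(paste0("mut_", 1:15), paste0("wt_", 1:15))))
  calls["v1", ] <- c(rep(1L, 15), rep(0L, 14), 1L)  # fixed in mut, 1/15 in wt
  calls["v2", ] <- c(rep(1L, 14), 0L, rep(0L, 15))  # 14/15 in mut, 0/15 in wt
  pool <- setNames(c(rep("mutant", 15), rep("wild-type", 15)), colnames(calls))
  gt <- individual_genotypes(calls, pool)

  f <- individual_allele_frequency(gt, "v1", "mutant")
  expect_identical(f$freq, 1)
  expect_identical(f$n_carrier, 15L)
  fw <- individual_allele_frequency(gt, "v1", "wild-type")
  expect_equal(fw$freq, 1 / 15, tolerance = 1e-12)
  expect_identical(round(fw$freq, 4), 0.0667)
  expect_identical(individual_allele_frequency(gt, "v2", "wild-type")$freq, 0)

  # all-missing pool is flagged undefined
  calls2 <- calls
  calls2["v2", 16:30] <- NA_integer_
  gt2 <- individual_genotypes(calls2, pool)
  expect_true(is.na(individual_allele_frequency(gt2, "v2", "wild-type")$freq))
})

test_that("gene frequency filter demands fixation in mutants and <0.1 in wild types", {
  expect_true(gene_frequency_filter(1.0, 1 / 15))
  expect_false(gene_frequency_filter(1.0, 0.1))     # strict <
  expect_false(gene_frequency_filter(14 / 15, 0.0))
  # the exact "=1" clause is decided on counts when provided
  expect_true(gene_frequency_filter(NA, 0.05, n_carrier_mut = 15, n_called_mut = 15))
  expect_false(gene_frequency_filter(NA, 0.05, n_carrier_mut = 14, n_called_mut = 15))
})

test_that("gene-level frequency filtering combines its defining variants", {
  calls <- matrix(c(rep(1L, 15), rep(0L, 14), 1L,
                    rep(1L, 15), rep(0L, 15),
                    rep(1L, 14), 0L, rep(0L, 15)),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("vA", "vB", "vC"),
                                  c(paste0("mut_", 1:15), paste0("wt_", 1:15))))
  pool <- setNames(c(rep("mutant", 15), rep("wild-type", 15)), colnames(calls))
  gt <- individual_genotypes(calls, pool)
  res <- filter_genes_by_frequency(gt, list(gPass = c("vA", "vB"), gFail = "vC"))
  expect_identical(res$pass, c(TRUE, FALSE))
  expect_equal(res$freq_wt[res$gene_id == "gPass"], 1 / 15, tolerance = 1e-12)
})
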