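# Variant site classification against gene models and the two candidate-gene
# filters: nonsynonymous SNPs inside the candidate region, then per-individual
# mutant-allele frequencies (fixed in the mutant pool, rare in wild types).

SITE_CLASSES <- c("exonic-stopgain", "exonic-nonsynonymous", "splicing",
                  "exonic-synonymous", "intronic", "upstream", "downstream",
                  "intergenic")

# lower rank = more severe; used to pick the reported class across transcripts
class_rank <- function(cls) match(cls, SITE_CLASSES)

translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (grepl("N", codon)) return("X")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

# classify one variant against one transcript model; NULL when the variant is
# beyond the model's reach (outside gene span and flanks)
classify_one <- function(chrom, pos, ref, alt, model, genome,
                         upstream_bp, splice_bp) {
  if (model$chrom != chrom) return(NULL)
  span <- c(min(model$exons$start), max(model$exons$end))
  res <- list(gene_id = model$gene_id, transcript_id = model$transcript_id,
              codon_change = NA_character_, aa_change = NA_character_)
  cpos <- cds_position(model, pos)
  if (!is.na(cpos)) {
    cds <- cds_sequence(model, genome)
    gref <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
    if (gref != ref)
      stop("variant ref (", ref, ") disagrees with genome (", gref, ") at ",
           chrom, ":", pos)
    cref <- if (model$strand == "+") ref else comp_base(ref)
    calt <- if (model$strand == "+") alt else comp_base(alt)
    stopifnot(substr(cds, cpos, cpos) == cref)
    ci <- (cpos - 1L) %/% 3L + 1L
    off <- (cpos - 1L) %% 3L + 1L
    codon_ref <- substr(cds, (ci - 1L) * 3L + 1L, ci * 3L)
    codon_alt <- codon_ref
    substr(codon_alt, off, off) <- calt
    aa_ref <- translate_codon(codon_ref)
    aa_alt <- translate_codon(codon_alt)
    res$codon_change <- paste0(codon_ref, ">", codon_alt)
    res$aa_change <- paste0(aa_ref, ci, aa_alt)
    res$site_class <- if (aa_alt == aa_ref) "exonic-synonymous"
      else if (aa_alt == "*") "exonic-stopgain"
      else "exonic-nonsynonymous"
    return(res)
  }
  in_exon <- any(pos >= model$exons$start & pos <= model$exons$end)
  if (pos >= span[1] && pos <= span[2]) {
    # splice window: within splice_bp of an exon boundary, on the intron side
    near_splice <- any((pos >= model$exons$end + 1L & pos <= model$exons$end + splice_bp) |
                         (pos <= model$exons$start - 1L & pos >= model$exons$start - splice_bp))
    res$site_class <- if (!in_exon && near_splice) "splicing" else "intronic"
    return(res)
  }
  five_prime <- if (model$strand == "+") pos < span[1] else pos > span[2]
  dist <- if (pos < span[1]) span[1] - pos else pos - span[2]
  if (dist <= upstream_bp) {
    res$site_class <- if (five_prime) "upstream" else "downstream"
    return(res)
  }
  NULL
}

#' Classify a variant site against gene models
#'
#' Assigns one of the site classes exonic-synonymous / exonic-nonsynonymous /
#' exonic-stopgain / splicing / intronic / upstream / downstream / intergenic.
#' Within a CDS the reference codon is substituted (strand-aware) and
#' compared. With several overlapping transcripts the most severe class is
#' reported (stopgain > nonsynonymous > splicing > synonymous > intronic >
#' upstream > downstream).
#'
#' @param chrom,pos,ref,alt the variant (single-base SNV).
#' @param models list of [gene_model()] objects.
#' @param genome `DNAStringSet` for codon lookup.
#' @param upstream_bp flank width for upstream/downstream calls (default
#'   1000 bp). @param splice_bp intronic splice window (default 2 bp).
#' @return A one-row data.frame: `site_class`, `gene_id`, `transcript_id`,
#'   `codon_change`, `aa_change` (`NA`/empty outside CDS).
#' @export
classify_site <- function(chrom, pos, ref, alt, models, genome,
                          upstream_bp = 1000, splice_bp = 2) {
  hits <- Filter(Negate(is.null), lapply(models, function(m)
    classify_one(chrom, pos, ref, alt, m, genome, upstream_bp, splice_bp)))
  if (!length(hits)) {
    return(data.frame(site_class = "intergenic", gene_id = NA_character_,
                      transcript_id = NA_character_,
                      codon_change = NA_character_, aa_change = NA_character_,
                      stringsAsFactors = FALSE))
  }
  best <- hits[[which.min(vapply(hits, function(h) class_rank(h$site_class),
                                 numeric(1)))]]
  data.frame(site_class = best$site_class, gene_id = best$gene_id,
             transcript_id = best$transcript_id,
             codon_change = best$codon_change, aa_change = best$aa_change,
             stringsAsFactors = FALSE)
}

#' Annotate a table of variants
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `snp_id` (created from coordinates when absent).
#' @inheritParams classify_site
#' @return data.frame with one row per variant: the input coordinates plus the
#'   [classify_site()] columns.
#' @export
annotate_variants <- function(variants, models, genome,
                              upstream_bp = 1000, splice_bp = 2) {
  if (is.null(variants$snp_id))
    variants$snp_id <- paste0(variants$chrom, "_", variants$pos)
  ann <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
    classify_site(variants$chrom[i], variants$pos[i], variants$ref[i],
                  variants$alt[i], models, genome, upstream_bp, splice_bp)))
  cbind(variants[, c("snp_id", "chrom", "pos", "ref", "alt")], ann)
}

#' Filter candidate SNPs and genes from a scan
#'
#' Keeps SNPs that satisfy all of: raw ED strictly above the scan threshold,
#' position inside a candidate region, and site class exonic-nonsynonymous.
#' The distinct gene ids of the survivors are the candidate genes.
#'
#' @param scan an [ed_scan()] result.
#' @param regions regions from [call_regions()].
#' @param annotations output of [annotate_variants()] sharing `snp_id` with
#'   the scan.
#' @return list with `snps` (data.frame of surviving SNPs with their ED and
#'   annotation) and `genes` (character vector of candidate gene ids).
#' @export
candidate_snp_filter <- function(scan, regions, annotations) {
  thr <- scan_threshold(scan)
  merged <- merge(as.data.frame(scan)[, c("snp_id", "chrom", "pos", "ed")],
                  annotations[, c("snp_id", "site_class", "gene_id", "aa_change")],
                  by = "snp_id")
  in_region <- vapply(seq_len(nrow(merged)), function(i)
    any(regions$chrom == merged$chrom[i] &
          regions$start <= merged$pos[i] & regions$end >= merged$pos[i]),
    logical(1))
  keep <- merged$ed > thr & in_region &
    merged$site_class == "exonic-nonsynonymous"
  snps <- merged[keep, , drop = FALSE]
  rownames(snps) <- NULL
  list(snps = snps, genes = unique(snps$gene_id))
}

# ---- per-individual allele frequencies -------------------------------------

#' Per-individual haploid genotype calls
#'
#' @param calls matrix of 0/1/`NA` haploid calls, variants (rows, named by
#'   snp_id) x individuals (columns).
#' @param pool named character vector, `"mutant"` or `"wild-type"` per
#'   individual (names matching the columns of `calls`).
#' @return An `individual_genotypes` object.
#' @export
individual_genotypes <- function(calls, pool) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, NA))) stop("calls must be 0, 1 or NA (haploid)")
  if (is.null(colnames(calls)) || !all(colnames(calls) %in% names(pool)))
    stop("every column of calls needs a pool label")
  pool <- pool[colnames(calls)]
  if (!all(pool %in% c("mutant", "wild-type")))
    stop("pool labels must be 'mutant' or 'wild-type'")
  structure(list(calls = calls, pool = pool), class = "individual_genotypes")
}

# identify the mutant allele for one variant: the allele fixed in the mutant
# pool if one exists, else the non-reference allele (1)
mutant_allele <- function(gt, variant) {
  v <- gt$calls[variant, gt$pool == "mutant"]
  v <- v[!is.na(v)]
  if (length(v) && length(unique(v)) == 1L) unique(v) else 1L
}

#' Mutant-allele frequency of a variant in one pool
#'
#' Number of individuals in the pool carrying the mutant allele divided by
#' the number of non-missing calls in the pool.
#'
#' @param gt an [individual_genotypes()] object.
#' @param variant variant id (rowname of the call matrix).
#' @param pool `"mutant"` or `"wild-type"`.
#' @return list with `freq`, `n_carrier`, `n_called` (`freq` is `NA` when the
#'   pool has no non-missing call).
#' @export
individual_allele_frequency <- function(gt, variant, pool = c("mutant", "wild-type")) {
  pool <- match.arg(pool)
  if (!variant %in% rownames(gt$calls)) stop("unknown variant: ", variant)
  allele <- mutant_allele(gt, variant)
  v <- gt$calls[variant, gt$pool == pool]
  n_called <- sum(!is.na(v))
  n_carrier <- sum(v == allele, na.rm = TRUE)
  list(freq = if (n_called) n_carrier / n_called else NA_real_,
       n_carrier = n_carrier, n_called = n_called)
}

#' Per-individual allele-frequency filter for candidate genes
#'
#' A gene-defining variant passes when its mutant-allele frequency equals 1
#' in the mutant pool (every non-missing mutant individual carries it — an
#' exact count condition, not a floating comparison) and is strictly below
#' 0.1 in the wild-type pool.
#'
#' @param freq_mut,freq_wt frequencies per variant (vectorised). When
#'   `n_carrier_mut`/`n_called_mut` are supplied the "= 1" clause is decided
#'   on those counts instead of on `freq_mut`.
#' @param n_carrier_mut,n_called_mut optional carrier/called counts in the
#'   mutant pool.
#' @return Logical vector: passes the filter.
#' @examples
#' gene_frequency_filter(1.0, 1 / 15)   # TRUE  (0.0667 < 0.1)
#' gene_frequency_filter(1.0, 0.1)      # FALSE (strict <)
#' @export
gene_frequency_filter <- function(freq_mut, freq_wt,
                                  n_carrier_mut = NULL, n_called_mut = NULL) {
  fixed_mut <- if (!is.null(n_carrier_mut) && !is.null(n_called_mut)) {
    n_called_mut > 0 & n_carrier_mut == n_called_mut
  } else freq_mut == 1
  fixed_mut & freq_wt < 0.1
}

#' Apply the frequency filter to candidate genes
#'
#' For each candidate gene, every supplied defining variant must pass
#' [gene_frequency_filter()] computed from per-individual genotypes.
#'
#' @param gt an [individual_genotypes()] object.
#' @param variants_by_gene named list: gene id -> character vector of variant
#'   ids defining it.
#' @return data.frame per gene: `gene_id`, `freq_mut`, `freq_wt`, `pass`.
#' @export
filter_genes_by_frequency <- function(gt, variants_by_gene) {
  rows <- lapply(names(variants_by_gene), function(g) {
    res <- lapply(variants_by_gene[[g]], function(v) {
      fm <- individual_allele_frequency(gt, v, "mutant")
      fw <- individual_allele_frequency(gt, v, "wild-type")
      data.frame(freq_mut = fm$freq, freq_wt = fw$freq,
                 pass = gene_frequency_filter(fm$freq, fw$freq,
                                              fm$n_carrier, fm$n_called))
    })
    res <- do.call(rbind, res)
    data.frame(gene_id = g, freq_mut = max(res$freq_mut),
               freq_wt = max(res$freq_wt), pass = all(res$pass),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
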