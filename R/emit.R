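# Writers for the simulator's outputs: VCF with per-pool allele depths, a
# per-individual genotype matrix, the truth table, and a toy GFF3/FASTA
# reference so annotation and consequence modules can be exercised end to end.

#' Write a site-count table as a two-sample VCF
#'
#' Each pool becomes one sample column with GT (placeholder `./.`), AD
#' (ref,alt), DP and the four-base BC FORMAT field that makes the count table
#' round-trip exactly through [read_pool_vcf()]. QD/FS/MQ annotations present
#' in the table are written to INFO.
#'
#' @param counts a [pool_site_counts()] table.
#' @param path output VCF path.
#' @param mut_name,wt_name sample names of the two pools.
#' @export
write_pool_vcf <- function(counts, path, mut_name = "MUT", wt_name = "WT") {
  chroms <- unique(counts$chrom)
  contig_len <- vapply(chroms, function(cc) max(counts$pos[counts$chrom == cc]),
                       numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haploscan_simcross",
           paste0("##contig=<ID=", chroms, ",length=", format(contig_len, scientific = FALSE, trim = TRUE), ">"),
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FisherStrand phred-scaled p\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=BC,Number=4,Type=Integer,Description=\"Read counts for A,C,G,T\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", mut_name, wt_name, sep = "\t"))
  ri <- match(counts$ref, BASES)
  ai <- match(counts$alt, BASES)
  cm <- pool_freqs(counts, "mut", "count")
  cw <- pool_freqs(counts, "wt", "count")
  fmt_num <- function(x) ifelse(is.na(x), ".", formatC(x, format = "f", digits = 3))
  info <- ifelse(is.na(counts$qd) & is.na(counts$fs) & is.na(counts$mq), ".",
                 paste0("QD=", fmt_num(counts$qd), ";FS=", fmt_num(counts$fs),
                        ";MQ=", fmt_num(counts$mq)))
  samp <- function(cnt, dp, i) {
    paste0("./.:", cnt[cbind(seq_len(nrow(cnt)), ri)], ",",
           cnt[cbind(seq_len(nrow(cnt)), ai)], ":", dp, ":",
           cnt[, 1], ",", cnt[, 2], ",", cnt[, 3], ",", cnt[, 4])
  }
  rows <- paste(counts$chrom, counts$pos, counts$snp_id, counts$ref, counts$alt,
                ".", "PASS", info, "GT:AD:DP:BC",
                samp(cm, counts$mut_dp), samp(cw, counts$wt_dp), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    attr_g <- paste0("ID=", m$gene_id,
                     if (nzchar(m$annotation)) paste0(";description=", m$annotation))
    lines <- c(lines,
      paste(m$chrom, "haploscan", "gene", span[1], span[2], ".", m$strand, ".",
            attr_g, sep = "\t"),
      paste(m$chrom, "haploscan", "mRNA", span[1], span[2], ".", m$strand, ".",
            paste0("ID=", m$transcript_id, ";Parent=", m$gene_id), sep = "\t"))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, paste(m$chrom, "haploscan", "exon", m$exons$start[i],
                              m$exons$end[i], ".", m$strand, ".",
                              paste0("ID=", m$transcript_id, ".exon", i,
                                     ";Parent=", m$transcript_id), sep = "\t"))
    for (i in seq_len(nrow(m$cds)))
      lines <- c(lines, paste(m$chrom, "haploscan", "CDS", m$cds$start[i],
                              m$cds$end[i], ".", m$strand, "0",
                              paste0("ID=", m$transcript_id, ".cds", i,
                                     ";Parent=", m$transcript_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# sense (non-stop) codons of the standard genetic code
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# stop-free CDS of a given length: ATG + sense codons + TAA
random_cds <- function(len) {
  stopifnot(len %% 3 == 0, len >= 9)
  body <- sample(setdiff(sense_codons(), "ATG"), len / 3 - 2, replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Build a toy reference (genome + gene models) for a marker map
#'
#' Generates a random genome covering every marker, places a few multi-exon
#' genes per chromosome (alternating strand) and rewrites the genome inside
#' each CDS with a stop-free coding sequence, so every model translates
#' cleanly. The gene covering the causal locus is constructed so that the
#' causal position falls inside its CDS.
#'
#' @param map a [marker_map()].
#' @param config a [cross_config()] locating the causal marker.
#' @param genes_per_chrom genes placed per chromosome (>= 1).
#' @param exon_bp,intron_bp exon and intron lengths of the toy models (exon_bp
#'   must be divisible by 3).
#' @param n_exons exons per gene.
#' @return List with `genome` (`DNAStringSet`) and `models` (list of
#'   [gene_model()]); the causal gene's id is in attribute `causal_gene`.
#' @export
toy_reference <- function(map, config, genes_per_chrom = 2,
                          exon_bp = 300, intron_bp = 200, n_exons = 3) {
  stopifnot(exon_bp %% 3 == 0)
  chroms <- unique(map$chrom)
  glen <- vapply(chroms, function(cc) max(map$pos[map$chrom == cc]) + 1000L,
                 numeric(1))
  genome <- Biostrings::DNAStringSet(vapply(glen, function(L)
    paste(sample(BASES, L, replace = TRUE), collapse = ""), character(1)))
  names(genome) <- chroms

  gene_span <- n_exons * exon_bp + (n_exons - 1) * intron_bp
  models <- list()
  causal_gene <- NULL
  gi <- 0L
  for (cc in chroms) {
    L <- glen[[cc]]
    starts <- round(seq(L * 0.15, L * 0.85, length.out = genes_per_chrom))
    if (cc == config$causal_chrom) {
      # anchor one gene so the causal marker sits mid second exon
      anchor <- config$causal_pos - (exon_bp + intron_bp + exon_bp %/% 2)
      starts[which.min(abs(starts - anchor))] <- anchor
    }
    for (s in starts) {
      gi <- gi + 1L
      ex_start <- s + (seq_len(n_exons) - 1L) * (exon_bp + intron_bp)
      exons <- data.frame(start = ex_start, end = ex_start + exon_bp - 1L)
      strand <- if (gi %% 2L == 0L) "-" else "+"
      m <- gene_model(gene_id = sprintf("g%03d", gi), chrom = cc,
                      strand = strand, exons = exons, cds = exons,
                      annotation = sprintf("toy gene %d", gi))
      # rewrite genome within the CDS so it translates without internal stops
      cds <- random_cds(m$cds_length)
      if (strand == "-")
        cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      offset <- 0L
      chr_seq <- genome[[cc]]
      for (i in seq_len(nrow(exons))) {
        w <- exons$end[i] - exons$start[i] + 1L
        Biostrings::subseq(chr_seq, exons$start[i], exons$end[i]) <-
          Biostrings::DNAString(substr(cds, offset + 1L, offset + w))
        offset <- offset + w
      }
      genome[[cc]] <- chr_seq
      if (cc == config$causal_chrom &&
          any(config$causal_pos >= exons$start & config$causal_pos <= exons$end))
        causal_gene <- m$gene_id
      models[[m$transcript_id]] <- m
    }
  }
  out <- list(genome = genome, models = models)
  attr(out, "causal_gene") <- causal_gene
  out
}

#' Write the complete synthetic truth set to disk
#'
#' Emits `cross.vcf` (per-pool AD/DP/BC), `genotypes.tsv` (one haploid 0/1
#' call per drone per marker), `truth.tsv` (expected pool frequencies with the
#' causal locus in header comments) and, when a reference is supplied,
#' `genome.fa` and `genes.gff3`. Identical simulations produce byte-identical
#' files.
#'
#' @param sim a `cross_sim` from [simulate_cross()].
#' @param out_dir output directory (created if needed).
#' @param reference optional [toy_reference()] output.
#' @param site_quality when TRUE (default), draw plausible QD/FS/MQ INFO
#'   annotations for each record (deterministic under the simulation seed
#'   when called right after [simulate_cross()]).
#' @return Named character vector of the files written.
#' @export
emit_truth_and_files <- function(sim, out_dir, reference = NULL,
                                 site_quality = TRUE) {
  stopifnot(inherits(sim, "cross_sim"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  counts <- sim$counts
  if (site_quality) {
    m <- nrow(counts)
    counts$qd <- round(stats::runif(m, 5, 35), 3)
    counts$fs <- round(stats::runif(m, 0, 10), 3)
    counts$mq <- round(stats::runif(m, 50, 60), 3)
  }
  paths <- c(vcf = file.path(out_dir, "cross.vcf"),
             genotypes = file.path(out_dir, "genotypes.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_pool_vcf(counts, paths[["vcf"]])
  gt <- data.frame(snp_id = rownames(sim$genotypes),
                   chrom = sim$map$chrom, pos = sim$map$pos,
                   ref = sim$map$ref, alt = sim$map$alt,
                   sim$genotypes, stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(gt, paths[["genotypes"]])
  con <- file(paths[["truth"]], "w")
  writeLines(c(paste0("#causal_chrom=", sim$config$causal_chrom),
               paste0("#causal_pos=", sim$config$causal_pos)), con)
  utils::write.table(as.data.frame(sim$truth), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(reference)) {
    paths <- c(paths, fasta = file.path(out_dir, "genome.fa"),
               gff3 = file.path(out_dir, "genes.gff3"))
    Biostrings::writeXStringSet(reference$genome, paths[["fasta"]])
    write_gff3(reference$models, paths[["gff3"]])
  }
  paths
}

#' Read a per-individual haploid genotype matrix written by
#' [emit_truth_and_files()]
#'
#' @param path `genotypes.tsv` file; individual columns must be named
#'   `mut_<i>` / `wt_<i>`.
#' @return An `individual_genotypes` object (see [individual_genotypes()]).
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ind_cols <- grep("^(mut|wt)_", names(df), value = TRUE)
  if (!length(ind_cols)) stop("no individual columns (mut_*/wt_*) in ", path)
  calls <- as.matrix(df[, ind_cols])
  rownames(calls) <- df$snp_id
  pool <- ifelse(startsWith(ind_cols, "mut_"), "mutant", "wild-type")
  individual_genotypes(calls, stats::setNames(pool, ind_cols))
}
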