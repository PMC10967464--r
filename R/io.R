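# Readers for the standard formats the pipeline consumes (VCF, GFF3, FASTA)
# and small writers for BED/TSV. Parsing is delegated to VariantAnnotation,
# rtracklayer and Biostrings; this module reshapes their containers into the
# pipeline's domain types.

#' Read per-pool allele depths from a VCF
#'
#' Maps biallelic SNP records to four-nucleotide read counts per pool:
#' reference and alternate AD counts are placed on their bases and the other
#' bases set to 0, unless the record carries the full four-base `BC` FORMAT
#' field written by [write_pool_vcf()], in which case counts round-trip
#' exactly. Multiallelic SNP records have every single-base allele's count
#' placed on its base and are flagged `"multiallelic"`; indel records are
#' passed through with the `"indel"` flag and zero base counts. Each pool may
#' be one sample or several (per-individual libraries), in which case AD/BC
#' are summed across the pool's samples.
#'
#' @param path VCF 4.x file (plain text or bgzipped).
#' @param mut_sample,wt_sample sample name(s) of the mutant and wild-type pool.
#' @return A [pool_site_counts()] table, with `qd`/`fs`/`mq` columns filled
#'   from the INFO field when present.
#' @export
read_pool_vcf <- function(path, mut_sample = "MUT", wt_sample = "WT") {
  vcf <- VariantAnnotation::readVcf(path)
  missing <- setdiff(c(mut_sample, wt_sample), colnames(vcf))
  if (length(missing))
    stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
  if (!"AD" %in% names(VariantAnnotation::geno(vcf)))
    stop("VCF lacks the AD FORMAT field: ", path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  alt_chr <- lapply(seq_along(alt_list), function(i) as.character(alt_list[[i]]))
  n_alt <- lengths(alt_chr)
  is_indel <- nchar(ref) > 1L |
    vapply(alt_chr, function(a) any(nchar(a) != 1L), logical(1))
  site_type <- ifelse(is_indel, "indel",
                      ifelse(n_alt > 1L, "multiallelic", "snp"))

  has_bc <- "BC" %in% names(VariantAnnotation::geno(vcf))
  sum_pool <- function(field, samples) {
    # Number=R fields parse to a matrix of integer-vector lists; fixed-Number
    # fields to a variants x samples x Number array
    x <- VariantAnnotation::geno(vcf)[[field]]
    if (length(dim(x)) == 3L) {
      x <- x[, samples, , drop = FALSE]
      x[is.na(x)] <- 0L
      tot <- apply(x, c(1, 3), sum)
      lapply(seq_len(nrow(tot)), function(i) as.integer(tot[i, ]))
    } else {
      x <- x[, samples, drop = FALSE]
      lapply(seq_len(nrow(x)), function(i) {
        vals <- x[i, ]
        if (!is.list(vals)) vals <- list(vals)
        Reduce(`+`, lapply(vals, function(v) {
          v[is.na(v)] <- 0L
          v
        }))
      })
    }
  }
  build_counts <- function(samples) {
    cnt <- matrix(0L, length(pos), 4L, dimnames = list(NULL, BASES))
    if (has_bc) {
      bc <- sum_pool("BC", samples)
      ok <- !vapply(bc, function(v) length(v) != 4L || all(v == 0L), logical(1))
      for (i in which(ok)) cnt[i, ] <- bc[[i]]
      need_ad <- which(!ok)
    } else need_ad <- seq_along(pos)
    if (length(need_ad)) {
      ad <- sum_pool("AD", samples)
      for (i in need_ad) {
        if (is_indel[i]) next
        v <- ad[[i]]
        if (length(v) != n_alt[i] + 1L)
          stop("AD length mismatch at record ", chrom[i], ":", pos[i])
        bases <- c(ref[i], alt_chr[[i]])
        cnt[i, match(bases, BASES)] <- v
      }
    }
    cnt
  }
  cm <- build_counts(mut_sample)
  cw <- build_counts(wt_sample)

  info <- VariantAnnotation::info(vcf)
  get_info <- function(key) {
    if (key %in% colnames(info)) as.numeric(info[[key]]) else NA_real_
  }
  pool_site_counts(chrom = chrom, pos = pos, ref = ref,
                   alt = vapply(alt_chr, paste, character(1), collapse = ","),
                   counts_mut = cm, counts_wt = cw, site_type = site_type,
                   qd = get_info("QD"), fs = get_info("FS"), mq = get_info("MQ"))
}

#' GATK-style hard filter on variant quality annotations
#'
#' A site fails when QD < 4.0, FS > 60.0 or MQ < 40.0; a missing annotation
#' cannot fail its clause. The reason string lists every violated clause.
#'
#' @param qd,fs,mq numeric vectors (recycled); `NA` = annotation absent.
#' @return data.frame with logical `pass` and character `reason` (`""` for
#'   passing sites).
#' @examples
#' hard_filter(qd = c(10, 3.9), fs = c(5, 5), mq = c(60, 60))
#' @export
hard_filter <- function(qd = NA_real_, fs = NA_real_, mq = NA_real_) {
  n <- max(length(qd), length(fs), length(mq))
  qd <- rep_len(as.numeric(qd), n)
  fs <- rep_len(as.numeric(fs), n)
  mq <- rep_len(as.numeric(mq), n)
  if (any(qd < 0, na.rm = TRUE) || any(fs < 0, na.rm = TRUE) || any(mq < 0, na.rm = TRUE))
    stop("quality annotations must be non-negative")
  bad_qd <- !is.na(qd) & qd < 4.0
  bad_fs <- !is.na(fs) & fs > 60.0
  bad_mq <- !is.na(mq) & mq < 40.0
  reason <- vapply(seq_len(n), function(i) {
    paste(c(if (bad_qd[i]) "QD<4.0", if (bad_fs[i]) "FS>60.0",
            if (bad_mq[i]) "MQ<40.0"), collapse = ";")
  }, character(1))
  data.frame(pass = !(bad_qd | bad_fs | bad_mq), reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply the hard filter to a site-count table
#'
#' @param counts a [pool_site_counts()] table with `qd`/`fs`/`mq` columns.
#' @return The table restricted to passing sites.
#' @export
hard_filter_counts <- function(counts) {
  hf <- hard_filter(counts$qd, counts$fs, counts$mq)
  counts[hf$pass, , drop = FALSE]
}

# ---- gene models -----------------------------------------------------------

#' Construct a transcript gene model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome label; `strand` must be "+" or "-".
#' @param exons,cds data.frames with `start`/`end` (1-based inclusive); exons
#'   must be non-overlapping and CDS intervals contained in exons.
#' @param annotation free-text description.
#' @return A `gene_model` list; `complete` is TRUE when the concatenated CDS
#'   length is divisible by 3.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds,
                       transcript_id = paste0(gene_id, ".t1"), annotation = "") {
  if (!strand %in% c("+", "-")) stop("unknown strand for ", gene_id, ": ", strand)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  exons[] <- lapply(exons, as.integer)
  cds[] <- lapply(cds, as.integer)
  rownames(exons) <- NULL
  rownames(cds) <- NULL
  if (any(exons$end < exons$start) || any(cds$end < cds$start))
    stop("malformed intervals in ", gene_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in ", gene_id)
  in_exon <- vapply(seq_len(nrow(cds)), function(i)
    any(cds$start[i] >= exons$start & cds$end[i] <= exons$end), logical(1))
  if (!all(in_exon)) stop("CDS outside exons in ", gene_id)
  len <- sum(cds$end - cds$start + 1L)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = as.character(chrom), strand = strand,
                 exons = exons, cds = cds, annotation = annotation,
                 cds_length = len, complete = len %% 3L == 0L),
            class = "gene_model")
}

#' Read gene models from a GFF3 file
#'
#' Resolves the gene/mRNA/exon/CDS hierarchy through `Parent` attributes into
#' one [gene_model()] per transcript. Orphan CDS/exon features (whose parent
#' transcript is absent) and features on an unknown strand are errors.
#'
#' @param path GFF3 file.
#' @return List of `gene_model` objects, named by transcript id.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) gr$ID else rep(NA, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr))) {
    lapply(seq_along(gr), function(i) as.character(gr$Parent[[i]]))
  } else rep(list(character(0)), length(gr))
  tx_idx <- which(type %in% c("mRNA", "transcript"))
  gene_idx <- which(type == "gene")
  gene_ann <- character(0)
  if (length(gene_idx)) {
    ann_col <- intersect(c("description", "Note", "product"),
                         names(S4Vectors::mcols(gr)))
    gene_ann <- stats::setNames(
      if (length(ann_col)) as.character(S4Vectors::mcols(gr)[gene_idx, ann_col[1]])
      else rep("", length(gene_idx)),
      ids[gene_idx])
    gene_ann[is.na(gene_ann)] <- ""
  }
  tx_ids <- ids[tx_idx]
  child_idx <- which(type %in% c("exon", "CDS"))
  for (i in child_idx) {
    if (!length(parents[[i]]) || !any(parents[[i]] %in% tx_ids))
      stop("orphan ", type[i], " feature at line ", i, " of ", path)
  }
  models <- lapply(seq_along(tx_idx), function(k) {
    i <- tx_idx[k]
    tid <- ids[i]
    gid <- if (length(parents[[i]])) parents[[i]][1] else tid
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-"))
      stop("unknown strand for transcript ", tid)
    pick <- function(ft) {
      j <- child_idx[type[child_idx] == ft &
                       vapply(parents[child_idx], function(p) tid %in% p, logical(1))]
      data.frame(start = GenomicRanges::start(gr[j]),
                 end = GenomicRanges::end(gr[j]))
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    if (nrow(exons) == 0L) exons <- cds
    gene_model(gene_id = gid, transcript_id = tid,
               chrom = as.character(GenomicRanges::seqnames(gr[i])),
               strand = strand, exons = exons, cds = cds,
               annotation = if (gid %in% names(gene_ann)) gene_ann[[gid]] else "")
  })
  stats::setNames(models, ids[tx_idx])
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A `Biostrings::DNAStringSet` named by sequence id (first token of
#'   each header).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Spliced CDS sequence of a gene model
#'
#' Concatenates the CDS intervals in genomic order and reverse-complements for
#' minus-strand models, so the result always starts at the start codon.
#'
#' @param model a [gene_model()].
#' @param genome a `DNAStringSet` containing the model's chromosome.
#' @return CDS sequence as a character string.
#' @export
cds_sequence <- function(model, genome) {
  chr <- genome[[model$chrom]]
  if (is.null(chr)) stop("chromosome not in genome: ", model$chrom)
  parts <- vapply(seq_len(nrow(model$cds)), function(i)
    as.character(Biostrings::subseq(chr, model$cds$start[i], model$cds$end[i])),
    character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

#' Map a genomic position into spliced-CDS coordinates
#'
#' @param model a [gene_model()].
#' @param pos genomic position (1-based).
#' @return 1-based position within the spliced CDS (counted from the start
#'   codon, strand-aware), or `NA` if `pos` is not in the CDS.
#' @export
cds_position <- function(model, pos) {
  cds <- model$cds
  hit <- which(pos >= cds$start & pos <= cds$end)[1]
  if (is.na(hit)) return(NA_integer_)
  widths <- cds$end - cds$start + 1L
  if (model$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (pos - cds$start[hit]) + 1L
  } else {
    after <- if (hit < nrow(cds)) sum(widths[seq(hit + 1L, nrow(cds))]) else 0L
    after + (cds$end[hit] - pos) + 1L
  }
}

# ---- small writers ---------------------------------------------------------

#' Write candidate regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so a
#' region `[start, end]` becomes `start-1, end`.
#'
#' @param regions data.frame with `chrom`, `start`, `end` and optionally a
#'   name column (`region_id`).
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  name <- if ("region_id" %in% names(regions)) regions$region_id
          else paste0("region_", seq_len(nrow(regions)))
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
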