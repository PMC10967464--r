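# Per-site, per-pool nucleotide read counts — the container the ED statistic
# is computed from. One row per variant site; counts on all four bases for the
# mutant and wild-type pool, with derived frequencies.

#' Construct a pool site-count table
#'
#' @param chrom,pos,ref,alt site coordinates and alleles (`ref`/`alt` single
#'   bases for SNPs; longer strings allowed for indel pass-through rows).
#' @param counts_mut,counts_wt integer matrices, sites x 4, columns A,C,G,T.
#' @param site_type per-site flag: `"snp"`, `"multiallelic"` or `"indel"`.
#'   Only `"snp"` rows enter the Euclidean-distance scan by default.
#' @param qd,fs,mq optional variant-quality annotations (QualByDepth,
#'   FisherStrand, RMSMappingQuality) carried for [hard_filter()].
#' @return A `pool_site_counts` data.frame with columns `snp_id`, coordinates,
#'   per-pool base counts (`mut_A` ... `wt_T`), depths (`mut_dp`, `wt_dp`),
#'   frequencies (`fmut_A` ... `fwt_T`, `NA` at zero depth) and the
#'   `zero_depth` flag (set when either pool has depth 0).
#' @export
pool_site_counts <- function(chrom, pos, ref, alt, counts_mut, counts_wt,
                             site_type = "snp", qd = NA_real_, fs = NA_real_,
                             mq = NA_real_) {
  m <- length(pos)
  counts_mut <- matrix(as.integer(counts_mut), m, 4)
  counts_wt <- matrix(as.integer(counts_wt), m, 4)
  if (any(counts_mut < 0, na.rm = TRUE) || any(counts_wt < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  colnames(counts_mut) <- paste0("mut_", BASES)
  colnames(counts_wt) <- paste0("wt_", BASES)
  mut_dp <- as.integer(rowSums(counts_mut))
  wt_dp <- as.integer(rowSums(counts_wt))
  fmut <- counts_mut / ifelse(mut_dp > 0, mut_dp, NA_integer_)
  fwt <- counts_wt / ifelse(wt_dp > 0, wt_dp, NA_integer_)
  colnames(fmut) <- paste0("fmut_", BASES)
  colnames(fwt) <- paste0("fwt_", BASES)
  out <- data.frame(snp_id = paste0(chrom, "_", pos),
                    chrom = as.character(chrom), pos = as.integer(pos),
                    ref = as.character(ref), alt = as.character(alt),
                    site_type = rep_len(site_type, m),
                    counts_mut, counts_wt, mut_dp = mut_dp, wt_dp = wt_dp,
                    fmut, fwt,
                    zero_depth = mut_dp == 0L | wt_dp == 0L,
                    qd = rep_len(as.numeric(qd), m),
                    fs = rep_len(as.numeric(fs), m),
                    mq = rep_len(as.numeric(mq), m),
                    stringsAsFactors = FALSE)
  class(out) <- c("pool_site_counts", "data.frame")
  out
}

#' Extract a pool's nucleotide frequency matrix
#'
#' @param counts a `pool_site_counts` table.
#' @param pool `"mut"` or `"wt"`.
#' @param what `"freq"` (default) or `"count"`.
#' @return Numeric matrix, sites x 4 (A,C,G,T).
#' @export
pool_freqs <- function(counts, pool = c("mut", "wt"), what = c("freq", "count")) {
  pool <- match.arg(pool)
  what <- match.arg(what)
  pre <- if (what == "freq") paste0("f", pool, "_") else paste0(pool, "_")
  as.matrix(counts[, paste0(pre, BASES)])
}
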