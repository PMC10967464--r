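# Coding-consequence prediction: apply an SNV/indel to a spliced CDS,
# translate with the standard genetic code, and report frameshift, premature
# stop, truncation and protein-domain disruption.

#' Apply a variant to a spliced CDS
#'
#' Coordinates are 1-based within the spliced CDS (use [cds_position()] to
#' map a genomic variant, strand-aware). VCF-style alleles work directly: a
#' deletion is `ref` longer than `alt`, an insertion the reverse. A deletion
#' running past the CDS end is truncated to the CDS bounds and flagged with
#' attribute `clipped = TRUE` (with a warning).
#'
#' @param cds CDS sequence (character, ACGT).
#' @param pos 1-based position of the first `ref` base within the CDS.
#' @param ref,alt reference and alternate alleles.
#' @return The mutated CDS (character); attribute `clipped` marks boundary
#'   truncation.
#' @examples
#' apply_variant_to_cds("ATGAAAGCTAGCGGATGA", 7, "AGC", "A")
#' @export
apply_variant_to_cds <- function(cds, pos, ref, alt) {
  n <- nchar(cds)
  if (pos < 1L || pos > n) stop("position outside CDS: ", pos)
  clipped <- FALSE
  if (pos + nchar(ref) - 1L > n) {
    warning("variant overlaps the CDS end; truncated to CDS bounds")
    ref <- substr(ref, 1L, n - pos + 1L)
    clipped <- TRUE
  }
  found <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (found != ref)
    stop("ref allele mismatch at CDS position ", pos, ": expected ", ref,
         ", found ", found)
  out <- paste0(substr(cds, 1L, pos - 1L), alt,
                substring(cds, pos + nchar(ref)))
  attr(out, "clipped") <- clipped
  out
}

#' Translate a CDS with the standard genetic code
#'
#' Translation stops at (and excludes) the first stop codon. Incomplete
#' trailing codons are reported, not translated. `N` is allowed and yields an
#' `X` residue; any other non-ACGT symbol is an error.
#'
#' @param cds CDS sequence (character, length >= 3).
#' @return list: `peptide` (character), `stop_codon` (the stop triplet or
#'   `NA` when no stop is reached), `stop_index` (codon index of the stop, or
#'   `NA`), `trailing` (count of untranslated bases after the stop or at the
#'   end).
#' @examples
#' translate_cds("ATGAAAGCTAGCGGATGA")  # MKASG, stop TGA
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  if (grepl("[^ACGTN]", cds)) stop("non-ACGTN symbol in CDS")
  n_codons <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * (seq_len(n_codons) - 1L) + 1L,
                      3L * seq_len(n_codons))
  aa <- vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
  stop_at <- which(aa == "*")[1]
  if (!is.na(stop_at)) {
    list(peptide = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stop_codon = codons[stop_at], stop_index = stop_at,
         trailing = nchar(cds) - 3L * stop_at)
  } else {
    list(peptide = paste(aa, collapse = ""), stop_codon = NA_character_,
         stop_index = NA_integer_, trailing = nchar(cds) %% 3L)
  }
}

#' Protein domain intervals
#'
#' @param label domain names.
#' @param start_aa,end_aa 1-based inclusive amino-acid coordinates on the
#'   original protein.
#' @return data.frame of domain intervals.
#' @export
domain_intervals <- function(label, start_aa, end_aa) {
  if (any(start_aa < 1) || any(end_aa < start_aa))
    stop("domain intervals require 1 <= start_aa <= end_aa")
  data.frame(label = as.character(label), start_aa = as.integer(start_aa),
             end_aa = as.integer(end_aa), stringsAsFactors = FALSE)
}

#' Classify the coding consequence of a variant
#'
#' Compares the original and mutated CDS: a net length change not divisible
#' by 3 is a frameshift; a stop codon with further codons after it in the
#' mutated CDS is a premature stop, while a stop falling on the final codon
#' (as after an in-frame codon deletion) is the ordinary terminator; an
#' original stop never reached is "lost". Domains are disrupted when truncated — their span intersects
#' `[truncation point, original protein end]` — or when they contain a
#' residue altered by a frameshift; in-frame missense changes inside a domain
#' are reported separately as `domain_variants`.
#'
#' @param original,mutated CDS sequences (characters).
#' @param domains optional [domain_intervals()] on the original protein.
#' @return A `consequence_report` list: `cds_effect` ("in-frame" or
#'   "frameshift"), `stop_status` ("none", "premature", "lost"),
#'   `stop_codon`, `stop_codon_index`, `original_length`, `mutant_length`
#'   (aa), `altered_residues`, `disrupted_domains`, `domain_variants`.
#' @examples
#' classify_consequence("ATGAAAGCTAGCGGATGA", "ATGAAATAGCGGATGA")
#' @export
classify_consequence <- function(original, mutated, domains = NULL) {
  shift <- (nchar(mutated) - nchar(original)) %% 3L != 0L
  tr_o <- translate_cds(original)
  tr_m <- translate_cds(mutated)
  len_o <- nchar(tr_o$peptide)
  len_m <- nchar(tr_m$peptide)
  stop_o <- if (is.na(tr_o$stop_index)) Inf else tr_o$stop_index
  stop_m <- if (is.na(tr_m$stop_index)) Inf else tr_m$stop_index
  # a stop is premature when codons remain after it in the mutated CDS; the
  # terminal codon of an in-frame-shortened CDS is the ordinary stop
  stop_status <- if (is.finite(stop_o) && !is.finite(stop_m)) "lost"
    else if (is.finite(stop_m) && stop_m < nchar(mutated) %/% 3L) "premature"
    else "none"
  pmin_len <- min(len_o, len_m)
  altered <- if (pmin_len)
    which(strsplit(substr(tr_o$peptide, 1, pmin_len), "")[[1]] !=
            strsplit(substr(tr_m$peptide, 1, pmin_len), "")[[1]])
  else integer(0)
  disrupted <- character(0)
  domain_variants <- character(0)
  if (!is.null(domains) && nrow(domains)) {
    trunc_point <- if (len_m < len_o) len_m + 1L else Inf
    truncated <- is.finite(trunc_point) & domains$end_aa >= trunc_point
    has_alt <- vapply(seq_len(nrow(domains)), function(i)
      any(altered >= domains$start_aa[i] & altered <= domains$end_aa[i]),
      logical(1))
    disrupted <- domains$label[truncated | (shift & has_alt)]
    domain_variants <- setdiff(domains$label[!shift & has_alt], disrupted)
  }
  structure(list(cds_effect = if (shift) "frameshift" else "in-frame",
                 stop_status = stop_status,
                 stop_codon = tr_m$stop_codon,
                 stop_codon_index = tr_m$stop_index,
                 original_length = len_o, mutant_length = len_m,
                 altered_residues = altered,
                 disrupted_domains = disrupted,
                 domain_variants = domain_variants),
            class = "consequence_report")
}

#' @export
print.consequence_report <- function(x, ...) {
  cat("coding consequence:", x$cds_effect, "| stop:", x$stop_status)
  if (x$stop_status == "premature")
    cat(" (", x$stop_codon, " at codon ", x$stop_codon_index, ")", sep = "")
  cat("\nprotein:", x$original_length, "aa ->", x$mutant_length, "aa\n")
  if (length(x$disrupted_domains))
    cat("disrupted domains:", paste(x$disrupted_domains, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the coding consequence of a genomic variant
#'
#' Maps a genomic variant into a gene model's spliced CDS (strand-aware; on
#' the minus strand the alleles are reverse-complemented), applies it and
#' classifies the consequence.
#'
#' @param model a [gene_model()].
#' @param genome `DNAStringSet`.
#' @param pos genomic position of the first `ref` base.
#' @param ref,alt alleles on the forward genomic strand.
#' @param domains optional [domain_intervals()].
#' @return A `consequence_report` (see [classify_consequence()]).
#' @export
consequence_for_gene <- function(model, genome, pos, ref, alt, domains = NULL) {
  cds <- cds_sequence(model, genome)
  if (model$strand == "-") {
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # map the LAST ref base (5'-most on the minus strand) into the CDS
    cpos <- cds_position(model, pos + nchar(ref) - 1L)
    ref <- rc(ref)
    alt <- rc(alt)
  } else {
    cpos <- cds_position(model, pos)
  }
  if (is.na(cpos)) stop("variant does not fall in the CDS of ", model$gene_id)
  mutated <- apply_variant_to_cds(cds, cpos, ref, alt)
  classify_consequence(cds, mutated, domains)
}
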