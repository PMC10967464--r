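# The mapping core: per-SNP Euclidean distance between the two pools'
# nucleotide-frequency vectors, power transform, Lowess smoothing per
# chromosome, genome-wide quantile threshold and candidate-region calling.

#' Euclidean distance between pool nucleotide frequencies
#'
#' ed = sqrt(sum_b (f_mut,b - f_wt,b)^2) over the four nucleotides. Ranges
#' from 0 (identical pools) to sqrt(2) (pools fixed for different alleles)
#' and is symmetric in pool order.
#'
#' @param freq_mut,freq_wt frequency 4-vectors (A,C,G,T) or matrices with 4
#'   columns (one row per site); each row must sum to 1.
#' @return Numeric vector of distances.
#' @examples
#' compute_ed(c(0, 1, 0, 0), c(0.93, 0.07, 0, 0))  # 0.93 * sqrt(2)
#' @export
compute_ed <- function(freq_mut, freq_wt) {
  if (is.null(dim(freq_mut))) freq_mut <- matrix(freq_mut, nrow = 1)
  if (is.null(dim(freq_wt))) freq_wt <- matrix(freq_wt, nrow = 1)
  if (ncol(freq_mut) != 4L || ncol(freq_wt) != 4L ||
      nrow(freq_mut) != nrow(freq_wt))
    stop("frequency inputs must be 4-vectors or n x 4 matrices")
  ok <- stats::complete.cases(freq_mut) & stats::complete.cases(freq_wt)
  bad_sum <- ok & (abs(rowSums(freq_mut) - 1) > 1e-6 |
                     abs(rowSums(freq_wt) - 1) > 1e-6)
  if (any(bad_sum)) stop("frequency vectors must sum to 1")
  out <- sqrt(rowSums((freq_mut - freq_wt)^2))
  out[!ok] <- NA_real_
  out
}

#' Raise the scan statistic to a power
#'
#' Amplifies strong allele-segregation signals and suppresses background
#' noise; order-preserving, so the scan's argmax is unchanged.
#'
#' @param ed Euclidean distances.
#' @param k integer power >= 1 (default 4).
#' @return `ed^k`.
#' @export
power_transform <- function(ed, k = 4) {
  if (length(k) != 1L || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  ed^k
}

#' Locally weighted regression (Lowess) smoothing
#'
#' Classic Cleveland smoother: for each point, a weighted least-squares line
#' is fitted over its `ceiling(span * n)` nearest neighbours with tricube
#' weights and evaluated at the point. `robust_iters` bisquare re-weighting
#' passes (residual scale 6 x median absolute residual) downweight outliers.
#'
#' @param x abscissa (e.g. physical position); need not be sorted.
#' @param y response values.
#' @param span neighbourhood fraction, 0 < span <= 1.
#' @param robust_iters number of robustness iterations (>= 0).
#' @return Fitted values at `x`, in input order.
#' @export
lowess_fit <- function(x, y, span = 0.1, robust_iters = 2) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2L) stop("need at least 2 points")
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  q <- as.integer(ceiling(span * n))
  if (q < 2L) stop("span yields fewer than 2 neighbours")
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in seq_len(robust_iters + 1L)) {
    lo <- 1L
    hi <- q
    for (i in seq_len(n)) {
      # slide the q-nearest window along the sorted abscissa
      while (hi < n && xs[i] - xs[lo] > xs[hi + 1L] - xs[i]) {
        lo <- lo + 1L
        hi <- hi + 1L
      }
      idx <- lo:hi
      d <- abs(xs[idx] - xs[i])
      h <- max(d)
      w <- if (h > 0) (1 - pmin(d / h, 1)^3)^3 else rep(1, length(idx))
      w <- w * rw[idx]
      sw <- sum(w)
      if (sw <= 0) {              # all neighbours downweighted to zero
        fit[i] <- ys[i]
        next
      }
      xm <- sum(w * xs[idx]) / sw
      ym <- sum(w * ys[idx]) / sw
      dx <- xs[idx] - xm
      sxx <- sum(w * dx * dx)
      b <- if (sxx > 1e-12 * h^2 && h > 0) sum(w * dx * (ys[idx] - ym)) / sxx else 0
      fit[i] <- ym + b * (xs[i] - xm)
    }
    if (it <= robust_iters) {
      res <- ys - fit
      s <- stats::median(abs(res))
      if (s <= 0) break           # perfect fit: nothing to re-weight
      rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
    }
  }
  fit[order(ord)]
}

#' Genome-wide quantile threshold on the raw statistic
#'
#' Empirical q-quantile with linear interpolation between order statistics
#' (type 7). The 0.5% tail is sensitive to the interpolation convention, so
#' it is fixed here and documented.
#'
#' @param ed raw per-SNP Euclidean distances, whole genome (`NA` dropped).
#' @param q quantile level in (0, 1); default 0.995, i.e. the top 0.5%.
#' @return The threshold.
#' @export
quantile_threshold <- function(ed, q = 0.995) {
  ed <- ed[!is.na(ed)]
  if (!length(ed)) stop("empty scan: no Euclidean distances")
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  unname(stats::quantile(ed, probs = q, type = 7))
}

#' Run the Euclidean-distance genome scan
#'
#' Computes per-SNP ED from a site-count table, raises it to the power `k`,
#' smooths the powered values per chromosome with [lowess_fit()] against
#' physical position (or SNP index with `x_index = TRUE`) and sets the
#' genome-wide threshold at the `q`-quantile of the raw ED. Indels are never
#' scored; multiallelic records are excluded unless `keep_multiallelic`;
#' zero-depth sites are skipped with a logged count.
#'
#' @param counts a [pool_site_counts()] table (apply [hard_filter_counts()]
#'   first if quality annotations are available).
#' @param k power transform (default 4).
#' @param q threshold quantile on raw ED (default 0.995).
#' @param span,robust_iters Lowess parameters (defaults 0.1 and 2).
#' @param keep_multiallelic score multiallelic SNP records too.
#' @param x_index smooth against SNP index instead of physical position.
#' @return An `ed_scan` data.frame (`snp_id`, `chrom`, `pos`, `ed`, `ed_k`,
#'   `smoothed`) with attributes `threshold`, `k`, `q`, `span`,
#'   `n_skipped_zero_depth`.
#' @export
ed_scan <- function(counts, k = 4, q = 0.995, span = 0.1, robust_iters = 2,
                    keep_multiallelic = FALSE, x_index = FALSE) {
  keep_type <- c("snp", if (keep_multiallelic) "multiallelic")
  n_zero <- sum(counts$zero_depth & counts$site_type %in% keep_type)
  use <- counts$site_type %in% keep_type & !counts$zero_depth
  if (n_zero > 0)
    message("ed_scan: skipping ", n_zero, " zero-depth site(s)")
  sub <- counts[use, , drop = FALSE]
  if (!nrow(sub)) stop("no scorable SNP sites")
  ed <- compute_ed(pool_freqs(sub, "mut"), pool_freqs(sub, "wt"))
  ed_k <- power_transform(ed, k)
  smoothed <- numeric(length(ed))
  for (cc in unique(sub$chrom)) {
    i <- which(sub$chrom == cc)
    xx <- if (x_index) seq_along(i) else sub$pos[i]
    smoothed[i] <- lowess_fit(xx, ed_k[i], span = span,
                              robust_iters = robust_iters)
  }
  out <- data.frame(snp_id = sub$snp_id, chrom = sub$chrom, pos = sub$pos,
                    ed = ed, ed_k = ed_k, smoothed = smoothed,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- quantile_threshold(ed, q)
  attr(out, "k") <- k
  attr(out, "q") <- q
  attr(out, "span") <- span
  attr(out, "n_skipped_zero_depth") <- n_zero
  class(out) <- c("ed_scan", "data.frame")
  out
}

#' Threshold of an ED scan
#'
#' @param scan an `ed_scan`.
#' @param powered return the threshold raised to the scan's power `k`, the
#'   scale on which the smoothed curve is compared.
#' @return The threshold on the requested scale.
#' @export
scan_threshold <- function(scan, powered = FALSE) {
  th <- attr(scan, "threshold")
  if (powered) th^attr(scan, "k") else th
}

#' Call candidate regions from a smoothed scan
#'
#' A candidate region is a maximal run of consecutive SNPs (within one
#' chromosome) whose smoothed powered statistic strictly exceeds the
#' threshold raised to the same power. Runs with fewer than `min_snps`
#' members are dropped. Regions are ranked by their peak smoothed value.
#'
#' @param scan an `ed_scan`.
#' @param min_snps minimum SNPs per region (default 10).
#' @return data.frame of regions: `region_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `peak_position`, `peak_smoothed`, `snp_ids`
#'   (comma-separated), ordered by decreasing `peak_smoothed`.
#' @export
call_regions <- function(scan, min_snps = 10) {
  thr_k <- scan_threshold(scan, powered = TRUE)
  out <- list()
  for (cc in unique(scan$chrom)) {
    s <- scan[scan$chrom == cc, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    above <- s$smoothed > thr_k
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      idx <- starts[j]:ends[j]
      if (length(idx) < min_snps) next
      pk <- idx[which.max(s$smoothed[idx])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start = s$pos[idx[1]], end = s$pos[idx[length(idx)]],
        n_snps = length(idx), peak_position = s$pos[pk],
        peak_smoothed = s$smoothed[pk],
        snp_ids = paste(s$snp_id[idx], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), peak_position = integer(0),
                      peak_smoothed = numeric(0), snp_ids = character(0),
                      stringsAsFactors = FALSE))
  regions <- do.call(rbind, out)
  regions <- regions[order(-regions$peak_smoothed), , drop = FALSE]
  regions <- cbind(region_id = paste0("region_", seq_len(nrow(regions))),
                   regions, stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  regions
}

#' Region length in megabases
#'
#' @param start,end 1-based region boundaries (bp); a regions data.frame from
#'   [call_regions()] may be given as `start`.
#' @return `(end - start) / 1e6`, rounded to 3 decimals.
#' @examples
#' region_length_mb(242173, 1177784)  # 0.936
#' @export
region_length_mb <- function(start, end = NULL) {
  if (is.data.frame(start)) {
    end <- start$end
    start <- start$start
  }
  if (any(end < start)) stop("end must be >= start")
  round((end - start) / 1e6, 3)
}
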