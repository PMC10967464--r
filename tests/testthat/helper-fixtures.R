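# Fixtures are built in code at test time; nothing binary is shipped.

# -- hand-built two-gene reference ------------------------------------------
# chrF carries a plus-strand gene whose spliced CDS is the 18-nt worked
# example ATGAAAGCTAGCGGATGA split over two exons, and chrR the same CDS on
# the minus strand. Everything else is a fixed non-coding filler.

worked_cds <- "ATGAAAGCTAGCGGATGA"

fixture_reference <- function() {
  filler <- strrep("C", 120)
  plus <- filler
  substr(plus, 21, 29) <- substr(worked_cds, 1, 9)    # exon 1
  substr(plus, 41, 49) <- substr(worked_cds, 10, 18)  # exon 2
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  minus <- filler
  # minus-strand CDS: genomic exon order reversed, sequence reverse-complemented
  substr(minus, 21, 29) <- rc(substr(worked_cds, 10, 18))
  substr(minus, 41, 49) <- rc(substr(worked_cds, 1, 9))
  genome <- Biostrings::DNAStringSet(c(chrF = plus, chrR = minus))
  ivl <- data.frame(start = c(21L, 41L), end = c(29L, 49L))
  models <- list(
    gP.t1 = gene_model("gP", "chrF", "+", exons = ivl, cds = ivl,
                       annotation = "plus-strand worked gene"),
    gM.t1 = gene_model("gM", "chrR", "-", exons = ivl, cds = ivl,
                       annotation = "minus-strand worked gene"))
  list(genome = genome, models = models)
}

# -- small simulated cross ---------------------------------------------------

tiny_map <- function(n_chrom = 2, chrom_length = 2e5, spacing = 5e3)
  default_marker_map(n_chrom, chrom_length, spacing)

tiny_config <- function(seed = 7, ...)
  cross_config(causal_chrom = "chr1", causal_pos = 1e5, seed = seed, ...)

# -- inline VCF fixture ------------------------------------------------------
# AD-only two-pool VCF with a clean SNP, a zero-depth record, an indel and a
# multiallelic record.

write_fixture_vcf <- function(path, extra_samples = FALSE) {
  samples <- if (extra_samples) "MUT1\tMUT2\tWT1\tWT2" else "MUT\tWT"
  body <- if (extra_samples) c(
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT:AD\t.:0,10\t.:0,20\t.:18,1\t.:10,1"
  ) else c(
    "chr1\t100\t.\tA\tC\t.\tPASS\tQD=20.0;FS=1.0;MQ=55.0\tGT:AD\t.:0,30\t.:28,2",
    "chr1\t200\t.\tG\tT\t.\tPASS\tQD=3.0;FS=1.0;MQ=55.0\tGT:AD\t.:0,0\t.:15,15",
    "chr1\t300\t.\tGA\tG\t.\tPASS\t.\tGT:AD\t.:12,13\t.:20,5",
    "chr1\t400\t.\tT\tA,G\t.\tPASS\t.\tGT:AD\t.:10,5,5\t.:20,0,0")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"qd\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"fs\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"mq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", samples),
    body), path)
  path
}

# brute-force per-point Lowess oracle: explicit q-nearest-neighbour tricube
# weighted lm at every point, with Cleveland bisquare robustness passes
lowess_oracle <- function(x, y, span, robust_iters = 0) {
  n <- length(x)
  q <- ceiling(span * n)
  rw <- rep(1, n)
  fit <- numeric(n)
  for (it in seq_len(robust_iters + 1)) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      idx <- order(d)[seq_len(q)]
      h <- max(d[idx])
      w <- if (h > 0) (1 - pmin(d[idx] / h, 1)^3)^3 else rep(1, q)
      w <- w * rw[idx]
      if (sum(w) == 0) {
        fit[i] <- y[i]
        next
      }
      if (sum(w > 0) == 1L || stats::var(x[idx][w > 0]) == 0) {
        fit[i] <- sum(w * y[idx]) / sum(w)
      } else {
        fm <- stats::lm(yy ~ xx, weights = w,
                        data = data.frame(yy = y[idx], xx = x[idx]))
        fit[i] <- unname(stats::coef(fm)[1] + stats::coef(fm)[2] * x[i])
      }
    }
    if (it <= robust_iters) {
      res <- y - fit
      s <- stats::median(abs(res))
      if (s <= 0) break
      rw <- (1 - pmin(abs(res) / (6 * s), 1)^2)^2
    }
  }
  fit
}

# assemble a fake ed_scan object from bare vectors (for region-calling tests)
fake_scan <- function(chrom, pos, smoothed, threshold, k = 1, ed = smoothed) {
  s <- data.frame(snp_id = paste0(chrom, "_", pos), chrom = chrom, pos = pos,
                  ed = ed, ed_k = ed^k, smoothed = smoothed,
                  stringsAsFactors = FALSE)
  attr(s, "threshold") <- threshold
  attr(s, "k") <- k
  attr(s, "q") <- 0.995
  class(s) <- c("ed_scan", "data.frame")
  s
}
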