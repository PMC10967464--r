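# ---- marker map ------------------------------------------------------------

#' Marker map for a simulated cross
#'
#' A marker map lists the biallelic SNP markers that will segregate in the
#' simulated cross: their chromosome, physical position and the local
#' recombination rate used to convert physical to genetic distance.
#'
#' @param chrom character vector of chromosome labels, one per marker.
#' @param pos integer vector of 1-based physical positions (bp); strictly
#'   increasing within each chromosome.
#' @param rate_cM_per_Mb recombination rate, either a single value applied to
#'   every chromosome or a named vector with one entry per chromosome label.
#'   Honeybees recombine at an unusually high rate; the default is 20 cM/Mb.
#' @return A `marker_map` object: a data.frame with columns `chrom` and `pos`
#'   and a `rates` attribute (named, cM/Mb per chromosome). Columns `ref` and
#'   `alt` are added later by [assign_map_alleles()].
#' @seealso [default_marker_map()] for the grid used throughout the package.
#' @export
marker_map <- function(chrom, pos, rate_cM_per_Mb = 20) {
  stopifnot(length(chrom) == length(pos), length(pos) >= 2)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  chroms <- unique(chrom)
  if (length(rate_cM_per_Mb) == 1L && is.null(names(rate_cM_per_Mb))) {
    rates <- stats::setNames(rep(as.numeric(rate_cM_per_Mb), length(chroms)), chroms)
  } else {
    if (!all(chroms %in% names(rate_cM_per_Mb)))
      stop("rate_cM_per_Mb must name every chromosome in the map")
    rates <- rate_cM_per_Mb[chroms]
  }
  if (any(rates <= 0)) stop("genetic rate must be > 0")
  for (cc in chroms) {
    p <- pos[chrom == cc]
    if (length(p) < 2L) stop("at least 2 markers required per chromosome: ", cc)
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing on ", cc)
  }
  mp <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  attr(mp, "rates") <- rates
  class(mp) <- c("marker_map", "data.frame")
  mp
}

#' Default marker grid: evenly spaced SNPs on equal-length chromosomes
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param spacing marker spacing in bp (default one SNP per 10 kb).
#' @param rate_cM_per_Mb recombination rate passed to [marker_map()].
#' @return A `marker_map`.
#' @export
default_marker_map <- function(n_chrom = 3, chrom_length = 10e6, spacing = 1e4,
                               rate_cM_per_Mb = 20) {
  pos1 <- seq(as.integer(spacing), as.integer(chrom_length), by = as.integer(spacing))
  marker_map(chrom = rep(paste0("chr", seq_len(n_chrom)), each = length(pos1)),
             pos = rep(pos1, n_chrom), rate_cM_per_Mb = rate_cM_per_Mb)
}

map_rates <- function(map) attr(map, "rates")

# ---- cross configuration ---------------------------------------------------

#' Configuration of the simulated single-queen haplodiploid cross
#'
#' Describes the genetic design being emulated: a single heterozygous queen
#' whose unfertilised eggs develop into haploid drones, each drone one
#' recombinant gamete. Drones are phenotyped by the allele they carry at the
#' causal locus and pooled by phenotype; each pool is then sequenced at finite
#' depth with base-call error.
#'
#' @param causal_chrom,causal_pos location of the causal marker; must coincide
#'   with a marker of the map used for simulation.
#' @param n_mut_pool,n_wt_pool pool sizes (default 15 + 15 drones).
#' @param mean_depth expected read depth per site per pool (Poisson mean).
#' @param error_rate per-base miscall probability, redistributed uniformly over
#'   the other three nucleotides. Must satisfy 0 <= error_rate < 0.25.
#' @param phenotyping_error probability that a drone is assigned to the wrong
#'   pool (0 <= p < 0.5).
#' @param n_mislabeled_wt fixed-contamination preset: this many drones of
#'   the wild-type pool are forced to be causal-allele carriers (1 of 15 gives
#'   the 0.07 wild-type carrier frequency pattern).
#' @param seed random seed consumed by [simulate_cross()].
#' @return A `cross_config` list.
#' @export
cross_config <- function(causal_chrom = "chr1", causal_pos = 5e6,
                         n_mut_pool = 15, n_wt_pool = 15,
                         mean_depth = 30, error_rate = 0.001,
                         phenotyping_error = 0, n_mislabeled_wt = 0L,
                         seed = NULL) {
  if (n_mut_pool < 1 || n_wt_pool < 1) stop("pools must have >= 1 drone")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  if (phenotyping_error < 0 || phenotyping_error >= 0.5)
    stop("phenotyping_error must be in [0, 0.5)")
  if (mean_depth < 0) stop("mean_depth must be >= 0")
  if (n_mislabeled_wt < 0 || n_mislabeled_wt > n_wt_pool)
    stop("n_mislabeled_wt must be between 0 and n_wt_pool")
  structure(list(causal_chrom = as.character(causal_chrom),
                 causal_pos = as.integer(causal_pos),
                 n_mut_pool = as.integer(n_mut_pool),
                 n_wt_pool = as.integer(n_wt_pool),
                 mean_depth = mean_depth, error_rate = error_rate,
                 phenotyping_error = phenotyping_error,
                 n_mislabeled_wt = as.integer(n_mislabeled_wt),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "cross_config")
}

#' Read a cross configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [cross_config()].
#' @return A `cross_config`.
#' @export
read_cross_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cross_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(cross_config, vals)
}

# ---- recombination ---------------------------------------------------------

#' Haldane map function
#'
#' Converts a genetic distance to a recombination fraction assuming no
#' crossover interference: r = 0.5 (1 - exp(-2 d)) with d in Morgans.
#'
#' @param distance_cM genetic distance in centiMorgans (vectorised, >= 0).
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_recomb_fraction(c(0, 10, 1000))
#' @export
haldane_recomb_fraction <- function(distance_cM) {
  if (any(distance_cM < 0)) stop("genetic distance must be >= 0")
  0.5 * (1 - exp(-2 * distance_cM / 100))
}

# genetic distances (cM) between adjacent markers of one chromosome
adjacent_cM <- function(pos, rate_cM_per_Mb) diff(pos) / 1e6 * rate_cM_per_Mb

#' Simulate gametes of a heterozygous queen along one chromosome
#'
#' The queen carries two haplotypes (0 and 1). A gamete is a Markov walk along
#' the ordered markers: the starting haplotype is Bernoulli(0.5) and the walk
#' switches haplotype between adjacent markers with the Haldane recombination
#' fraction of their genetic distance.
#'
#' @param map a [marker_map()].
#' @param chrom chromosome label to simulate.
#' @param n number of gametes.
#' @return Integer matrix, `n` rows (gametes) by markers, entries 0/1.
#' @export
simulate_gametes <- function(map, chrom, n = 1) {
  stopifnot(inherits(map, "marker_map"))
  sel <- map$chrom == chrom
  if (!any(sel)) stop("chromosome not in map: ", chrom)
  pos <- map$pos[sel]
  r <- haldane_recomb_fraction(adjacent_cM(pos, map_rates(map)[[chrom]]))
  m <- length(pos)
  g <- matrix(0L, n, m)
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  for (j in seq_len(m - 1L)) {
    sw <- stats::rbinom(n, 1L, r[j])
    g[, j + 1L] <- ifelse(sw == 1L, 1L - g[, j], g[, j])
  }
  g
}

# whole-genome gametes: n x nrow(map) matrix, columns in map order
simulate_genomes <- function(map, n) {
  do.call(cbind, lapply(unique(map$chrom), function(cc) simulate_gametes(map, cc, n)))
}

# ---- pools -----------------------------------------------------------------

#' Build phenotype-sorted drone pools
#'
#' Simulates haploid drones until both pool quotas are met. A drone's true
#' phenotype is determined by its allele at the causal marker (allele 1 =
#' mutant); `phenotyping_error` flips the observed phenotype, so a flipped
#' drone lands in the wrong pool. With `n_mislabeled_wt > 0` that many
#' wild-type-pool slots are filled with causal-allele carriers instead,
#' reproducing a fixed-contamination design.
#'
#' @param config a [cross_config()].
#' @param map a [marker_map()] containing the causal marker.
#' @return A `drone_pools` list: `mut` and `wt` integer haplotype matrices
#'   (drones x markers, map order), plus `map` and `config`.
#' @export
build_pools <- function(config, map) {
  stopifnot(inherits(config, "cross_config"), inherits(map, "marker_map"))
  ci <- which(map$chrom == config$causal_chrom & map$pos == config$causal_pos)
  if (length(ci) != 1L)
    stop("causal locus (", config$causal_chrom, ":", config$causal_pos,
         ") must coincide with exactly one map marker")
  n_mut <- config$n_mut_pool
  n_wt <- config$n_wt_pool
  n_wt_true <- n_wt - config$n_mislabeled_wt   # mislabeled slots carry allele 1
  mut <- wt <- NULL
  guard <- 0L
  while (is.null(mut) || nrow(mut) < n_mut + config$n_mislabeled_wt ||
         is.null(wt) || nrow(wt) < n_wt_true) {
    guard <- guard + 1L
    if (guard > 1000L) stop("simulation failed to fill pool quotas")
    g <- simulate_genomes(map, max(2L * (n_mut + n_wt), 32L))
    pheno <- g[, ci]
    if (config$phenotyping_error > 0) {
      flip <- stats::rbinom(nrow(g), 1L, config$phenotyping_error)
      pheno <- ifelse(flip == 1L, 1L - pheno, pheno)
    }
    mut <- rbind(mut, g[pheno == 1L, , drop = FALSE])
    wt <- rbind(wt, g[pheno == 0L, , drop = FALSE])
  }
  pools <- list(
    mut = mut[seq_len(n_mut), , drop = FALSE],
    wt = rbind(wt[seq_len(n_wt_true), , drop = FALSE],
               mut[n_mut + seq_len(config$n_mislabeled_wt), , drop = FALSE]),
    map = map, config = config, causal_index = ci)
  class(pools) <- "drone_pools"
  pools
}

# ---- pooled sequencing -----------------------------------------------------

BASES <- c("A", "C", "G", "T")

# split E errors uniformly over three target bases; vectorised over sites
split_errors3 <- function(E) {
  t1 <- stats::rbinom(length(E), E, 1 / 3)
  t2 <- stats::rbinom(length(E), E - t1, 0.5)
  cbind(t1, t2, E - t1 - t2)
}

# sequence one pool at every marker: 4-column base-count matrix + depth
sequence_one_pool <- function(hap, ref, alt, mean_depth, error_rate) {
  n <- nrow(hap)
  m <- ncol(hap)
  p_alt <- colMeans(hap)                      # each read samples a member uniformly
  depth <- stats::rpois(m, mean_depth)
  alt_true <- stats::rbinom(m, depth, p_alt)
  ref_true <- depth - alt_true
  e_alt <- stats::rbinom(m, alt_true, error_rate)
  e_ref <- stats::rbinom(m, ref_true, error_rate)
  cnt <- matrix(0L, m, 4L, dimnames = list(NULL, BASES))
  idx <- cbind(seq_len(m), match(ref, BASES))
  cnt[idx] <- cnt[idx] + (ref_true - e_ref)
  idx_a <- cbind(seq_len(m), match(alt, BASES))
  cnt[idx_a] <- cnt[idx_a] + (alt_true - e_alt)
  # errors land uniformly on the three bases other than the source base
  for (src in BASES) {
    s <- which(ref == src | alt == src)
    if (!length(s)) next
    from_ref <- ref[s] == src
    E <- ifelse(from_ref, e_ref[s], e_alt[s])
    tgt <- setdiff(BASES, src)
    sp <- split_errors3(E)
    for (k in 1:3) {
      j <- match(tgt[k], BASES)
      cnt[cbind(s, j)] <- cnt[cbind(s, j)] + sp[, k]
    }
  }
  list(counts = cnt, depth = depth)
}

#' Sequence both pools at every marker
#'
#' Per site and pool the read depth is Poisson(`mean_depth`); each read is
#' drawn from a pool member uniformly at random and reports that member's
#' allele, miscalled with probability `error_rate` to one of the other three
#' nucleotides chosen uniformly. Zero-depth sites are emitted with the
#' `zero_depth` flag set; downstream scans must skip them.
#'
#' @param pools a `drone_pools` object from [build_pools()].
#' @param config a [cross_config()]; defaults to the one stored in `pools`.
#' @return A `pool_site_counts` data.frame (see [pool_site_counts()]).
#' @export
sequence_pools <- function(pools, config = pools$config) {
  map <- pools$map
  if (is.null(map$ref)) map <- assign_map_alleles(map)
  sm <- sequence_one_pool(pools$mut, map$ref, map$alt, config$mean_depth, config$error_rate)
  sw <- sequence_one_pool(pools$wt, map$ref, map$alt, config$mean_depth, config$error_rate)
  pool_site_counts(chrom = map$chrom, pos = map$pos, ref = map$ref, alt = map$alt,
                   counts_mut = sm$counts, counts_wt = sw$counts)
}

#' Assign reference and alternate alleles to map markers
#'
#' The reference base is taken from `genome` when supplied (a named
#' `DNAStringSet` covering every marker position), otherwise drawn uniformly;
#' the alternate base is drawn uniformly among the other three. Queen
#' haplotype 0 carries the reference base, haplotype 1 the alternate.
#'
#' @param map a [marker_map()].
#' @param genome optional `Biostrings::DNAStringSet` named by chromosome.
#' @return The map with `ref` and `alt` columns added.
#' @export
assign_map_alleles <- function(map, genome = NULL) {
  if (is.null(genome)) {
    ref <- sample(BASES, nrow(map), replace = TRUE)
  } else {
    ref <- vapply(seq_len(nrow(map)), function(i) {
      as.character(Biostrings::subseq(genome[[map$chrom[i]]], map$pos[i], map$pos[i]))
    }, character(1))
  }
  shift <- sample(1:3, nrow(map), replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  map$ref <- ref
  map$alt <- alt
  map
}

# ---- truth -----------------------------------------------------------------

#' Expected pool allele frequencies at every marker (the truth record)
#'
#' At a marker with recombination fraction r to the causal locus the mutant
#' pool carries the alternate allele with expected frequency
#' (1-e)(1-r) + e r and the wild-type pool with (1-e) r + e (1-r), where e is
#' the effective mislabeling fraction of that pool. Markers on other
#' chromosomes have expectation 0.5 in both pools.
#'
#' @param config a [cross_config()].
#' @param map a [marker_map()].
#' @return A `truth_record` data.frame with columns `chrom`, `pos`,
#'   `r_to_causal`, `exp_freq_mut`, `exp_freq_wt`, plus attributes
#'   `causal_chrom` and `causal_pos`.
#' @export
truth_record <- function(config, map) {
  rates <- map_rates(map)
  on_chr <- map$chrom == config$causal_chrom
  d_cM <- ifelse(on_chr,
                 abs(map$pos - config$causal_pos) / 1e6 * rates[map$chrom],
                 Inf)
  r <- ifelse(is.finite(d_cM), haldane_recomb_fraction(pmin(d_cM, 1e6)), 0.5)
  e_mut <- config$phenotyping_error
  e_wt <- config$phenotyping_error + config$n_mislabeled_wt / config$n_wt_pool
  tr <- data.frame(chrom = map$chrom, pos = map$pos, r_to_causal = r,
                   exp_freq_mut = (1 - e_mut) * (1 - r) + e_mut * r,
                   exp_freq_wt = (1 - e_wt) * r + e_wt * (1 - r),
                   stringsAsFactors = FALSE)
  attr(tr, "causal_chrom") <- config$causal_chrom
  attr(tr, "causal_pos") <- config$causal_pos
  class(tr) <- c("truth_record", "data.frame")
  tr
}

# ---- top-level simulation --------------------------------------------------

#' Simulate a complete phenotype-pooled resequencing experiment
#'
#' Runs the full generator: recombinant gametes of one heterozygous queen,
#' phenotype pooling at the causal locus, and finite-depth pooled sequencing.
#' Consumes `config$seed` (when set) so a given seed reproduces the experiment
#' exactly.
#'
#' @param config a [cross_config()].
#' @param map a [marker_map()]; alleles are assigned with
#'   [assign_map_alleles()] if absent.
#' @param genome optional genome (`DNAStringSet`) fixing reference bases.
#' @return A `cross_sim` list: `counts` (pool_site_counts), `pools`,
#'   `genotypes` (markers x drones 0/1 matrix, columns `mut_i`/`wt_i`),
#'   `truth`, `map`, `config`.
#' @export
simulate_cross <- function(config, map = default_marker_map(), genome = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(map$ref)) map <- assign_map_alleles(map, genome)
  pools <- build_pools(config, map)
  pools$map <- map
  counts <- sequence_pools(pools, config)
  gt <- t(rbind(pools$mut, pools$wt))
  colnames(gt) <- c(paste0("mut_", seq_len(config$n_mut_pool)),
                    paste0("wt_", seq_len(config$n_wt_pool)))
  rownames(gt) <- paste0(map$chrom, "_", map$pos)
  sim <- list(counts = counts, pools = pools, genotypes = gt,
              truth = truth_record(config, map), map = map, config = config)
  class(sim) <- "cross_sim"
  sim
}

#' @export
print.cross_sim <- function(x, ...) {
  cat("haplodiploid cross simulation:",
      x$config$n_mut_pool, "mutant +", x$config$n_wt_pool, "wild-type drones,",
      nrow(x$map), "markers on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("causal locus:", x$config$causal_chrom, "at", x$config$causal_pos, "bp\n")
  invisible(x)
}
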