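test_that("Haldane map function matches its closed form", {
  expect_identical(haldane_recomb_fraction(0), 0)
  expect_equal(haldane_recomb_fraction(10), 0.5 * (1 - exp(-0.2)), tolerance = 1e-12)
  expect_equal(haldane_recomb_fraction(10), 0.0906, tolerance = 1e-3)
  expect_equal(haldane_recomb_fraction(1000), 0.5, tolerance = 1e-6)
  d <- seq(0, 300, by = 0.5)
  expect_true(all(diff(haldane_recomb_fraction(d)) > 0))
  expect_error(haldane_recomb_fraction(-1), "distance")
})

test_that("gamete simulation switches haplotype at the Haldane rate", {
  # adjacent markers 10 cM apart (0.5 Mb at 20 cM/Mb)
  map <- marker_map(c("c1", "c1"), c(1L, 500001L), rate_cM_per_Mb = 20)
  set.seed(11)
  g <- simulate_gametes(map, "c1", n = 10000)
  r <- haldane_recomb_fraction(10)
  obs <- mean(g[, 1] != g[, 2])
  expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / 10000))
  # start haplotype is fair
  expect_lt(abs(mean(g[, 1]) - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("markers at ~zero genetic distance co-segregate and seeds reproduce", {
  map <- marker_map(c("c1", "c1"), c(1L, 2L), rate_cM_per_Mb = 1e-6)
  set.seed(2)
  g <- simulate_gametes(map, "c1", n = 1000)
  expect_true(all(g[, 1] == g[, 2]))
  set.seed(99)
  g1 <- simulate_gametes(tiny_map(), "chr1", n = 5)
  set.seed(99)
  g2 <- simulate_gametes(tiny_map(), "chr1", n = 5)
  expect_identical(g1, g2)
})

test_that("pools are sorted by causal allele when phenotyping is perfect", {
  map <- tiny_map()
  cfg <- tiny_config()
  set.seed(cfg$seed)
  pools <- build_pools(cfg, map)
  ci <- pools$causal_index
  expect_identical(nrow(pools$mut), cfg$n_mut_pool)
  expect_identical(nrow(pools$wt), cfg$n_wt_pool)
  expect_true(all(pools$mut[, ci] == 1L))
  expect_true(all(pools$wt[, ci] == 0L))
})

test_that("mutant-pool allele counts at a linked marker follow 15(1-r)", {
  # two markers, 10 cM apart: causal and one linked
  map <- marker_map(c("c1", "c1"), c(1L, 500001L), rate_cM_per_Mb = 20)
  cfg <- cross_config(causal_chrom = "c1", causal_pos = 1)
  r <- haldane_recomb_fraction(10)
  set.seed(21)
  counts <- replicate(200, sum(build_pools(cfg, map)$mut[, 2]))
  se <- sqrt(15 * r * (1 - r) / 200)
  expect_lt(abs(mean(counts) - 15 * (1 - r)), 3 * se)
})

test_that("mislabeled wild-type drones carry the causal allele", {
  map <- tiny_map()
  cfg <- tiny_config(n_mislabeled_wt = 1)
  set.seed(5)
  pools <- build_pools(cfg, map)
  expect_identical(sum(pools$wt[, pools$causal_index]), 1L)
  expect_true(all(pools$mut[, pools$causal_index] == 1L))
})

test_that("error-free sequencing of a fixed pool returns pure alt reads", {
  map <- assign_map_alleles(tiny_map())
  cfg <- tiny_config(error_rate = 0)
  pools <- structure(list(mut = matrix(1L, 15, nrow(map)),
                          wt = matrix(0L, 15, nrow(map)),
                          map = map, config = cfg), class = "drone_pools")
  set.seed(3)
  cts <- sequence_pools(pools, cfg)
  ai <- cbind(seq_len(nrow(cts)), match(cts$alt, c("A", "C", "G", "T")))
  expect_identical(pool_freqs(cts, "mut", "count")[ai], cts$mut_dp)
  ri <- cbind(seq_len(nrow(cts)), match(cts$ref, c("A", "C", "G", "T")))
  expect_identical(pool_freqs(cts, "wt", "count")[ri], cts$wt_dp)
})

test_that("zero mean depth flags every site and scans refuse them", {
  cfg <- tiny_config(mean_depth = 0)
  sim <- simulate_cross(cfg, tiny_map())
  expect_true(all(sim$counts$zero_depth))
  expect_error(ed_scan(sim$counts), "no scorable")
})

test_that("miscall rate matches the error model on a monomorphic pool", {
  n_sites <- 10000
  map <- assign_map_alleles(marker_map(rep("c1", n_sites), seq_len(n_sites),
                                       rate_cM_per_Mb = 20))
  err <- 0.01
  cfg <- cross_config(causal_chrom = "c1", causal_pos = 1, error_rate = err,
                      mean_depth = 30)
  pools <- structure(list(mut = matrix(0L, 15, n_sites),
                          wt = matrix(0L, 15, n_sites),
                          map = map, config = cfg), class = "drone_pools")
  set.seed(13)
  cts <- sequence_pools(pools, cfg)
  cnt <- pool_freqs(cts, "mut", "count")
  ri <- cbind(seq_len(n_sites), match(cts$ref, c("A", "C", "G", "T")))
  total <- sum(cts$mut_dp)
  nonref <- total - sum(cnt[ri])
  expect_lt(abs(nonref / total - err), 3 * sqrt(err * (1 - err) / total))
  # errors reach all three non-reference bases at ref = A sites
  a_sites <- cts$ref == "A"
  expect_true(all(colSums(cnt[a_sites, c("mut_C", "mut_G", "mut_T")]) > 0))
})

test_that("frequencies sum to one and counts are conserved", {
  sim <- simulate_cross(tiny_config(), tiny_map())
  ok <- !sim$counts$zero_depth
  expect_equal(rowSums(pool_freqs(sim$counts, "mut")[ok, ]), rep(1, sum(ok)),
               tolerance = 1e-9)
  expect_equal(rowSums(pool_freqs(sim$counts, "wt")[ok, ]), rep(1, sum(ok)),
               tolerance = 1e-9)
  expect_identical(unname(rowSums(pool_freqs(sim$counts, "mut", "count"))),
                   as.numeric(sim$counts$mut_dp))
})

test_that("truth record matches the analytic linkage-decay expectation", {
  cfg <- tiny_config(phenotyping_error = 0.1)
  tr <- truth_record(cfg, tiny_map())
  at_causal <- tr[tr$chrom == "chr1" & tr$pos == 1e5, ]
  expect_equal(at_causal$exp_freq_mut, 0.9)   # 1 - phenotyping_error
  off <- tr[tr$chrom == "chr2", ]
  expect_true(all(off$exp_freq_mut == 0.5 & off$exp_freq_wt == 0.5))
  expect_true(all(tr$exp_freq_mut >= 0 & tr$exp_freq_mut <= 1))
  # expectation decays monotonically with distance from the causal locus
  right <- tr$chrom == "chr1" & tr$pos >= 1e5
  expect_true(all(diff(tr$exp_freq_mut[right]) <= 0))
})

test_that("mean pool frequencies track 1 - r within 3 SE", {
  map <- tiny_map(n_chrom = 1, chrom_length = 2e5, spacing = 2e4)  # 10 markers
  cfg <- cross_config(causal_chrom = "chr1", causal_pos = 1e5,
                      mean_depth = 30, error_rate = 0)
  n_rep <- 120
  set.seed(31)
  fm <- replicate(n_rep, {
    sim <- simulate_cross(cfg, map)
    ai <- cbind(seq_len(nrow(sim$counts)),
                match(sim$counts$alt, c("A", "C", "G", "T")))
    pool_freqs(sim$counts, "mut")[ai]
  })
  tr <- truth_record(cfg, map)
  obs <- rowMeans(fm)
  # conservative per-marker SE: drone sampling + read sampling
  se <- sqrt((tr$exp_freq_mut * (1 - tr$exp_freq_mut)) * (1 / 15 + 1 / 30) / n_rep)
  expect_true(all(abs(obs - tr$exp_freq_mut) < pmax(3 * se, 1e-3)))
})

test_that("identical seeds give byte-identical emitted files", {
  run <- function() {
    map <- tiny_map(n_chrom = 1, chrom_length = 5e4, spacing = 5e3)
    cfg <- cross_config(causal_chrom = "chr1", causal_pos = 2.5e4, seed = 77)
    sim <- simulate_cross(cfg, map)
    d <- withr::local_tempdir(.local_envir = parent.frame(2))
    emit_truth_and_files(sim, d)
  }
  p1 <- run()
  p2 <- run()
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("configuration invariants are enforced", {
  expect_error(cross_config(error_rate = 0.3), "error_rate")
  expect_error(cross_config(phenotyping_error = 0.6), "phenotyping_error")
  expect_error(cross_config(n_mut_pool = 0), "pools")
  expect_error(marker_map(c("c1", "c1"), c(10, 10)), "strictly increasing")
  expect_error(marker_map(c("c1", "c1"), c(10, 20), rate_cM_per_Mb = 0), "rate")
  expect_error(build_pools(tiny_config(), marker_map(c("cX", "cX"), c(1, 2))),
               "causal locus")
})
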