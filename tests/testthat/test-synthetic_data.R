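test_that("parental divergence controls the AIM fraction (quadrature oracle)", {
  probs <- vapply(c(0.05, 0.2, 0.5), function(f) {
    cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 5000,
                      divergence = f, seed = 31)
    tr <- simulate_parental_frequencies(cfg)
    mean(abs(tr$p1 - tr$p0) >= 0.3)
  }, numeric(1))
  # rises steeply over the low-to-moderate range
  expect_true(all(diff(probs) > 0))
  # near-zero-divergence limit: frequencies nearly identical
  cfg0 <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10000,
                     divergence = 0.005, seed = 32)
  tr0 <- simulate_parental_frequencies(cfg0)
  expect_lt(mean(abs(tr0$p1 - tr0$p0)), 0.05)
  # high divergence matches the analytic Balding-Nichols oracle within
  # 3 binomial SEs
  cfg9 <- sim_config(n_chromosomes = 1, loci_per_chromosome = 10000,
                     divergence = 0.9, seed = 33)
  tr9 <- simulate_parental_frequencies(cfg9)
  obs <- mean(abs(tr9$p1 - tr9$p0) >= 0.3)
  expected <- bn_diff_prob(0.9)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(obs - expected), 3 * se + 0.01)
  # identical seeds give identical tables
  trA <- simulate_parental_frequencies(cfg9)
  expect_identical(trA$p0, tr9$p0)
})

test_that("ancient-hybrid ancestry blocks have the configured run length", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 1000,
                    block_length = 50, seed = 41)
  tr <- simulate_parental_frequencies(cfg)
  set.seed(42)
  anc <- simulate_ancient_hybrid(cfg, tr, n = 40,
                                 q_target = rep(0.5, 1000))
  runs <- unlist(apply(anc$ancestry1, 2, function(z) rle(z)$lengths))
  # end-of-chromosome censoring pulls the observed mean slightly below the
  # nominal 50; allow a generous Monte-Carlo band
  expect_gt(mean(runs), 38)
  expect_lt(mean(runs), 62)
  # run length holds away from q = 0.5 too (the rates are balanced)
  set.seed(43)
  anc8 <- simulate_ancient_hybrid(cfg, tr, n = 40,
                                  q_target = rep(0.8, 1000))
  runs8 <- unlist(apply(anc8$ancestry1, 2, function(z) rle(z)$lengths))
  expect_gt(mean(runs8), 38)
  expect_lt(mean(runs8), 62)
})

test_that("ancient-hybrid realized ancestry tracks the target profile", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 600,
                    block_length = 20, seed = 51)
  tr <- simulate_parental_frequencies(cfg)
  tr$p0[] <- 0; tr$p1[] <- 1  # diagnostic loci
  q_target <- rep(c(0.2, 0.8), each = 300)
  set.seed(52)
  anc <- simulate_ancient_hybrid(cfg, tr, n = 60, q_target = q_target)
  # allele-count q-hat at diagnostic loci within 3 binomial SEs of target
  q_hat <- rowMeans(anc$genotypes) / 2
  se <- sqrt(q_target * (1 - q_target) / (2 * 60))
  # block autocorrelation inflates the variance well beyond binomial;
  # check the block-level means instead of per-locus counts
  expect_lt(abs(mean(q_hat[1:300]) - 0.2), 0.1)
  expect_lt(abs(mean(q_hat[301:600]) - 0.8), 0.1)
  # pure parent-1 limit
  anc1 <- simulate_ancient_hybrid(cfg, tr, n = 5,
                                  q_target = rep(1, 600))
  expect_true(all(anc1$ancestry1 == 1L))
  expect_true(all(anc1$genotypes == 2L))
})

test_that("contemporary-zone ancestry follows the cline function", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 400,
                    h_beta_a = 0.5, h_beta_b = 0.5, seed = 61)
  tr <- simulate_parental_frequencies(cfg)
  tr$p0[] <- 0; tr$p1[] <- 1
  set.seed(62)
  zone <- simulate_contemporary_zone(cfg, tr, n = 120,
                                     alpha = rep(0, 400),
                                     beta = rep(0, 400))
  # neutral clines: realized parent-1 fraction per individual ~ h
  frac <- colMeans(zone$genotypes) / 2
  expect_lt(max(abs(frac - zone$h)), 0.12)
  expect_gt(cor(frac, zone$h), 0.98)
  # U-shaped hybrid-index distribution spans 0-1
  expect_gt(mean(zone$h < 0.2) + mean(zone$h > 0.8), 0.4)
  # beta = +2 steepens the transition around h = 0.5
  set.seed(63)
  zb <- simulate_contemporary_zone(cfg, tr, n = 400,
                                   alpha = rep(0, 400),
                                   beta = rep(2, 400))
  mid <- abs(zb$h - 0.5) < 0.15
  lo <- zb$h < 0.35 & zb$h > 0.05
  # slope oracle from phi: ancestry changes faster than h near the center
  fit_mid <- coef(lm(colMeans(zb$genotypes)[mid] / 2 ~ zb$h[mid]))[2]
  expect_gt(fit_mid, 1.3)  # neutral slope is 1
})

test_that("GBS likelihood generator hits its limiting regimes", {
  loci <- locus_map(paste0("l", 1:200), "c1", seq_len(200))
  geno <- matrix(sample(0:2, 2000, TRUE), 200, 10)
  set.seed(71)
  hi <- simulate_gbs_likelihoods(geno, loci, depth = 400, error = 0)
  map_geno <- apply(hi$gl, c(1, 2), which.max) - 1L
  expect_equal(as.vector(map_geno), as.vector(geno))
  lo <- simulate_gbs_likelihoods(geno, loci, depth = 0.01)
  expect_gt(mean(clinemosaic:::gl_is_flat(lo)), 0.97)
})

test_that("EM on simulated likelihoods recovers parental truth (RMSE)", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 500, seed = 81)
  tr <- simulate_parental_frequencies(cfg)
  set.seed(82)
  geno <- matrix(rbinom(500 * 50, 2, tr$p0), 500, 50)
  gl <- simulate_gbs_likelihoods(geno, tr$loci, depth = 8)
  f <- em_allele_frequencies(gl, population_map(gl$individuals, "p"))
  expect_lt(sqrt(mean((f$p - tr$p0)^2)), 0.08)
})

test_that("topology-window labels are Markov-autocorrelated and recoverable", {
  # switch probability 0: one label per chromosome
  cfg0 <- sim_config(n_chromosomes = 6, windows_per_chromosome = 5,
                     window_snps = 60, switch_prob = 0,
                     topology_noise = 0, seed = 91)
  tw0 <- simulate_topology_windows(cfg0)
  per_chr <- tapply(tw0$windows$true_label, tw0$windows$chromosome,
                    function(x) length(unique(x)))
  expect_true(all(per_chr == 1))
  # zero noise: inference recovers every label
  topo0 <- infer_topologies(tw0$windows, tw0$x)
  expect_equal(topo0$topology, tw0$windows$true_topology_id)
  # lag-1 agreement beats the label-frequency baseline when switching is rare
  cfg <- sim_config(n_chromosomes = 8, windows_per_chromosome = 30,
                    window_snps = 30, switch_prob = 0.2,
                    topology_noise = 0.05, seed = 92)
  tw <- simulate_topology_windows(cfg)
  lab <- tw$windows$true_label
  same_chr <- tw$windows$chromosome[-1] == head(tw$windows$chromosome, -1)
  lag1 <- mean((lab[-1] == head(lab, -1))[same_chr])
  baseline <- sum(table(lab)^2) / length(lab)^2
  expect_gt(lag1, baseline)
})

test_that("generators are deterministic end to end under a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2, loci_per_chromosome = 40,
                    n_per_pop = 6, n_hybrids = 8,
                    windows_per_chromosome = 2, window_snps = 30,
                    seed = 101)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$gl$gl, s2$gl$gl)
  expect_identical(s1$zone$h, s2$zone$h)
  expect_identical(s1$windows_panel$x, s2$windows_panel$x)
})
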