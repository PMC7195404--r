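test_that("pure parent-1 data drives q to 1 at diagnostic loci", {
  nl <- 30
  loci <- locus_map(paste0("l", 1:nl), "c1", seq_len(nl) * 10L)
  geno <- matrix(2L, nl, 8)
  gl <- certain_gl(geno, loci)
  track <- fit_ancestry_frequencies(
    gl, p0 = rep(0, nl), p1 = rep(1, nl),
    cfg = ancestry_model_config(n_iter = 2000, burnin = 500, thin = 2,
                                seed = 1))
  expect_true(all(track$q_hat > 0.95))
  expect_true(all(track$q_hat <= 1))
})

test_that("single-locus posterior matches the conjugate beta-binomial oracle", {
  # one locus on its own chromosome, certain genotypes, nu -> 0: the window
  # mean drops out and the posterior is Beta(S + eps, m - S + eps), whose
  # mean is S / m = 6/12 here
  geno <- matrix(c(0L, 1L, 2L, 2L, 1L, 0L), nrow = 1)
  gl <- certain_gl(geno, locus_map("solo", "c9", 100))
  track <- fit_ancestry_frequencies(
    gl, p0 = 0, p1 = 1,
    cfg = ancestry_model_config(nu = 1e-6, n_iter = 6000, burnin = 1000,
                                thin = 2, seed = 2))
  expect_lt(abs(track$q_hat - 0.5), 0.05)
  # asymmetric counts: S = 9 of 12
  geno2 <- matrix(c(2L, 2L, 2L, 1L, 1L, 1L), nrow = 1)
  gl2 <- certain_gl(geno2, locus_map("solo", "c9", 100))
  track2 <- fit_ancestry_frequencies(
    gl2, p0 = 0, p1 = 1,
    cfg = ancestry_model_config(nu = 1e-6, n_iter = 6000, burnin = 1000,
                                thin = 2, seed = 3))
  expect_lt(abs(track2$q_hat - 9 / 12), 0.05)
})

test_that("blockwise truth is recovered within RMSE 0.1 and chains agree", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 240,
                    block_length = 5, seed = 5)
  tr <- simulate_parental_frequencies(cfg, min_diff = 0.3)
  q_true <- rep(rep(c(0.2, 0.8), each = 40), 3)
  set.seed(6)
  anc <- simulate_ancient_hybrid(cfg, tr, n = 25, q_target = q_true)
  gl <- simulate_gbs_likelihoods(anc$genotypes, tr$loci, depth = 8)
  fit1 <- fit_ancestry_frequencies(
    gl, tr$p0, tr$p1,
    cfg = ancestry_model_config(n_iter = 3000, burnin = 1000, thin = 5,
                                seed = 7))
  expect_lt(sqrt(mean((fit1$q_hat - q_true)^2)), 0.1)
  # a different seed agrees within Monte-Carlo error
  fit2 <- fit_ancestry_frequencies(
    gl, tr$p0, tr$p1,
    cfg = ancestry_model_config(n_iter = 3000, burnin = 1000, thin = 5,
                                seed = 8))
  expect_lt(mean(abs(fit1$q_hat - fit2$q_hat)), 0.03)
})

test_that("window smoothing shrinks variance and roles swap coherently", {
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 150,
                    block_length = 50, seed = 9)
  tr <- simulate_parental_frequencies(cfg, min_diff = 0.3)
  set.seed(10)
  anc <- simulate_ancient_hybrid(cfg, tr, n = 20,
                                 q_target = rep(0.5, 150))
  gl <- simulate_gbs_likelihoods(anc$genotypes, tr$loci, depth = 4)
  smooth <- fit_ancestry_frequencies(
    gl, tr$p0, tr$p1,
    cfg = ancestry_model_config(window = 3, nu = 10, n_iter = 3000,
                                burnin = 1000, thin = 5, seed = 11))
  rough <- fit_ancestry_frequencies(
    gl, tr$p0, tr$p1,
    cfg = ancestry_model_config(window = 1, nu = 1e-4, n_iter = 3000,
                                burnin = 1000, thin = 5, seed = 11))
  # on constant-q truth the smoothed estimator varies less across loci
  expect_lte(var(smooth$q_hat), var(rough$q_hat))
  # swapping parental roles mirrors the estimate (within MC error)
  swapped <- fit_ancestry_frequencies(
    gl, p0 = tr$p1, p1 = tr$p0,
    cfg = ancestry_model_config(n_iter = 3000, burnin = 1000, thin = 5,
                                seed = 12))
  base <- fit_ancestry_frequencies(
    gl, tr$p0, tr$p1,
    cfg = ancestry_model_config(n_iter = 3000, burnin = 1000, thin = 5,
                                seed = 12))
  expect_lt(mean(abs((1 - swapped$q_hat) - base$q_hat)), 0.04)
})

test_that("uninformative loci (p0 == p1) are flagged with prior-like posteriors", {
  nl <- 5
  loci <- locus_map(paste0("l", 1:nl), "c1", seq_len(nl))
  geno <- matrix(1L, nl, 6)
  gl <- certain_gl(geno, loci)
  p <- rep(0.5, nl)
  expect_message(
    track <- fit_ancestry_frequencies(
      gl, p0 = p, p1 = p,
      cfg = ancestry_model_config(n_iter = 1000, burnin = 200, thin = 2,
                                  seed = 13)),
    "unidentifiable")
  expect_true(all(track$flagged))
  expect_true(all(track$q_hat >= 0 & track$q_hat <= 1))
})

test_that("fixation summary counts thresholds inclusively by scope", {
  track <- data.frame(
    locus_id = paste0("l", 1:100),
    chromosome = rep(c("c1", "cZ"), each = 50),
    position = rep(1:50, 2), is_Z = rep(c(FALSE, TRUE), each = 50),
    q_hat = seq(0, 1, length.out = 100), q_sd = 0.01, flagged = FALSE)
  class(track) <- c("ancestry_track", "data.frame")
  fx <- summarize_fixation(track, threshold = 0.95)
  overall <- fx[fx$scope == "overall", ]
  # grid 0, 1/99, ..., 1: values >= 0.95 are 95/99..99/99 -> 5 of 100
  expect_equal(overall$frac_parent1, 0.05)
  expect_equal(overall$frac_parent0, 0.05)
  z <- fx[fx$scope == "Z", ]
  expect_equal(z$n_loci, 50)
  expect_equal(z$frac_parent1, 0.10)
  # all-fixed degenerate case
  track$q_hat <- 1
  expect_equal(summarize_fixation(track)$frac_parent1[1], 1)
  # q_hat = 0.95 exactly is included
  track$q_hat <- rep(0.95, 100)
  expect_equal(summarize_fixation(track)$frac_parent1[1], 1)
})
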