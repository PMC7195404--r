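test_that("top-quantile sets have floor(qN) members with stable ties", {
  scores <- setNames(c(5, 4, 3, 2, 1, 1, 1, 0.5, 0.2, 0.1),
                     paste0("l", 1:10))
  expect_equal(topq_set(scores, 0.10)$members, "l1")
  expect_length(topq_set(scores, 1)$members, 10)
  s1164 <- setNames(rnorm(1164), paste0("x", 1:1164))
  expect_length(topq_set(s1164, 0.10)$members, 116)
  # bottom direction picks the minimum
  expect_equal(topq_set(scores, 0.10, "bottom")$members, "l10")
  # tie crossing the cutoff is reported, broken by locus order
  expect_message(s <- topq_set(scores, 0.5), "tie")
  expect_equal(s$members, paste0("l", 1:5))
  expect_error(topq_set(setNames(rep(1, 5), letters[1:5]), 0.2),
               "all scores equal")
})

test_that("overlap randomization matches the hypergeometric null", {
  uni <- paste0("l", 1:400)
  A <- uni[1:40]
  B <- uni[21:60]   # overlap 20
  r <- overlap_randomization_test(A, B, uni, n_perm = 4000, seed = 1)
  expect_equal(r$observed, 20)
  expected <- 40 * 40 / 400
  se <- r$null_sd / sqrt(r$n_perm)
  expect_lt(abs(r$null_mean - expected), 3 * se)
  expect_lt(r$p_one_sided, 0.001)
  # identical sets: x-fold ~ N / |A|
  r2 <- overlap_randomization_test(A, A, uni, n_perm = 4000, seed = 2)
  expect_equal(r2$observed, 40)
  expect_equal(r2$x_fold, 400 / 40, tolerance = 0.1)
  expect_warning(overlap_randomization_test(A, B, uni, n_perm = 50),
                 "unstable")
})

test_that("category test supports excess and deficit directions", {
  uni <- paste0("l", 1:300)
  memb <- setNames(seq_along(uni) <= 60, uni)  # 20% category
  set_hi <- uni[1:30]                          # all in category
  r <- category_enrichment_test(set_hi, memb, n_perm = 2000, seed = 3)
  expect_equal(r$observed, 30)
  expect_equal(r$x_fold, 30 / (30 * 60 / 300), tolerance = 0.15)
  expect_lt(r$p_one_sided, 0.01)
  set_lo <- uni[200:229]                       # none in category
  rd <- category_enrichment_test(set_lo, memb, n_perm = 2000,
                                 direction = "deficit", seed = 4)
  expect_equal(rd$observed, 0)
  expect_lt(rd$p_one_sided, 0.01)
  # excess P for an underrepresented set is ~ 1
  re <- category_enrichment_test(set_lo, memb, n_perm = 2000, seed = 5)
  expect_gt(re$p_one_sided, 0.95)
  expect_error(category_enrichment_test(set_hi, setNames(rep(FALSE, 300),
                                                         uni)),
               "undefined")
})

test_that("p-values are calibrated under independent-score nulls", {
  set.seed(6)
  uni <- paste0("l", 1:200)
  ps <- replicate(60, {
    A <- sample(uni, 20)
    B <- sample(uni, 20)
    overlap_randomization_test(A, B, uni, n_perm = 400)$p_one_sided
  })
  expect_gt(mean(ps <= 0.05), 0)  # sanity: some small values occur
  expect_lt(mean(ps <= 0.05), 0.20)
  expect_gt(mean(ps), 0.35)       # roughly uniform center of mass
})

test_that("proportion-size correlation reproduces closed forms", {
  expect_equal(proportion_size_correlation(1:5 / 10, (1:5) * 1e6)$r, 1)
  expect_equal(proportion_size_correlation(5:1 / 10, (1:5) * 1e6)$r, -1)
  prop <- c(0.12, 0.80, 0.33, 0.45, 0.60)
  size <- c(3.1, 9.2, 4.8, 5.0, 7.7) * 1e6
  res <- proportion_size_correlation(prop, size)
  r_hand <- cov(prop, size) / (sd(prop) * sd(size))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p_two_sided, 2 * pt(-abs(t_hand), df = 3),
               tolerance = 1e-12)
  expect_error(proportion_size_correlation(rep(0.3, 4), 1:4 * 1e6),
               "zero variance")
  # exclusion by chromosome name
  res2 <- proportion_size_correlation(prop, size,
                                      chromosome = c("c1", "c2", "c3",
                                                     "c4", "cZ"),
                                      exclude = "cZ")
  expect_equal(res2$n, 4)
})

test_that("consistency grid recovers planted coincident loci and scopes", {
  set.seed(7)
  n <- 300
  ids <- paste0("l", 1:n)
  is_Z <- c(rep(TRUE, 60), rep(FALSE, 240))
  planted <- 1:30
  beta_score <- rnorm(n)
  beta_score[planted] <- beta_score[planted] + 4
  q_hat <- runif(n, 0.2, 0.8)
  q_hat[planted] <- runif(30, 0.96, 1)
  cline_est <- data.frame(locus_id = ids, is_Z = is_Z,
                          alpha_mean = rnorm(n), beta_mean = beta_score)
  track <- data.frame(locus_id = ids, q_hat = q_hat)
  grid <- consistency_suite(cline_est, track, quantiles = 0.10,
                            n_perm = 1000, seed = 8)
  hit <- grid[grid$comparison == "high_beta vs high_parent1_ancestry" &
                grid$scope == "all", ]
  expect_gt(hit$x_fold, 2)
  expect_lt(hit$p_one_sided, 0.01)
  # independent scores: x-fold near 1, few significant cells
  null_grid <- consistency_suite(
    data.frame(locus_id = ids, is_Z = is_Z,
               alpha_mean = rnorm(n), beta_mean = rnorm(n)),
    data.frame(locus_id = ids, q_hat = runif(n)),
    quantiles = c(0.10, 0.05), n_perm = 500, seed = 9)
  expect_lt(mean(null_grid$significant), 0.25)
  expect_lt(abs(median(null_grid$x_fold) - 1), 0.75)
  # Z scope restricts the universe before permuting
  zrow <- grid[grid$scope == "Z", ][1, ]
  expect_lte(zrow$observed, 60)
  expect_true(all(grid$scope %in% c("all", "autosomes", "Z")))
})
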