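taxa5 <- c("idas", "melissa", "sierra", "warner", "anna")

test_that("window splitting is exact, chromosome-bounded arithmetic", {
  loci <- locus_map(paste0("a", 1:2500), "chr1", 1:2500)
  expect_message(w <- split_windows(loci, 1000), "500 trailing")
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(0, 1000))
  expect_equal(w$end, c(1000, 2000))
  one <- split_windows(locus_map(paste0("b", 1:1000), "chr1", 1:1000), 1000)
  expect_equal(nrow(one), 1)
  # windows never span chromosomes; short chromosome yields none
  two_chr <- locus_map(paste0("c", 1:1500),
                       rep(c("chr1", "chr2"), c(1100, 400)),
                       c(1:1100, 1:400))
  expect_message(w2 <- split_windows(two_chr, 1000))
  expect_equal(w2$chromosome, "chr1")
})

test_that("there are exactly 15 canonical topologies with stable ids", {
  tt <- five_taxon_topologies(taxa5)
  expect_length(tt, 15)
  # ids are self-consistent and stable across calls
  for (k in c(1, 8, 15))
    expect_equal(topology_id(tt[[k]], taxa5), k)
  tt2 <- five_taxon_topologies(taxa5)
  expect_equal(ape::write.tree(tt[[3]]), ape::write.tree(tt2[[3]]))
  # Newick import maps onto the same enumeration
  nk <- ape::read.tree(text = "((idas,melissa),sierra,(warner,anna));")
  id <- topology_id(nk, taxa5)
  expect_equal(phangorn::RF.dist(tt[[id]], nk), 0)
})

test_that("Fitch scoring equals the phangorn parsimony oracle", {
  set.seed(60)
  tt <- five_taxon_topologies(taxa5)
  X <- matrix(sample(c(0, 0.5, 1), 5 * 60, TRUE,
                     prob = c(0.45, 0.1, 0.45)), 5,
              dimnames = list(taxa5, NULL))
  chars <- matrix(as.character(X), 5, dimnames = list(taxa5, NULL))
  chars[chars == "0.5"] <- "?"
  pd <- phangorn::phyDat(chars, type = "USER", levels = c("0", "1"),
                         ambiguity = "?")
  tab <- clinemosaic:::phylo_tables(taxa5)
  codes <- round(2 * X)
  pat <- 1L + as.integer(codes[1, ] + 3 * codes[2, ] + 9 * codes[3, ] +
                           27 * codes[4, ] + 81 * codes[5, ])
  for (k in seq_len(15)) {
    mine <- sum(tab$fitch[pat, k])
    expect_equal(mine, phangorn::parsimony(tt[[k]], pd))
  }
})

test_that("clean synapomorphies and additive distances are recovered exactly", {
  tt <- five_taxon_topologies(taxa5)
  target <- topology_id(
    ape::read.tree(text = "((idas,melissa),sierra,(warner,anna));"), taxa5)
  # sites split cleanly on the two internal edges of the target tree
  x <- cbind(matrix(rep(c(1, 1, 0, 0, 0), 30), 5),
             matrix(rep(c(0, 0, 0, 1, 1), 30), 5))
  rownames(x) <- taxa5
  res <- infer_window_topology(x)
  expect_equal(res$topology, target)
  expect_false(res$tie)
  expect_equal(res$score, 60)  # one change per site, no homoplasy
  # least-squares on the same clean window finds the same tree with RSS ~ 0
  res_ls <- infer_window_topology(x, method = "me_ls")
  expect_equal(res_ls$topology, target)
  expect_lt(res_ls$score, 1e-20)
  # an all-invariant window ties across all topologies
  inv <- matrix(1, 5, 20, dimnames = list(taxa5, NULL))
  res_inv <- infer_window_topology(inv)
  expect_true(res_inv$uninformative)
  expect_true(res_inv$tie)
})

test_that("windows with 10% conflicting sites are recovered >= 95% of the time", {
  cfg <- sim_config(n_chromosomes = 5, windows_per_chromosome = 40,
                    window_snps = 100, topology_noise = 0.10,
                    switch_prob = 0.3, seed = 61)
  tw <- simulate_topology_windows(cfg)
  topo <- infer_topologies(tw$windows, tw$x)
  expect_gte(mean(topo$topology == tw$windows$true_topology_id), 0.95)
})

test_that("topology class tests detect planted excess and deficit", {
  set.seed(62)
  n_win <- 200
  table <- data.frame(window_id = 1:n_win,
                      chromosome = rep(c("c1", "cZ"), each = 100),
                      topology = sample(c(1, 4, 9), n_win, TRUE,
                                        prob = c(0.5, 0.3, 0.2)))
  # class = all windows: x-fold exactly 1
  r_all <- topology_class_test(table, 4, table$window_id, n_perm = 200,
                               seed = 63)
  expect_equal(r_all$x_fold, 1)
  # plant an excess of topology 9 in the Z windows
  table$topology[101:150] <- 9
  rz <- topology_class_test(table, 9, table$window_id[101:200],
                            n_perm = 1000, seed = 64)
  expect_gt(rz$x_fold, 1.3)
  expect_lte(rz$p_one_sided, 0.001 + 1e-9)
  # planted absence: deficit tail significant
  table$topology[1:100][table$topology[1:100] == 9] <- 1
  rd <- topology_class_test(table, 9, table$window_id[1:100],
                            n_perm = 1000, direction = "deficit",
                            seed = 65)
  expect_lt(rd$x_fold, 1)
  expect_lt(rd$p_one_sided, 0.01)
  expect_error(topology_class_test(table, 13, 1:10), "absent")
})

test_that("f_d matches its limits and a brute-force site-by-site oracle", {
  # complete sharing: P2 = P3 everywhere
  expect_equal(fd_statistic(rep(0, 8), rep(0.5, 8), rep(0.5, 8),
                            rep(0, 8))$fd, 1)
  # no shared derived alleles
  expect_equal(fd_statistic(rep(0, 8), rep(0, 8), rep(0.6, 8),
                            rep(0, 8))$fd, 0)
  # 4-site hand table vs explicit per-site evaluation
  p1 <- c(0.0, 0.2, 0.1, 0.5)
  p2 <- c(0.5, 0.9, 0.0, 0.5)
  p3 <- c(1.0, 0.8, 0.3, 0.5)
  pO <- c(0.0, 0.1, 0.0, 0.0)
  num <- den <- 0
  for (s in 1:4) {
    abba <- (1 - p1[s]) * p2[s] * p3[s] * (1 - pO[s])
    baba <- p1[s] * (1 - p2[s]) * p3[s] * (1 - pO[s])
    pD <- max(p2[s], p3[s])
    num <- num + (abba - baba)
    den <- den + ((1 - p1[s]) * pD * pD * (1 - pO[s]) -
                    p1[s] * (1 - pD) * pD * (1 - pO[s]))
  }
  res <- fd_statistic(p1, p2, p3, pO)
  expect_equal(res$fd, num / den)
  # missing sites skipped; all-zero denominator flagged
  expect_equal(fd_statistic(c(p1, NA), c(p2, 1), c(p3, 1),
                            c(pO, 0))$n_sites, 4)
  und <- fd_statistic(0, 0, 0, 0)
  expect_true(und$undefined)
})

test_that("f_d window-set null behaves at its boundary cases", {
  set.seed(66)
  fd <- runif(80, 0.2, 0.4)
  # candidate = all windows: degenerate null, P ~ 0.5
  r_all <- fd_window_set_test(fd, seq_along(fd), n_draws = 500, seed = 67)
  expect_equal(r_all$observed, r_all$null_mean)
  expect_lt(abs(r_all$p_one_sided - 0.5), 0.05)
  # planted zero-admixture candidates: lower-tail P significant
  fd[1:10] <- 0
  r <- fd_window_set_test(fd, 1:10, n_draws = 1000, seed = 68)
  expect_lte(r$p_one_sided, 0.002)
  # undefined windows are excluded with a message
  fd[15] <- NA
  expect_message(fd_window_set_test(fd, c(1:10, 15), n_draws = 200,
                                    seed = 69), "undefined")
})

test_that("topology-size correlation delegates to the shared routine", {
  prop <- c(0.5, 0.4, 0.3, 0.25, 0.1, 0.05)
  size <- c(1, 2, 3, 4, 5, 6) * 1e6
  a <- topology_size_correlation(prop, size)
  b <- proportion_size_correlation(prop, size)
  expect_identical(a, b)
  expect_lt(a$r, -0.9)
})
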