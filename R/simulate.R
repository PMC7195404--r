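# Synthetic-data generators.  These produce every input the pipeline
# consumes, with the statistical structure the inference models assume, and
# return the generating truth alongside so parameter recovery can be tested.
#
# The defaults describe the study conditions the package targets: two
# divergent parental gene pools typed at GBS-like low coverage, ancient
# hybrid populations whose ancestry varies in autocorrelated, partially
# fixed blocks (with the Z chromosome biased toward parent 1), a
# contemporary zone whose hybrid indexes span 0-1 with locus-specific cline
# deviations, and genome windows whose five-taxon topology labels are
# autocorrelated along chromosomes.

#' Simulation configuration
#'
#' @param n_chromosomes number of chromosomes; the last one is the Z
#'   (default 23, i.e. 22 autosomes + Z).
#' @param loci_per_chromosome integer vector (recycled) of loci per
#'   chromosome; the default ramps from 60 to 120 so chromosome size varies,
#'   with the Z among the largest.
#' @param divergence Balding-Nichols F-like parental divergence in (0, 1).
#' @param n_per_pop individuals per population.
#' @param depth mean sequencing depth, reads/site (GBS-like default 2).
#' @param error per-read base error rate.
#' @param h_beta_a,h_beta_b Beta parameters of the zone hybrid-index
#'   distribution (default 0.5, 0.5: U-shaped, spanning 0-1).
#' @param n_hybrids individuals in the contemporary zone (default 115).
#' @param alpha_frac,alpha_effect fraction of loci with directional cline
#'   deviation and the (+/-) effect size.
#' @param beta_frac,beta_effect fraction of loci with restricted
#'   introgression (beta > 0) and the effect size.
#' @param block_length mean ancestry-block length of the ancient hybrids,
#'   in loci.
#' @param fix1_frac,fix0_frac fraction of ancient-hybrid genome segments
#'   fixed (q >= 0.95) for parent-1 / parent-0 ancestry on autosomes.
#' @param z_fix1_frac same for the Z chromosome (parent-1-biased).
#' @param window_snps,windows_per_chromosome,topology_weights,z_topology_weights,switch_prob,topology_noise
#'   five-taxon window generator settings: SNPs per window, windows per
#'   chromosome, label mixing weights for the three generating topologies
#'   (autosomes and Z), Markov switch probability along a chromosome, and
#'   fraction of conflicting (noise) sites.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 23,
                       loci_per_chromosome = round(seq(60, 120,
                                                       length.out = 23)),
                       divergence = 0.8,
                       n_per_pop = 30,
                       depth = 2,
                       error = 0.01,
                       h_beta_a = 0.5, h_beta_b = 0.5,
                       n_hybrids = 115,
                       alpha_frac = 0.15, alpha_effect = 1.5,
                       beta_frac = 0.05, beta_effect = 2,
                       block_length = 25,
                       fix1_frac = 0.11, fix0_frac = 0.035,
                       z_fix1_frac = 0.30,
                       window_snps = 1000,
                       windows_per_chromosome = 4,
                       topology_weights = c(0.45, 0.40, 0.15),
                       z_topology_weights = c(0.45, 0.05, 0.50),
                       switch_prob = 0.25,
                       topology_noise = 0.10,
                       seed = 1) {
  stopifnot(divergence > 0, divergence < 1, depth > 0,
            error >= 0, error < 0.5, block_length >= 1,
            h_beta_a > 0, h_beta_b > 0,
            all(c(alpha_frac, beta_frac, fix1_frac, fix0_frac,
                  z_fix1_frac, switch_prob, topology_noise) >= 0),
            all(c(alpha_frac, beta_frac, switch_prob,
                  topology_noise) <= 1))
  loci_per_chromosome <- rep_len(loci_per_chromosome, n_chromosomes)
  structure(as.list(environment()), class = "sim_config")
}

# chromosome names: chr1..chr(k-1) and "chrZ" last
sim_chromosomes <- function(cfg) {
  n <- cfg$n_chromosomes
  if (n == 1L) "chrZ" else c(paste0("chr", seq_len(n - 1L)), "chrZ")
}

# locus map implied by the config: evenly spaced loci, 500 bp apart
sim_locus_map <- function(cfg) {
  chroms <- sim_chromosomes(cfg)
  chr <- rep(chroms, cfg$loci_per_chromosome)
  pos <- unlist(lapply(cfg$loci_per_chromosome,
                       function(n) seq(500L, by = 500L, length.out = n)))
  locus_map(paste0(chr, "_", pos), chr, pos, is_Z = chr == "chrZ")
}

#' Simulate divergent parental allele frequencies
#'
#' Balding-Nichols-style model: a common ancestral frequency per locus
#' (uniform on (0.05, 0.95)) and two descendant frequencies drawn from
#' `Beta(pi (1-F)/F, (1-pi)(1-F)/F)` with `F = divergence`.  The expected
#' fraction of loci with `|p1 - p0| >= 0.3` rises steeply with divergence
#' through moderate values and saturates around 0.4 at extreme divergence,
#' where both descendant frequencies increasingly collapse onto the *same*
#' boundary (an allele already near fixation ancestrally tends to fix in
#' both daughters).  With `min_diff` set, loci are redrawn until the
#' parental difference reaches it (used by the full-study preset to make
#' every locus an AIM).
#'
#' @param cfg a [sim_config()].
#' @param min_diff optional rejection threshold on `|p1 - p0|`.
#' @return list of class `sim_truth` (partial): `loci` ([locus_map()]),
#'   `p0`, `p1` (true parental frequencies).
#' @export
simulate_parental_frequencies <- function(cfg = sim_config(),
                                          min_diff = NULL) {
  set.seed(cfg$seed)
  loci <- sim_locus_map(cfg)
  L <- nrow(loci)
  f <- cfg$divergence
  shape <- (1 - f) / f
  draw <- function(n) {
    anc <- runif(n, 0.05, 0.95)
    list(p0 = rbeta(n, anc * shape, (1 - anc) * shape),
         p1 = rbeta(n, anc * shape, (1 - anc) * shape))
  }
  d <- draw(L)
  p0 <- d$p0; p1 <- d$p1
  if (!is.null(min_diff)) {
    for (rep in 1:200) {
      bad <- which(abs(p1 - p0) < min_diff)
      if (!length(bad)) break
      r <- draw(length(bad))
      p0[bad] <- r$p0; p1[bad] <- r$p1
    }
  }
  structure(list(loci = loci, p0 = p0, p1 = p1), class = "sim_truth")
}

# Blockwise target ancestry-frequency profile for one ancient hybrid
# population: the genome is partitioned into segments (geometric lengths,
# mean 4x the haplotype block length so fixed stretches span several
# ancestry blocks); each segment is fixed-parent-1, fixed-parent-0 or
# intermediate with the configured probabilities.
sim_q_profile <- function(cfg, loci) {
  q <- numeric(nrow(loci))
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    f1 <- if (loci$is_Z[idx[1]]) cfg$z_fix1_frac else cfg$fix1_frac
    f0 <- cfg$fix0_frac
    pos <- 1L
    while (pos <= length(idx)) {
      len <- 1L + rgeom(1, 1 / (4 * cfg$block_length))
      seg <- idx[seq.int(pos, min(pos + len - 1L, length(idx)))]
      u <- runif(1)
      q[seg] <- if (u < f1) runif(1, 0.95, 0.999)
      else if (u < f1 + f0) runif(1, 0.001, 0.05)
      else runif(1, 0.25, 0.85)
      pos <- pos + len
    }
  }
  q
}

#' Simulate an ancient (partially stabilized) hybrid population
#'
#' Each haplotype's ancestry along a chromosome follows a two-state Markov
#' chain whose local stationary frequency is the blockwise target profile
#' `q_l` and whose switch rates are `s1 = 1/(2 L q)` out of parent-1 and
#' `s0 = 1/(2 L (1-q))` out of parent-0 ancestry (`L` = `block_length`), so
#' the expected ancestry run length equals `block_length` at any `q`.
#' Alleles are drawn from the parent-1 or parent-0 frequency given the
#' copy's ancestry.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_parental_frequencies()] result.
#' @param n individuals (default `cfg$n_per_pop`).
#' @param q_target optional explicit target profile (length = loci)
#'   overriding the blockwise draw.
#' @return list: `genotypes` (loci x individuals, 0/1/2), `q_target`,
#'   `ancestry1`, `ancestry2` (loci x individuals 0/1 ancestry states of
#'   the two haplotypes), `q_realized` (mean ancestry per locus), `loci`.
#' @export
simulate_ancient_hybrid <- function(cfg, truth, n = cfg$n_per_pop,
                                    q_target = NULL) {
  loci <- truth$loci
  Lb <- cfg$block_length
  if (is.null(q_target)) q_target <- sim_q_profile(cfg, loci)
  q <- clamp01(q_target, 1e-3)
  nl <- nrow(loci)
  # switch rates out of parent-1 / parent-0 ancestry; exact 0/1 targets are
  # absorbing so that "q = 1 everywhere" really yields pure haplotypes
  s1 <- ifelse(q_target >= 1, 0,
               ifelse(q_target <= 0, 1, pmin(1 / (2 * Lb * q), 1)))
  s0 <- ifelse(q_target <= 0, 0,
               ifelse(q_target >= 1, 1, pmin(1 / (2 * Lb * (1 - q)), 1)))
  sim_haplo <- function() {
    z <- integer(nl)
    for (chr in unique(loci$chromosome)) {
      idx <- which(loci$chromosome == chr)
      z[idx[1]] <- rbinom(1, 1, q_target[idx[1]])
      if (length(idx) > 1) for (k in 2:length(idx)) {
        l <- idx[k]
        prev <- z[idx[k - 1L]]
        switch_p <- if (prev == 1L) s1[l] else s0[l]
        z[l] <- if (runif(1) < switch_p) 1L - prev else prev
      }
    }
    z
  }
  anc1 <- matrix(0L, nl, n)
  anc2 <- matrix(0L, nl, n)
  for (i in seq_len(n)) {
    anc1[, i] <- sim_haplo()
    anc2[, i] <- sim_haplo()
  }
  allele <- function(anc) {
    p <- ifelse(anc == 1L, truth$p1, truth$p0)
    matrix(rbinom(length(p), 1, p), nl, n)
  }
  genotypes <- allele(anc1) + allele(anc2)
  list(genotypes = genotypes, q_target = q_target,
       ancestry1 = anc1, ancestry2 = anc2,
       q_realized = rowMeans((anc1 + anc2) / 2), loci = loci)
}

#' Simulate a contemporary hybrid zone
#'
#' Hybrid indexes are drawn from `Beta(a, b)`; every allele copy at locus
#' `l` of individual `i` is parent-1-derived with probability
#' `phi(h_i; alpha_l, beta_l)` ([cline_function()]) and the allele given
#' its origin follows the parental frequencies.  A configured fraction of
#' loci carries nonzero alpha (sign random) or positive beta.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_parental_frequencies()] result.
#' @param n hybrids (default `cfg$n_hybrids`).
#' @param alpha,beta optional explicit per-locus cline parameters
#'   overriding the configured random assignment.
#' @return list: `genotypes` (loci x individuals), `h` (true hybrid
#'   indexes), `alpha`, `beta`, `loci`.
#' @export
simulate_contemporary_zone <- function(cfg, truth, n = cfg$n_hybrids,
                                       alpha = NULL, beta = NULL) {
  loci <- truth$loci
  nl <- nrow(loci)
  if (is.null(alpha)) {
    alpha <- numeric(nl)
    sel <- sample.int(nl, round(cfg$alpha_frac * nl))
    alpha[sel] <- sample(c(-1, 1), length(sel), TRUE) * cfg$alpha_effect
  }
  if (is.null(beta)) {
    beta <- numeric(nl)
    sel <- sample.int(nl, round(cfg$beta_frac * nl))
    beta[sel] <- cfg$beta_effect
  }
  h <- rbeta(n, cfg$h_beta_a, cfg$h_beta_b)
  genotypes <- matrix(0L, nl, n)
  for (i in seq_len(n)) {
    phi <- cline_function(h[i], alpha, beta)
    k <- rbinom(nl, 2, phi)  # parent-1-derived copies
    a1 <- rbinom(nl, 1, ifelse(k >= 1, truth$p1, truth$p0))
    a2 <- rbinom(nl, 1, ifelse(k == 2, truth$p1, truth$p0))
    genotypes[, i] <- a1 + a2
  }
  list(genotypes = genotypes, h = h, alpha = alpha, beta = beta,
       loci = loci)
}

#' Simulate a parental (reference) population
#'
#' Individuals drawn in Hardy-Weinberg proportions from population
#' frequencies that wobble around the parental truth with a small
#' within-species Balding-Nichols dispersion `f_within`.
#'
#' @param cfg a [sim_config()].
#' @param truth a [simulate_parental_frequencies()] result.
#' @param parent `0` or `1`.
#' @param n individuals.
#' @param f_within within-species divergence of the population from its
#'   species frequency (default 0.02).
#' @return list: `genotypes` (loci x individuals), `p_pop`, `loci`.
#' @export
simulate_parental_population <- function(cfg, truth, parent, n = cfg$n_per_pop,
                                         f_within = 0.02) {
  p_sp <- if (parent == 1) truth$p1 else truth$p0
  shape <- (1 - f_within) / f_within
  p_pop <- rbeta(length(p_sp), clamp01(p_sp, 1e-4) * shape,
                 (1 - clamp01(p_sp, 1e-4)) * shape)
  nl <- length(p_pop)
  genotypes <- matrix(rbinom(nl * n, 2, p_pop), nl, n)
  list(genotypes = genotypes, p_pop = p_pop, loci = truth$loci)
}

#' Simulate GBS-like genotype likelihoods
#'
#' Per site and individual, the read count is Poisson(`depth`); reads carry
#' the alternative allele with probability `error`, `0.5` or `1 - error`
#' for true genotypes 0, 1, 2, and the three genotype likelihoods are the
#' corresponding binomial read likelihoods.  Zero reads give a flat
#' (missing) triple.
#'
#' @param genotypes loci x individuals matrix of true genotypes (0/1/2).
#' @param loci a [locus_map()] for the rows.
#' @param individuals ids for the columns (default `ind1..indN`).
#' @param depth mean depth (> 0).
#' @param error per-read error rate in `[0, 0.5)`.
#' @return a [gl_matrix()].
#' @export
simulate_gbs_likelihoods <- function(genotypes, loci,
                                     individuals = NULL,
                                     depth = 2, error = 0.01) {
  stopifnot(depth > 0, error >= 0, error < 0.5)
  nl <- nrow(genotypes); n <- ncol(genotypes)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(n))
  reads <- matrix(rpois(nl * n, depth), nl, n)
  p_alt <- c(error, 0.5, 1 - error)[genotypes + 1L]
  alt <- matrix(rbinom(nl * n, as.vector(reads), as.vector(p_alt)), nl, n)
  gl <- array(NA_real_, c(nl, n, 3))
  for (g in 0:2)
    gl[, , g + 1L] <- dbinom(alt, reads, c(error, 0.5, 1 - error)[g + 1L])
  gl_matrix(gl, loci, individuals)
}

#' Simulate five-taxon topology windows
#'
#' Window topology labels follow a Markov chain along each chromosome
#' (switch probability from the config; on a switch the new label is drawn
#' from the mixing weights, which differ between autosomes and the Z).
#' Within a window, a site is a clean synapomorphy of one of the labeled
#' topology's two internal bipartitions with probability `1 - noise`, and
#' a random taxon bipartition otherwise.
#'
#' The three generating topologies mirror a hybrid-lineage scenario for the
#' taxa `(P1 idas-like, P2 melissa-like, hybrid lineages H1, H2, outgroup
#' anna-like)`: a species tree, an introgression tree uniting H2 with the
#' melissa-like lineage, and a tree uniting the two hybrid lineages.
#'
#' @param cfg a [sim_config()].
#' @param taxa five taxon names (order fixes the canonical topology ids).
#' @return list: `x` (5 x loci matrix of 0/1 calls), `loci`
#'   ([locus_map()]), `windows` ([split_windows()] table with
#'   `true_label` (1..3) and `true_topology_id` columns), `topology_ids`
#'   (canonical ids of the three generating topologies).
#' @export
simulate_topology_windows <- function(cfg = sim_config(),
                                      taxa = c("idas", "melissa",
                                               "sierra", "warner",
                                               "anna")) {
  set.seed(cfg$seed)
  gen_newicks <- c(
    species = "((idas,melissa),sierra,(warner,anna));",
    introgression = "((idas,anna),sierra,(warner,melissa));",
    hybrid_union = "((idas,melissa),anna,(warner,sierra));")
  gen_newicks <- gsub("idas", taxa[1], gen_newicks)
  gen_newicks <- gsub("melissa", taxa[2], gen_newicks)
  gen_newicks <- gsub("sierra", taxa[3], gen_newicks)
  gen_newicks <- gsub("warner", taxa[4], gen_newicks)
  gen_newicks <- gsub("anna", taxa[5], gen_newicks)
  gen_trees <- lapply(gen_newicks, function(s) ape::read.tree(text = s))
  ids <- vapply(gen_trees, topology_id, numeric(1), taxa = taxa)
  # the two internal bipartitions of each generating topology, as logical
  # masks over the taxa
  biparts <- lapply(gen_trees, function(t) {
    pp <- ape::prop.part(t)
    labs <- attr(pp, "labels")
    sides <- Filter(function(s) length(s) %in% 2:3,
                    lapply(pp, function(i) labs[i]))
    lapply(sides, function(s) taxa %in% s)
  })
  chroms <- rep(sim_chromosomes(cfg), each = cfg$windows_per_chromosome)
  n_win <- length(chroms)
  labels <- integer(n_win)
  for (w in seq_len(n_win)) {
    weights <- if (grepl("Z$", chroms[w])) cfg$z_topology_weights else
      cfg$topology_weights
    new_chrom <- w == 1L || chroms[w] != chroms[w - 1L]
    labels[w] <- if (new_chrom || runif(1) < cfg$switch_prob)
      sample.int(3L, 1L, prob = weights)
    else labels[w - 1L]
  }
  total <- n_win * cfg$window_snps
  x <- matrix(0, 5, total, dimnames = list(taxa, NULL))
  for (w in seq_len(n_win)) {
    cols <- seq.int((w - 1L) * cfg$window_snps + 1L, w * cfg$window_snps)
    bp <- biparts[[labels[w]]]
    for (s in cols) {
      if (runif(1) < cfg$topology_noise) {
        side <- sample(c(TRUE, FALSE), 5, TRUE)
        while (sum(side) %in% c(0L, 5L)) side <- sample(c(TRUE, FALSE), 5,
                                                        TRUE)
      } else {
        side <- bp[[sample.int(length(bp), 1L)]]
      }
      x[, s] <- as.numeric(side)
    }
  }
  pos <- unlist(lapply(seq_len(cfg$n_chromosomes), function(k)
    seq(100L, by = 100L,
        length.out = cfg$windows_per_chromosome * cfg$window_snps)))
  chr_site <- rep(sim_chromosomes(cfg),
                  each = cfg$windows_per_chromosome * cfg$window_snps)
  loci <- locus_map(paste0(chr_site, "_s", pos), chr_site, pos,
                    is_Z = chr_site == "chrZ")
  windows <- split_windows(loci, cfg$window_snps)
  windows$true_label <- labels
  windows$true_topology_id <- ids[labels]
  list(x = x, loci = loci, windows = windows, topology_ids = ids)
}
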