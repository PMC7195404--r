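# Locus-specific ancestry frequencies in old/ancient hybrid populations:
# a correlated-beta Gibbs sampler in the spirit of hidden-Markov local
# ancestry models, but with the ancestry *frequency* free to vary along the
# chromosome.  Each allele copy has a latent parental origin; the
# frequency q_l of parent-1 origins gets a Beta prior whose mean is the
# moving average of q over a small window of neighboring loci, which
# induces the expected autocorrelation of ancestry along chromosomes.

#' Configuration for the ancestry-frequency sampler
#'
#' @param window odd window width in loci for the local prior mean
#'   (default 3 SNPs).
#' @param nu precision of the correlated beta prior; larger values shrink
#'   q harder toward its local neighborhood mean (default 10).
#' @param n_iter,burnin,thin MCMC settings (defaults 10000 / 5000 / 10).
#' @param seed optional integer seed.
#' @return a list of class `ancestry_model_config`.
#' @export
ancestry_model_config <- function(window = 3, nu = 10, n_iter = 10000,
                                  burnin = 5000, thin = 10, seed = NULL) {
  stopifnot(window >= 1, window %% 2 == 1, nu > 0,
            n_iter > burnin, thin >= 1)
  structure(list(window = as.integer(window), nu = nu,
                 n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed),
            class = "ancestry_model_config")
}

#' Fit locus-specific ancestry frequencies in a hybrid population
#'
#' Model: each allele copy `c` of individual `i` at locus `l` has latent
#' origin `z_ilc ~ Bernoulli(q_l)` (1 = parent-1 derived); the allele given
#' its origin is Bernoulli(`p1_l`) or Bernoulli(`p0_l`); the genotype is
#' observed only through the genotype-likelihood triple.  The prior is
#' `q_l ~ Beta(nu * mu_l, nu * (1 - mu_l))` with `mu_l` the moving-window
#' mean of the current `q` (window truncated at chromosome ends).  Gibbs
#' sampling alternates origins given `q` (marginalizing the two copies into
#' a count 0/1/2 per individual) and `q` given origins (conjugate
#' beta-binomial update, `mu_l` held fixed within a sweep).
#'
#' Z-linked loci of female individuals are treated as hemizygous (one allele
#' copy) when `use_sex = TRUE`.
#'
#' @param gl a [gl_matrix()] restricted to the hybrid population's
#'   individuals (use [gl_subset()] or pass `individuals`).
#' @param p0,p1 parental allele frequencies at the loci of `gl` (parent 0
#'   and parent 1 respectively).
#' @param cfg an [ancestry_model_config()].
#' @param pops optional [population_map()] supplying `sex`.
#' @param use_sex model female Z hemizygosity (default `FALSE`: all
#'   individuals diploid everywhere, as when analyzing males only).
#' @return a `data.frame` of class `ancestry_track`: per locus `q_hat`
#'   (posterior mean of parent-1 ancestry frequency), `q_sd`, `flagged`
#'   (`TRUE` where `p0 == p1` leaves q unidentifiable, posterior ~ prior).
#' @export
fit_ancestry_frequencies <- function(gl, p0, p1,
                                     cfg = ancestry_model_config(),
                                     pops = NULL, use_sex = FALSE) {
  stopifnot(inherits(gl, "gl_matrix"))
  L <- nrow(gl$loci)
  n <- length(gl$individuals)
  if (n < 2) stop("need at least 2 individuals in the hybrid population")
  stopifnot(length(p0) == L, length(p1) == L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  flagged <- abs(p1 - p0) < 1e-12
  if (any(flagged))
    message(sum(flagged), " locus/loci with p0 == p1: ",
            "ancestry frequency unidentifiable there (posterior ~ prior)")

  G0 <- gl$gl[, , 1]; G1 <- gl$gl[, , 2]; G2 <- gl$gl[, , 3]
  dim(G0) <- dim(G1) <- dim(G2) <- c(L, n)

  # Likelihood of the GL triple given k = number of parent-1-derived copies.
  p_het <- function(a, b) a * (1 - b) + b * (1 - a)
  W0 <- G0 * (1 - p0)^2 + G1 * (2 * p0 * (1 - p0)) + G2 * p0^2
  W1 <- G0 * ((1 - p1) * (1 - p0)) + G1 * p_het(p1, p0) + G2 * (p1 * p0)
  W2 <- G0 * (1 - p1)^2 + G1 * (2 * p1 * (1 - p1)) + G2 * p1^2

  # ploidy per (locus, individual): 1 for female Z, else 2
  ploidy <- matrix(2L, L, n)
  if (use_sex && !is.null(pops)) {
    sex <- pops$sex[match(gl$individuals, pops$individual_id)]
    fem <- which(sex == "female")
    if (length(fem) && any(gl$loci$is_Z))
      ploidy[gl$loci$is_Z, fem] <- 1L
  }
  hemi <- ploidy == 1L
  # single-copy likelihoods (observed genotype read as 0 or 2 copies of the
  # counted allele for a hemizygote)
  V0 <- G0 * (1 - p0) + G2 * p0
  V1 <- G0 * (1 - p1) + G2 * p1
  m_l <- rowSums(ploidy)  # allele copies observed per locus

  keep <- seq.int(cfg$burnin + 1L, cfg$n_iter, by = cfg$thin)
  q <- rep(0.5, L)
  q_sum <- numeric(L)
  q_sumsq <- numeric(L)
  n_kept <- 0L
  chrom <- gl$loci$chromosome
  for (it in seq_len(cfg$n_iter)) {
    pr0 <- (1 - q)^2; pr1 <- 2 * q * (1 - q); pr2 <- q^2
    u0 <- W0 * pr0; u1 <- W1 * pr1; u2 <- W2 * pr2
    if (any(hemi)) {
      # overwrite hemizygous cells with the two-state (0/1 copy) problem
      u0[hemi] <- (V0 * (1 - q))[hemi]
      u1[hemi] <- (V1 * q)[hemi]
      u2[hemi] <- 0
    }
    tot <- u0 + u1 + u2
    r <- runif(L * n) * tot
    k <- (r > u0) + (r > u0 + u1)
    dim(k) <- c(L, n)
    S <- rowSums(k)
    mu <- window_mean(q, cfg$window, chrom)
    mu <- clamp01(mu, 1e-9)
    q <- rbeta(L, cfg$nu * mu + S, cfg$nu * (1 - mu) + m_l - S)
    q <- clamp01(q, 1e-12)
    if (it > cfg$burnin && (it - cfg$burnin - 1L) %% cfg$thin == 0L) {
      q_sum <- q_sum + q
      q_sumsq <- q_sumsq + q^2
      n_kept <- n_kept + 1L
    }
  }
  q_hat <- q_sum / n_kept
  q_var <- pmax(q_sumsq / n_kept - q_hat^2, 0)
  out <- data.frame(locus_id = gl$loci$locus_id,
                    chromosome = gl$loci$chromosome,
                    position = gl$loci$position,
                    is_Z = gl$loci$is_Z,
                    q_hat = q_hat,
                    q_sd = sqrt(q_var * n_kept / max(n_kept - 1L, 1L)),
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  attr(out, "n_kept") <- n_kept
  class(out) <- c("ancestry_track", "data.frame")
  out
}

#' Summarize fixation of ancestry
#'
#' Fractions of loci fixed or nearly fixed (`q_hat >= threshold` for
#' parent 1; `q_hat <= 1 - threshold` for parent 0), overall, per
#' chromosome, and for the Z versus the autosomes.  The threshold is
#' inclusive.
#'
#' @param track an [fit_ancestry_frequencies()] result.
#' @param threshold fixation threshold (default 0.95).
#' @return `data.frame` with columns `scope`, `n_loci`, `frac_parent1`,
#'   `frac_parent0`, `frac_fixed` (either ancestry).
#' @export
summarize_fixation <- function(track, threshold = 0.95) {
  stopifnot(nrow(track) > 0)
  one <- function(scope, idx) {
    q <- track$q_hat[idx]
    f1 <- mean(q >= threshold - 1e-12)
    f0 <- mean(q <= 1 - threshold + 1e-12)
    data.frame(scope = scope, n_loci = length(q),
               frac_parent1 = f1, frac_parent0 = f0,
               frac_fixed = f1 + f0, stringsAsFactors = FALSE)
  }
  rows <- list(one("overall", seq_len(nrow(track))),
               one("autosomes", which(!track$is_Z)),
               one("Z", which(track$is_Z)))
  for (chr in unique(track$chromosome))
    rows[[length(rows) + 1L]] <-
      one(paste0("chr:", chr), which(track$chromosome == chr))
  out <- do.call(rbind, rows)
  out[out$n_loci > 0, , drop = FALSE]
}
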