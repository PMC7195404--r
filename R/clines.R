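# Hybrid indexes and Bayesian genomic clines.  The cline function maps an
# individual's genome-wide hybrid index h onto the locus-specific
# probability of parent-1 ancestry; alpha shifts the cline center
# (directional introgression), beta changes its steepness (restricted
# introgression when beta > 0).

#' Genomic cline function
#'
#' `phi = h + 2 h (1 - h) (alpha + beta (2 h - 1))`, truncated to `[0, 1]`.
#' The endpoints are pinned: `phi(0) = 0` and `phi(1) = 1` for any
#' parameters, and `alpha = beta = 0` gives the neutral cline `phi = h`.
#' In a geographic reading, `alpha` equals twice the shift in cline center
#' and `beta` the proportional decrease in cline width.
#'
#' @param h hybrid index in `[0, 1]` (vectorized).
#' @param alpha,beta cline parameters (vectorized, recycled against `h`).
#' @return probability of parent-1 ancestry for each allele copy.
#' @export
cline_function <- function(h, alpha, beta) {
  if (any(h < 0 | h > 1 | !is.finite(h)))
    stop("hybrid index must lie in [0, 1]")
  clamp01(h + 2 * h * (1 - h) * (alpha + beta * (2 * h - 1)))
}

#' Maximum-likelihood hybrid index
#'
#' For each individual, maximizes the genotype-likelihood-weighted binomial
#' likelihood `sum_l log sum_g GL_lg * Binom(g; 2, pi_l)` with
#' `pi_l = h p1_l + (1 - h) p0_l` over `h` in `[0, 1]` (bounded 1-D
#' optimization, tolerance 1e-6).  An individual with only flat triples is
#' reported at `h = 0.5` and flagged uninformative.
#'
#' @param gl a [gl_matrix()] restricted to AIMs for the admixed individuals.
#' @param p0,p1 parental allele frequencies at the loci of `gl`.
#' @return `data.frame` of class `hybrid_index` with columns
#'   `individual_id`, `h`, `loglik`, `uninformative`.
#' @export
estimate_hybrid_index <- function(gl, p0, p1) {
  stopifnot(inherits(gl, "gl_matrix"))
  L <- nrow(gl$loci)
  stopifnot(length(p0) == L, length(p1) == L)
  if (L < 10)
    warning("fewer than 10 AIMs: hybrid-index estimates will be imprecise")
  flat <- gl_is_flat(gl)
  out <- data.frame(individual_id = gl$individuals, h = NA_real_,
                    loglik = NA_real_, uninformative = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(gl$individuals)) {
    g0 <- gl$gl[, i, 1]; g1 <- gl$gl[, i, 2]; g2 <- gl$gl[, i, 3]
    if (all(flat[, i])) {
      out$h[i] <- 0.5
      out$uninformative[i] <- TRUE
      out$loglik[i] <- 0
      next
    }
    f <- function(h) {
      pi <- h * p1 + (1 - h) * p0
      sum(log(pmax(g0 * (1 - pi)^2 + g1 * 2 * pi * (1 - pi) + g2 * pi^2,
                   1e-300)))
    }
    opt <- optimize(f, c(0, 1), maximum = TRUE, tol = 1e-6)
    # optimize() never evaluates the exact endpoints; snap if better there
    cand <- c(opt$maximum, 0, 1)
    vals <- c(opt$objective, f(0), f(1))
    best <- which.max(vals)
    out$h[i] <- cand[best]
    out$loglik[i] <- vals[best]
  }
  class(out) <- c("hybrid_index", "data.frame")
  out
}

#' Configuration for the genomic-cline MCMC
#'
#' Defaults follow common practice for per-locus cline fitting: five chains
#' of 25,000 iterations, 5000 burn-in, thinning interval 5, standard-normal
#' priors on alpha and beta, and proposal scales auto-tuned during burn-in
#' toward 20-40% acceptance.
#'
#' @param chains,n_iter,burnin,thin MCMC settings.
#' @param prior_sd_alpha,prior_sd_beta normal prior standard deviations.
#' @param proposal_sd initial random-walk proposal scale.
#' @param adapt tune proposal scales during burn-in.
#' @param seed optional integer seed.
#' @return list of class `cline_mcmc_config`.
#' @export
cline_mcmc_config <- function(chains = 5, n_iter = 25000, burnin = 5000,
                              thin = 5, prior_sd_alpha = 1,
                              prior_sd_beta = 1, proposal_sd = 0.3,
                              adapt = TRUE, seed = NULL) {
  stopifnot(chains >= 1, n_iter > burnin, thin >= 1,
            prior_sd_alpha > 0, prior_sd_beta > 0, proposal_sd > 0)
  structure(list(chains = as.integer(chains), n_iter = as.integer(n_iter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 prior_sd_alpha = prior_sd_alpha,
                 prior_sd_beta = prior_sd_beta,
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt),
                 seed = seed),
            class = "cline_mcmc_config")
}

# per-locus log-likelihood (length L) for given alpha, beta (length L);
# G* are L x n, h-derived vectors length n.
cline_loglik <- function(alpha, beta, G0, G1, G2, p0, p1, h, w, v) {
  L <- length(alpha)
  n <- length(h)
  phi <- matrix(h, L, n, byrow = TRUE) +
    matrix(w, L, n, byrow = TRUE) * (alpha + outer(beta, v))
  phi <- clamp01(phi)
  a <- phi * p1 + (1 - phi) * p0
  lik <- G0 * (1 - a)^2 + G1 * (2 * a * (1 - a)) + G2 * a^2
  rowSums(log(pmax(lik, 1e-300)))
}

#' Fit Bayesian genomic clines
#'
#' Per AIM, each allele copy of hybrid `i` is parent-1-derived with
#' probability `phi(h_i; alpha_l, beta_l)` ([cline_function()]); the allele
#' given its origin follows the parental frequencies and the genotype is
#' observed through the likelihood triple.  Hybrid indexes are estimated
#' first and held fixed (two-stage fit).  Random-walk Metropolis updates
#' alpha and beta locus-by-locus (vectorized across loci) under independent
#' normal priors; chains are pooled after burn-in and thinning.  Loci whose
#' split R-hat exceeds 1.1 on either parameter are flagged, not dropped.
#'
#' @param gl a [gl_matrix()] of the hybrid individuals at the AIMs.
#' @param h a [estimate_hybrid_index()] result (or numeric vector of hybrid
#'   indexes matching `gl$individuals`).
#' @param p0,p1 parental allele frequencies at the loci of `gl`.
#' @param cfg a [cline_mcmc_config()].
#' @return `data.frame` of class `cline_fit`: per locus posterior mean /
#'   median / 95% equal-tail CI for alpha and beta, split R-hat per
#'   parameter, mixing flag, and the credible-deviation classification of
#'   [classify_credible()].
#' @export
fit_genomic_clines <- function(gl, h, p0, p1, cfg = cline_mcmc_config()) {
  stopifnot(inherits(gl, "gl_matrix"))
  if (is.data.frame(h)) h <- h$h[match(gl$individuals, h$individual_id)]
  n <- length(gl$individuals)
  L <- nrow(gl$loci)
  stopifnot(length(h) == n, length(p0) == L, length(p1) == L)
  if (length(unique(round(h, 8))) < 2)
    stop("need at least 2 hybrids with distinct hybrid indexes")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  G0 <- gl$gl[, , 1]; G1 <- gl$gl[, , 2]; G2 <- gl$gl[, , 3]
  dim(G0) <- dim(G1) <- dim(G2) <- c(L, n)
  w <- 2 * h * (1 - h)
  v <- 2 * h - 1
  n_keep <- length(seq.int(cfg$burnin + 1L, cfg$n_iter, by = cfg$thin))
  A <- array(NA_real_, dim = c(n_keep, cfg$chains, L))
  B <- array(NA_real_, dim = c(n_keep, cfg$chains, L))
  for (ch in seq_len(cfg$chains)) {
    alpha <- rnorm(L, 0, 0.1)
    beta <- rnorm(L, 0, 0.1)
    s_a <- rep(cfg$proposal_sd, L)
    s_b <- rep(cfg$proposal_sd, L)
    acc_a <- acc_b <- numeric(L)
    ll <- cline_loglik(alpha, beta, G0, G1, G2, p0, p1, h, w, v)
    kept <- 0L
    for (it in seq_len(cfg$n_iter)) {
      a_prop <- alpha + rnorm(L) * s_a
      ll_prop <- cline_loglik(a_prop, beta, G0, G1, G2, p0, p1, h, w, v)
      lr <- ll_prop - ll +
        dnorm(a_prop, 0, cfg$prior_sd_alpha, log = TRUE) -
        dnorm(alpha, 0, cfg$prior_sd_alpha, log = TRUE)
      acc <- log(runif(L)) < lr
      alpha[acc] <- a_prop[acc]
      ll[acc] <- ll_prop[acc]
      acc_a <- acc_a + acc

      b_prop <- beta + rnorm(L) * s_b
      ll_prop <- cline_loglik(alpha, b_prop, G0, G1, G2, p0, p1, h, w, v)
      lr <- ll_prop - ll +
        dnorm(b_prop, 0, cfg$prior_sd_beta, log = TRUE) -
        dnorm(beta, 0, cfg$prior_sd_beta, log = TRUE)
      acc <- log(runif(L)) < lr
      beta[acc] <- b_prop[acc]
      ll[acc] <- ll_prop[acc]
      acc_b <- acc_b + acc

      if (cfg$adapt && it <= cfg$burnin && it %% 50L == 0L) {
        rate_a <- acc_a / 50; rate_b <- acc_b / 50
        s_a <- pmin(pmax(s_a * exp(rate_a - 0.3), 1e-3), 10)
        s_b <- pmin(pmax(s_b * exp(rate_b - 0.3), 1e-3), 10)
        acc_a <- acc_b <- numeric(L)
      }
      if (it > cfg$burnin && (it - cfg$burnin - 1L) %% cfg$thin == 0L) {
        kept <- kept + 1L
        A[kept, ch, ] <- alpha
        B[kept, ch, ] <- beta
      }
    }
  }
  summarize <- function(S) {
    flatten <- matrix(S, nrow = n_keep * cfg$chains, ncol = L)
    qs <- apply(flatten, 2, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE)
    rh <- vapply(seq_len(L), function(l) split_rhat(S[, , l]), numeric(1))
    list(mean = colMeans(flatten), median = qs[2, ],
         lo = qs[1, ], hi = qs[3, ], rhat = rh)
  }
  sa <- summarize(A)
  sb <- summarize(B)
  out <- data.frame(locus_id = gl$loci$locus_id,
                    chromosome = gl$loci$chromosome,
                    is_Z = gl$loci$is_Z,
                    alpha_mean = sa$mean, alpha_median = sa$median,
                    alpha_lo = sa$lo, alpha_hi = sa$hi,
                    beta_mean = sb$mean, beta_median = sb$median,
                    beta_lo = sb$lo, beta_hi = sb$hi,
                    rhat_alpha = sa$rhat, rhat_beta = sb$rhat,
                    stringsAsFactors = FALSE)
  out$mixing_flag <- !is.na(out$rhat_alpha) &
    (out$rhat_alpha > 1.1 | out$rhat_beta > 1.1)
  out <- cbind(out, classify_credible(out)[, -1])
  attr(out, "config") <- cfg
  class(out) <- c("cline_fit", "data.frame")
  out
}

#' Classify credible cline deviations
#'
#' Flags each locus by its 95% equal-tail credible intervals:
#' `directional_parent1` when CI(alpha) > 0, `directional_parent0` when
#' CI(alpha) < 0, and `restricted` when CI(beta) > 0.
#'
#' @param est a [fit_genomic_clines()] result (any data frame with columns
#'   `alpha_lo`, `alpha_hi`, `beta_lo`, `beta_hi`).
#' @return `data.frame` with `locus_id` and the three logical columns;
#'   category counts are attached as `attr(, "counts")`.
#' @export
classify_credible <- function(est) {
  out <- data.frame(locus_id = est$locus_id,
                    directional_parent1 = est$alpha_lo > 0,
                    directional_parent0 = est$alpha_hi < 0,
                    restricted = est$beta_lo > 0,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- colSums(out[, -1])
  out
}
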