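# Polarized coupling/repulsion LD, the ratio-of-averages F_ST, and a
# Bayesian pairwise isolation-by-distance mixed model compared by DIC.

#' Polarized linkage disequilibrium among AIMs
#'
#' Pairwise Pearson correlations between posterior-mean genotypes at AIMs,
#' with each locus recoded so that the counted allele is the one more
#' common in parent 1.  Positive correlations then indicate coupling LD
#' (associations between same-parent alleles, as generated by admixture)
#' and negative correlations repulsion LD.  Genotypes are posterior means
#' under a Hardy-Weinberg prior at the population's own allele frequency,
#' so genotype uncertainty is carried through.
#'
#' @param gl a [gl_matrix()] restricted to one population's individuals at
#'   the AIM loci.
#' @param p0,p1 parental mean allele frequencies at those loci (used only
#'   for polarization via `sign(p1 - p0)`).
#' @param p_pop the population's own allele frequencies (posterior-mean
#'   genotype prior); defaults to a quick EM fit on `gl`.
#' @param min_n minimum individuals (default 20, the usual inclusion rule);
#'   smaller samples error unless `force = TRUE`.
#' @param force override `min_n`.
#' @return list of class `ld_matrix`: `r` (loci x loci), `mean_r` (mean of
#'   the upper triangle over defined pairs), `n_ind`.
#' @export
polarized_ld <- function(gl, p0, p1, p_pop = NULL, min_n = 20,
                         force = FALSE) {
  stopifnot(inherits(gl, "gl_matrix"))
  n <- length(gl$individuals)
  if (n < min_n && !force)
    stop("population has ", n, " individuals (< ", min_n,
         "); pass force = TRUE to override")
  L <- nrow(gl$loci)
  if (is.null(p_pop)) {
    pm <- population_map(gl$individuals, "pop")
    p_pop <- em_allele_frequencies(gl, pm)$p
  }
  w0 <- (1 - p_pop)^2; w1 <- 2 * p_pop * (1 - p_pop); w2 <- p_pop^2
  G0 <- gl$gl[, , 1]; G1 <- gl$gl[, , 2]; G2 <- gl$gl[, , 3]
  dim(G0) <- dim(G1) <- dim(G2) <- c(L, n)
  denom <- G0 * w0 + G1 * w1 + G2 * w2
  g <- (G1 * w1 + 2 * G2 * w2) / pmax(denom, 1e-300)
  flip <- p1 < p0
  g[flip, ] <- 2 - g[flip, ]
  gv <- apply(g, 1, sd)
  mono <- gv == 0
  r <- suppressWarnings(cor(t(g)))
  r[mono, ] <- NA
  r[, mono] <- NA
  diag(r)[!mono] <- 1
  dimnames(r) <- list(gl$loci$locus_id, gl$loci$locus_id)
  ut <- r[upper.tri(r)]
  structure(list(r = r, mean_r = mean(ut, na.rm = TRUE), n_ind = n,
                 n_monomorphic = sum(mono)),
            class = "ld_matrix")
}

#' Pairwise F_ST (ratio of averages)
#'
#' `F_ST = mean_l(H_T - H_S) / mean_l(H_T)` across loci, where
#' `H_S = (2 pA (1-pA) + 2 pB (1-pB)) / 2` is the mean within-population
#' expected heterozygosity and `H_T = 2 pbar (1-pbar)` with `pbar` the
#' unweighted mean of the two population frequencies.  (With populations
#' weighted equally, the heterozygosity of the pooled mixture equals
#' `H_S + (pA - pB)^2 / 2`, which is algebraically identical to
#' `2 pbar (1-pbar)`, so no separate "pooled" variant is needed.)
#'
#' @param pA,pB allele-frequency vectors for the two populations.
#' @return list of class `fst_result`: `fst`, `logit_fst` (values clipped
#'   to `[1e-6, 1 - 1e-6]` before the transform), `n_loci`,
#'   `undefined` flag.
#' @export
fst_pair <- function(pA, pB) {
  stopifnot(length(pA) == length(pB))
  hs <- (expected_heterozygosity(pA) + expected_heterozygosity(pB)) / 2
  htot <- expected_heterozygosity((pA + pB) / 2)
  undefined <- mean(htot) <= 0
  fst <- if (undefined) NA_real_ else mean(htot - hs) / mean(htot)
  lf <- if (is.na(fst)) NA_real_ else logit(clamp01(fst, 1e-6))
  structure(list(fst = fst, logit_fst = lf, n_loci = length(pA),
                 mean_hs = mean(hs), mean_ht = mean(htot),
                 undefined = undefined),
            class = "fst_result")
}

#' Pairwise table for the isolation-by-distance model
#'
#' Builds the response/covariate table for [fit_ibd_model()]: logit F_ST
#' for every population pair, log great-circle distance (haversine on
#' decimal degrees, km) and taxon distance (0 same, 1 different nominal
#' taxon).
#'
#' @param freqs an [em_allele_frequencies()] result.
#' @param coords `data.frame` with columns `population`, `lat`, `lon`,
#'   `taxon`.
#' @return `data.frame` with columns `pop_i`, `pop_j`, `logit_fst`,
#'   `log_dist`, `taxon_dist`.
#' @export
ibd_pair_table <- function(freqs, coords) {
  fm <- freq_matrix(freqs)
  pops <- intersect(colnames(fm), coords$population)
  if (length(pops) < 4) stop("need at least 4 populations")
  pairs <- utils::combn(pops, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    fr <- fst_pair(fm[, i], fm[, j])
    ci <- coords[coords$population == i, ]
    cj <- coords[coords$population == j, ]
    d_km <- geosphere::distHaversine(c(ci$lon, ci$lat),
                                     c(cj$lon, cj$lat)) / 1000
    data.frame(pop_i = i, pop_j = j, logit_fst = fr$logit_fst,
               log_dist = log(max(d_km, 1e-3)),
               taxon_dist = as.integer(ci$taxon != cj$taxon),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Gibbs sampler for one candidate model.  y = X b + Z u + e with
# b ~ N(0, 1/tau0), tau_u, tau_e ~ Gamma(1, 0.01); all conditionals
# conjugate.  Returns posterior summaries and the DIC.
ibd_gibbs <- function(y, X, Z, chains, n_iter, burnin, thin, tau0 = 0.001,
                      g_shape = 1, g_rate = 0.01) {
  m <- length(y)
  p <- ncol(X)
  npop <- ncol(Z)
  keep_idx <- seq.int(burnin + 1L, n_iter, by = thin)
  n_keep <- length(keep_idx)
  draws_b <- array(NA_real_, c(n_keep, chains, p))
  draws_tau <- array(NA_real_, c(n_keep, chains, 2))
  draws_u <- array(NA_real_, c(n_keep, chains, npop))
  dev <- matrix(NA_real_, n_keep, chains)
  XtX <- crossprod(X)
  ZtZ <- crossprod(Z)
  for (ch in seq_len(chains)) {
    b <- rnorm(p, 0, 0.5)
    u <- rnorm(npop, 0, 0.5)
    tau_e <- 1
    tau_u <- 1
    kept <- 0L
    for (it in seq_len(n_iter)) {
      # b | .
      prec <- tau_e * XtX + diag(tau0, p)
      ch_p <- chol(prec)
      mu_b <- backsolve(ch_p, forwardsolve(t(ch_p),
                                           tau_e * crossprod(X, y - Z %*% u)))
      b <- mu_b + backsolve(ch_p, rnorm(p))
      # u | . (joint update; small npop)
      prec_u <- tau_e * ZtZ + diag(tau_u, npop)
      ch_u <- chol(prec_u)
      mu_u <- backsolve(ch_u, forwardsolve(t(ch_u),
                                           tau_e * crossprod(Z, y - X %*% b)))
      u <- mu_u + backsolve(ch_u, rnorm(npop))
      resid <- y - X %*% b - Z %*% u
      tau_e <- rgamma(1, g_shape + m / 2, g_rate + sum(resid^2) / 2)
      tau_u <- rgamma(1, g_shape + npop / 2, g_rate + sum(u^2) / 2)
      if (it > burnin && (it - burnin - 1L) %% thin == 0L) {
        kept <- kept + 1L
        draws_b[kept, ch, ] <- b
        draws_u[kept, ch, ] <- u
        draws_tau[kept, ch, ] <- c(tau_e, tau_u)
        dev[kept, ch] <- -2 * sum(dnorm(y, X %*% b + Z %*% u,
                                        sqrt(1 / tau_e), log = TRUE))
      }
    }
  }
  flat <- function(a) matrix(a, nrow = n_keep * chains)
  bm <- flat(draws_b); um <- flat(draws_u); tm <- flat(draws_tau)
  b_bar <- colMeans(bm); u_bar <- colMeans(um)
  sigma_e_bar <- sqrt(mean(1 / tm[, 1]))
  d_bar <- mean(dev)
  d_hat <- -2 * sum(dnorm(y, X %*% b_bar + Z %*% u_bar, sigma_e_bar,
                          log = TRUE))
  p_d <- d_bar - d_hat
  list(coef = data.frame(term = colnames(X),
                         mean = b_bar,
                         sd = apply(bm, 2, sd),
                         lo = apply(bm, 2, quantile, 0.025),
                         hi = apply(bm, 2, quantile, 0.975),
                         rhat = vapply(seq_len(p), function(k)
                           split_rhat(draws_b[, , k]), numeric(1)),
                         row.names = NULL),
       sd_u = sqrt(mean(1 / tm[, 2])),
       sd_e = sqrt(mean(1 / tm[, 1])),
       dic = d_bar + p_d, p_d = p_d, mean_deviance = d_bar)
}

#' Bayesian pairwise isolation-by-distance mixed model
#'
#' Fits `y_ij = b0 + b1 log_dist + b2 taxon_dist + u_i + u_j + e_ij` to
#' logit-transformed pairwise F_ST, where the population random effects
#' `u` absorb the correlated error structure of pairwise observations.
#' Priors: coefficients normal(0, precision 0.001); random-effect and
#' residual precisions gamma(1, 0.01).  The full model and the two
#' single-covariate reductions (geography only, taxon only) are all fit and
#' compared by DIC (`DIC = mean deviance + p_D`, with
#' `p_D = mean deviance - deviance at the posterior means`).
#'
#' @param tbl an [ibd_pair_table()] result.
#' @param chains,n_iter,burnin,thin MCMC settings (defaults 3 chains of
#'   10000, burn-in 2000, thinning 5).
#' @param seed optional integer seed.
#' @return list of class `ibd_fit` with elements `full`, `geo_only`,
#'   `taxon_only` (each with `coef`, `sd_u`, `sd_e`, `dic`) and `dic`
#'   (named vector, increasing order preferred).
#' @export
fit_ibd_model <- function(tbl, chains = 3, n_iter = 10000, burnin = 2000,
                          thin = 5, seed = NULL) {
  pops <- sort(unique(c(tbl$pop_i, tbl$pop_j)))
  if (length(pops) < 4) stop("need at least 4 populations")
  y <- tbl$logit_fst
  if (!all(is.finite(y))) stop("non-finite logit F_ST in the pair table")
  if (sd(y) < 1e-10)
    stop("degenerate input: pairwise differentiation has no variance")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(tbl)
  Z <- matrix(0, m, length(pops), dimnames = list(NULL, pops))
  Z[cbind(seq_len(m), match(tbl$pop_i, pops))] <- 1
  Z[cbind(seq_len(m), match(tbl$pop_j, pops))] <- 1
  designs <- list(
    full = cbind(intercept = 1, log_dist = tbl$log_dist,
                 taxon_dist = tbl$taxon_dist),
    geo_only = cbind(intercept = 1, log_dist = tbl$log_dist),
    taxon_only = cbind(intercept = 1, taxon_dist = tbl$taxon_dist))
  fits <- lapply(designs, function(X)
    ibd_gibbs(y, X, Z, chains, n_iter, burnin, thin))
  dic <- vapply(fits, `[[`, numeric(1), "dic")
  structure(c(fits, list(dic = dic, preferred = names(which.min(dic)))),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("isolation-by-distance mixed model (logit F_ST)\n")
  cat("DIC:", paste(names(x$dic), round(x$dic, 2), sep = " = ",
                    collapse = ", "), "\n")
  cat("preferred model:", x$preferred, "\n\n")
  print(x$full$coef)
  invisible(x)
}
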