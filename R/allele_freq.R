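# Population allele frequencies from genotype likelihoods via EM, and
# designation of ancestry-informative markers (AIMs).

#' EM estimation of population allele frequencies
#'
#' For each population the counted-allele frequency `p` is estimated from
#' genotype likelihoods by expectation-maximization under a Hardy-Weinberg
#' prior: at every iteration `p <- (1/2n) * sum_i E[g_i | GL_i, p]`, which is
#' the maximizer of the observed-data likelihood at convergence.  Individuals
#' with flat (all-equal) likelihood triples carry no information and leave
#' the estimate at the symmetric initialization of 0.5.
#'
#' @param gl a [gl_matrix()].
#' @param pops a [population_map()] covering the individuals of `gl`.
#' @param tol convergence tolerance on `max |delta p|` (default 0.001).
#' @param max_iter maximum EM sweeps (default 20).
#' @param init initial frequency for every locus (default 0.5).
#' @return a `data.frame` of class `allele_freq_table` with columns
#'   `population`, `locus_id`, `p`, `n_eff` (individuals with informative
#'   data), `flagged` (`TRUE` when no individual was informative).  The
#'   per-population log-likelihood trace is kept in `attr(, "loglik")`.
#' @export
em_allele_frequencies <- function(gl, pops, tol = 0.001, max_iter = 20,
                                  init = 0.5) {
  stopifnot(inherits(gl, "gl_matrix"))
  pops <- pops[match(gl$individuals, pops$individual_id), , drop = FALSE]
  if (anyNA(pops$individual_id))
    stop("population map is missing some individuals in the gl matrix")
  L <- nrow(gl$loci)
  flat <- gl_is_flat(gl)
  res <- list()
  loglik_trace <- list()
  for (pop in unique(pops$population_id)) {
    cols <- which(pops$population_id == pop)
    G0 <- gl$gl[, cols, 1, drop = FALSE]; dim(G0) <- c(L, length(cols))
    G1 <- gl$gl[, cols, 2, drop = FALSE]; dim(G1) <- c(L, length(cols))
    G2 <- gl$gl[, cols, 3, drop = FALSE]; dim(G2) <- c(L, length(cols))
    p <- rep(init, L)
    ll <- numeric(0)
    for (it in seq_len(max_iter)) {
      w0 <- (1 - p)^2; w1 <- 2 * p * (1 - p); w2 <- p^2
      denom <- G0 * w0 + G1 * w1 + G2 * w2
      ll <- c(ll, sum(log(pmax(denom, 1e-300))))
      eg <- (G1 * w1 + 2 * G2 * w2) / pmax(denom, 1e-300)
      p_new <- rowMeans(eg) / 2
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) break
    }
    n_eff <- rowSums(!flat[, cols, drop = FALSE])
    res[[pop]] <- data.frame(population = pop,
                             locus_id = gl$loci$locus_id,
                             p = p, n_eff = n_eff,
                             flagged = n_eff == 0L,
                             stringsAsFactors = FALSE)
    loglik_trace[[pop]] <- ll
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "loglik") <- loglik_trace
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

#' Reshape an allele-frequency table to a loci x populations matrix
#'
#' @param freqs an [em_allele_frequencies()] result (or any data frame with
#'   `population`, `locus_id`, `p`).
#' @return numeric matrix with locus ids as row names and populations as
#'   column names.
#' @export
freq_matrix <- function(freqs) {
  pops <- unique(freqs$population)
  loci <- unique(freqs$locus_id)
  m <- matrix(NA_real_, length(loci), length(pops),
              dimnames = list(loci, pops))
  m[cbind(match(freqs$locus_id, loci), match(freqs$population, pops))] <-
    freqs$p
  m
}

#' Designate ancestry-informative markers
#'
#' AIMs are loci whose parental allele-frequency difference
#' `d = |pbar1 - pbar0|` is at least `threshold` (inclusive), where the
#' parental frequencies are unweighted means over the listed reference
#' populations.
#'
#' @param freqs an [em_allele_frequencies()] result.
#' @param parent0,parent1 character vectors of population ids for the two
#'   parental gene pools.
#' @param threshold inclusive difference threshold (default 0.3).
#' @return a list of class `aim_set`: `loci` (member locus ids), `d`
#'   (named differences for all loci), `p0`, `p1` (named parental mean
#'   frequencies), `threshold`, `parent0`, `parent1`.
#' @export
designate_aims <- function(freqs, parent0, parent1, threshold = 0.3) {
  fm <- freq_matrix(freqs)
  missing_pops <- setdiff(c(parent0, parent1), colnames(fm))
  if (length(missing_pops))
    stop("populations absent from frequency table: ",
         paste(missing_pops, collapse = ", "))
  p0 <- rowMeans(fm[, parent0, drop = FALSE])
  p1 <- rowMeans(fm[, parent1, drop = FALSE])
  d <- abs(p1 - p0)
  # guard against representation error right at the threshold boundary
  members <- names(d)[d >= threshold - 1e-12]
  if (!length(members))
    warning("no locus reaches the AIM threshold of ", threshold)
  structure(list(loci = members, d = d, p0 = p0, p1 = p1,
                 threshold = threshold,
                 parent0 = parent0, parent1 = parent1),
            class = "aim_set")
}

#' @export
print.aim_set <- function(x, ...) {
  cat("aim_set:", length(x$loci), "of", length(x$d),
      "loci with |p1 - p0| >=", x$threshold, "\n")
  invisible(x)
}

#' Expected heterozygosity
#'
#' `2 p (1 - p)` for an allele frequency `p`, the Hardy-Weinberg expected
#' heterozygosity used by the F_ST components H_S and H_T.
#'
#' @param p allele frequency (vectorized), must lie in `[0, 1]`.
#' @return numeric vector.
#' @export
expected_heterozygosity <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("allele frequencies must lie in [0, 1]")
  2 * p * (1 - p)
}
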