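# The randomization framework: top-quantile locus sets, x-fold enrichment
# of set overlap and of category membership (Z chromosome, near-feature),
# chromosome-size correlations, and the full consistency grid comparing
# contemporary-zone cline deviations with ancient-hybrid ancestry extremes.

new_enrichment_result <- function(observed, null, x_fold, p, n_perm,
                                  direction) {
  structure(list(observed = observed,
                 null_mean = mean(null), null_sd = sd(null),
                 null_quantiles = quantile(null, c(0.025, 0.5, 0.975),
                                           names = FALSE),
                 x_fold = x_fold, p_one_sided = p,
                 n_perm = n_perm, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed = %g, null mean = %.3f, x-fold = %.3f, one-sided P = %.4g (%s, %d perms)\n",
    x$observed, x$null_mean, x$x_fold, x$p_one_sided, x$direction, x$n_perm))
  invisible(x)
}

#' Top-quantile locus set
#'
#' The `floor(q * N)` loci with the largest (`direction = "top"`) or
#' smallest (`"bottom"`) scores, with ties broken stably by locus order.  A
#' tie crossing the cutoff is reported with a message.
#'
#' @param scores named numeric vector of per-locus scores (names are locus
#'   ids; unnamed vectors get integer ids).
#' @param q fraction in `(0, 1]`.
#' @param direction `"top"` or `"bottom"`.
#' @return list of class `locus_set` with `members`, `q`, `direction`,
#'   `n_universe`.
#' @export
topq_set <- function(scores, q, direction = c("top", "bottom")) {
  direction <- match.arg(direction)
  stopifnot(q > 0, q <= 1, !anyNA(scores))
  if (is.null(names(scores))) names(scores) <- as.character(seq_along(scores))
  if (diff(range(scores)) == 0)
    stop("all scores equal: top-quantile set is undefined")
  N <- length(scores)
  size <- max(floor(q * N), 1L)
  key <- if (direction == "top") -scores else scores
  ord <- order(key, seq_len(N))
  cut_val <- scores[ord[size]]
  if (size < N && scores[ord[size + 1L]] == cut_val)
    message("tie at the quantile cutoff (score = ", signif(cut_val, 6),
            "); broken by locus order")
  structure(list(members = names(scores)[ord[seq_len(size)]],
                 q = q, direction = direction, n_universe = N,
                 universe = names(scores)),
            class = "locus_set")
}

#' Set-overlap randomization test (x-fold enrichment)
#'
#' Observed statistic is the intersection size of two locus sets drawn from
#' the same universe of `N` loci.  Each permutation relabels one set's
#' membership uniformly at random over the `N` loci; x-fold enrichment is
#' observed / null mean and the one-sided P-value uses the add-one
#' estimator `(1 + #(perm >= observed)) / (n_perm + 1)`.
#'
#' @param setA,setB [topq_set()] results, or character vectors of member
#'   ids (then `universe` must be given).
#' @param universe character vector of all locus ids (defaults to the
#'   universe recorded in `setA`).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return an `enrichment_result`.
#' @export
overlap_randomization_test <- function(setA, setB, universe = NULL,
                                       n_perm = 10000, seed = NULL) {
  if (inherits(setA, "locus_set")) {
    universe <- universe %||% setA$universe
    setA <- setA$members
  }
  if (inherits(setB, "locus_set")) setB <- setB$members
  if (is.null(universe)) stop("a locus universe is required")
  if (n_perm < 100) warning("fewer than 100 permutations: unstable null")
  if (!is.null(seed)) set.seed(seed)
  N <- length(universe)
  a <- length(setA)
  inB <- universe %in% setB
  observed <- sum(setA %in% setB)
  null <- vapply(seq_len(n_perm),
                 function(i) sum(inB[sample.int(N, a)]), numeric(1))
  x_fold <- observed / mean(null)
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  new_enrichment_result(observed, null, x_fold, p, n_perm, "excess")
}

#' Category randomization test (x-fold enrichment or deficit)
#'
#' Observed statistic is the number of set members carrying a binary
#' category label (e.g. Z-linked, near-gene).  Permutations relabel the set
#' uniformly over the universe.  `direction = "deficit"` computes the
#' lower-tail P (`perm <= observed`).
#'
#' @param set a [topq_set()] or character vector of member ids.
#' @param membership logical vector over the universe (named by locus id,
#'   or aligned with `universe`).
#' @param universe locus ids; defaults to `names(membership)` or the set's
#'   recorded universe.
#' @param n_perm permutations (default 1000).
#' @param direction `"excess"` or `"deficit"`.
#' @param seed optional integer seed.
#' @return an `enrichment_result`.
#' @export
category_enrichment_test <- function(set, membership, universe = NULL,
                                     n_perm = 1000,
                                     direction = c("excess", "deficit"),
                                     seed = NULL) {
  direction <- match.arg(direction)
  if (inherits(set, "locus_set")) {
    universe <- universe %||% set$universe
    set <- set$members
  }
  universe <- universe %||% names(membership)
  if (is.null(universe)) stop("a locus universe is required")
  stopifnot(length(membership) == length(universe))
  if (!any(membership))
    stop("membership is false for every locus: x-fold undefined")
  if (n_perm < 100) warning("fewer than 100 permutations: unstable null")
  if (!is.null(seed)) set.seed(seed)
  N <- length(universe)
  k <- length(set)
  idx <- match(set, universe)
  observed <- sum(membership[idx])
  null <- vapply(seq_len(n_perm),
                 function(i) sum(membership[sample.int(N, k)]), numeric(1))
  x_fold <- observed / mean(null)
  p <- if (direction == "excess")
    (1 + sum(null >= observed)) / (n_perm + 1)
  else
    (1 + sum(null <= observed)) / (n_perm + 1)
  new_enrichment_result(observed, null, x_fold, p, n_perm, direction)
}

#' Correlation between a per-chromosome proportion and chromosome size
#'
#' Pearson correlation with the two-sided P from the usual t transform on
#' `n - 2` degrees of freedom (via [stats::cor.test()]), optionally
#' excluding named chromosomes (e.g. the Z) in a companion run.
#'
#' @param proportion per-chromosome proportions.
#' @param size_bp per-chromosome sizes (bp).
#' @param chromosome optional chromosome names (for `exclude`).
#' @param exclude chromosomes to drop before computing.
#' @return list with `r`, `p_two_sided`, `n`.
#' @export
proportion_size_correlation <- function(proportion, size_bp,
                                        chromosome = NULL, exclude = NULL) {
  if (!is.null(exclude)) {
    if (is.null(chromosome)) stop("chromosome names needed to exclude")
    keep <- !(chromosome %in% exclude)
    proportion <- proportion[keep]
    size_bp <- size_bp[keep]
  }
  if (length(proportion) < 3) stop("need at least 3 chromosomes")
  if (sd(proportion) == 0 || sd(size_bp) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(proportion, size_bp, method = "pearson")
  list(r = unname(ct$estimate), p_two_sided = ct$p.value,
       n = length(proportion))
}

#' Consistency grid: cline deviations versus ancestry extremes
#'
#' Runs the overlap randomization test for the nine standard comparisons
#' between contemporary-zone cline scores and ancient-hybrid ancestry
#' frequencies, across a ladder of top quantiles and chromosome scopes:
#' high alpha, low alpha and high beta in the zone, each against high
#' parent-1 ancestry, high parent-0 ancestry, and extreme (near-fixed
#' either way) ancestry in the ancient hybrids.
#'
#' Under the default `scope_rule = "within_scope"`, scope-restricted runs
#' (autosomes-only, Z-only) rebuild the top-quantile sets and permute within
#' the scope; `"global_sets_scoped_null"` instead intersects genome-wide
#' sets with the scope and permutes within it.
#'
#' @param cline_est a [fit_genomic_clines()] result.
#' @param track an [fit_ancestry_frequencies()] result on the same AIMs
#'   (or an averaged track with the same columns).
#' @param quantiles quantile ladder (default 10% down to 1%).
#' @param scopes subset of `c("all", "autosomes", "Z")`.
#' @param n_perm permutations per cell (default 1000).
#' @param scope_rule see Details.
#' @param seed optional integer seed.
#' @return long `data.frame`: `comparison`, `quantile`, `scope`,
#'   `observed`, `null_mean`, `x_fold`, `p_one_sided`, `significant`
#'   (P <= 0.05).
#' @export
consistency_suite <- function(cline_est, track,
                              quantiles = seq(0.10, 0.01, by = -0.01),
                              scopes = c("all", "autosomes", "Z"),
                              n_perm = 1000,
                              scope_rule = c("within_scope",
                                             "global_sets_scoped_null"),
                              seed = NULL) {
  scope_rule <- match.arg(scope_rule)
  scopes <- match.arg(scopes, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  m <- match(cline_est$locus_id, track$locus_id)
  if (anyNA(m)) stop("cline fit and ancestry track cover different AIMs")
  q_anc <- track$q_hat[m]
  is_Z <- cline_est$is_Z
  ids <- cline_est$locus_id
  zone_scores <- list(high_alpha = list(s = cline_est$alpha_mean, d = "top"),
                      low_alpha = list(s = cline_est$alpha_mean, d = "bottom"),
                      high_beta = list(s = cline_est$beta_mean, d = "top"))
  anc_scores <- list(high_parent1_ancestry = list(s = q_anc, d = "top"),
                     high_parent0_ancestry = list(s = q_anc, d = "bottom"),
                     extreme_ancestry = list(s = pmax(q_anc, 1 - q_anc),
                                             d = "top"))
  comparisons <- expand.grid(zone = names(zone_scores),
                             ancient = names(anc_scores),
                             stringsAsFactors = FALSE)
  rows <- list()
  for (scope in scopes) {
    in_scope <- switch(scope, all = rep(TRUE, length(ids)),
                       autosomes = !is_Z, Z = is_Z)
    if (!any(in_scope)) next
    for (ci in seq_len(nrow(comparisons))) {
      zs <- zone_scores[[comparisons$zone[ci]]]
      as_ <- anc_scores[[comparisons$ancient[ci]]]
      for (qq in quantiles) {
        res <- tryCatch({
          if (scope_rule == "within_scope") {
            sA <- topq_set(setNames(zs$s[in_scope], ids[in_scope]), qq,
                           zs$d)
            sB <- topq_set(setNames(as_$s[in_scope], ids[in_scope]), qq,
                           as_$d)
            uni <- ids[in_scope]
          } else {
            sA0 <- topq_set(setNames(zs$s, ids), qq, zs$d)
            sB0 <- topq_set(setNames(as_$s, ids), qq, as_$d)
            sA <- intersect(sA0$members, ids[in_scope])
            sB <- intersect(sB0$members, ids[in_scope])
            uni <- ids[in_scope]
          }
          nA <- if (inherits(sA, "locus_set")) length(sA$members) else
            length(sA)
          if (nA == 0) stop("empty set in scope")
          overlap_randomization_test(sA, sB, universe = uni,
                                     n_perm = n_perm)
        }, error = function(e) NULL)
        if (is.null(res)) {
          message("skipped ", comparisons$zone[ci], " vs ",
                  comparisons$ancient[ci], " at q = ", qq, ", scope ",
                  scope)
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          comparison = paste(comparisons$zone[ci], "vs",
                             comparisons$ancient[ci]),
          quantile = qq, scope = scope,
          observed = res$observed, null_mean = res$null_mean,
          x_fold = res$x_fold, p_one_sided = res$p_one_sided,
          significant = res$p_one_sided <= 0.05,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
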