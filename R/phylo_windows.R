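# Five-lineage phylogenomic windows: nonoverlapping 1000-SNP windows,
# exhaustive topology scoring over the 15 unrooted binary 5-taxon trees
# (Fitch parsimony by default, least-squares minimum evolution as an
# alternative), randomization tests for topology excess/deficit by window
# class, and f_d admixture proportions.

# cache of topology sets / scoring tables, keyed by the taxon vector
.phylo_cache <- new.env(parent = emptyenv())

#' The 15 unrooted binary topologies for five taxa
#'
#' Canonical, stable enumeration (ids 1..15) used everywhere a topology id
#' appears.  Trees are `ape` "phylo" objects.
#'
#' @param taxa character vector of 5 taxon names; the order fixes the
#'   enumeration.
#' @return list of 15 unrooted `phylo` trees.
#' @export
five_taxon_topologies <- function(taxa) {
  stopifnot(length(taxa) == 5, !anyDuplicated(taxa))
  key <- paste(taxa, collapse = "\r")
  if (!is.null(.phylo_cache[[key]])) return(.phylo_cache[[key]]$trees)
  trees <- phangorn::allTrees(5, rooted = FALSE, tip.label = taxa)
  trees <- unclass(ape::.uncompressTipLabel(trees))
  .phylo_cache[[key]] <- list(trees = trees)
  trees
}

#' Canonical topology id of a tree
#'
#' Matches an (unrooted) tree on the same 5 taxa against the canonical
#' enumeration of [five_taxon_topologies()], ignoring branch lengths.
#' Useful for importing externally inferred per-window trees from Newick.
#'
#' @param tree a `phylo` object (e.g. from [ape::read.tree()]).
#' @param taxa the canonical taxon vector.
#' @return integer id in 1..15.
#' @export
topology_id <- function(tree, taxa) {
  stopifnot(setequal(tree$tip.label, taxa))
  ref <- five_taxon_topologies(taxa)
  tree <- ape::unroot(tree)
  d <- vapply(ref, function(t) phangorn::RF.dist(tree, t), numeric(1))
  id <- which(d == 0)
  if (length(id) != 1) stop("tree does not match a binary 5-taxon topology")
  id
}

# Fitch parsimony length of one site pattern on a binary rooted tree,
# states coded as bitmasks over the two alleles (1 = {0}, 2 = {1},
# 3 = {0,1} ambiguous/heterozygous).
fitch_length <- function(tree, tip_masks) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- max(tr$edge)
  mask <- integer(nnode)
  mask[seq_along(tip_masks)] <- tip_masks
  cost <- 0L
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    if (mask[par] == 0L) {
      mask[par] <- mask[child]
    } else {
      inter <- bitwAnd(mask[par], mask[child])
      if (inter == 0L) {
        mask[par] <- bitwOr(mask[par], mask[child])
        cost <- cost + 1L
      } else {
        mask[par] <- inter
      }
    }
  }
  cost
}

# Precomputed 243 x 15 table of Fitch lengths for every 5-taxon pattern of
# states {0, 0.5, 1}; plus the 10 x 7 pair-path design matrices for the
# least-squares method.  Cached per taxon set.
phylo_tables <- function(taxa) {
  key <- paste(taxa, collapse = "\r")
  five_taxon_topologies(taxa)  # populate cache
  cache <- .phylo_cache[[key]]
  if (!is.null(cache$fitch)) return(cache)
  trees <- cache$trees
  rooted <- lapply(trees, function(t)
    ape::root(t, outgroup = taxa[5], resolve.root = TRUE))
  # row i = digits of i-1 in base 3, taxon 1 least significant, matching
  # the pattern index computed in infer_window_topology()
  codes <- as.matrix(expand.grid(rep(list(0:2), 5)))
  state_mask <- c(1L, 3L, 2L)  # 0 -> {0}, 0.5 -> {0,1}, 1 -> {1}
  fitch <- matrix(0L, nrow(codes), length(trees))
  for (j in seq_along(trees)) {
    for (i in seq_len(nrow(codes)))
      fitch[i, j] <- fitch_length(rooted[[j]], state_mask[codes[i, ] + 1L])
  }
  pairs <- utils::combn(5, 2)
  paths <- lapply(trees, function(t) {
    P <- matrix(0, ncol(pairs), nrow(t$edge))
    for (k in seq_len(ncol(pairs))) {
      np <- ape::nodepath(t, pairs[1, k], pairs[2, k])
      for (s in seq_len(length(np) - 1L)) {
        e <- which((t$edge[, 1] == np[s] & t$edge[, 2] == np[s + 1]) |
                     (t$edge[, 2] == np[s] & t$edge[, 1] == np[s + 1]))
        P[k, e] <- 1
      }
    }
    P
  })
  cache$fitch <- fitch
  cache$paths <- paths
  cache$pairs <- pairs
  .phylo_cache[[key]] <- cache
  cache
}

#' Split a locus order into nonoverlapping SNP windows
#'
#' Consecutive blocks of exactly `window_snps` loci per chromosome; a
#' trailing remainder shorter than a window is dropped (reported with a
#' message).  Windows never span chromosomes.
#'
#' @param loci a [locus_map()] (rows define the locus order).
#' @param window_snps SNPs per window (default 1000).
#' @return `data.frame`: `window_id`, `chromosome`, `start`, `end`
#'   (0-based half-open indexes into the locus order), `is_Z`.
#' @export
split_windows <- function(loci, window_snps = 1000) {
  stopifnot(window_snps >= 2)
  rows <- list()
  dropped <- 0L
  wid <- 0L
  for (chr in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == chr)
    nw <- length(idx) %/% window_snps
    dropped <- dropped + length(idx) - nw * window_snps
    if (nw == 0L) next
    for (k in seq_len(nw)) {
      wid <- wid + 1L
      s <- idx[1] - 1L + (k - 1L) * window_snps
      rows[[wid]] <- data.frame(window_id = wid, chromosome = chr,
                                start = s, end = s + window_snps,
                                is_Z = loci$is_Z[idx[1]],
                                stringsAsFactors = FALSE)
    }
  }
  if (dropped > 0)
    message(dropped, " trailing loci dropped (shorter than a window)")
  if (!length(rows))
    return(data.frame(window_id = integer(), chromosome = character(),
                      start = integer(), end = integer(),
                      is_Z = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Infer the topology of one SNP window
#'
#' Scores all 15 unrooted binary topologies and returns the best.
#' `parsimony`: Fitch length summed over sites, heterozygous calls (0.5)
#' treated as ambiguity sets.  `me_ls`: ordinary least-squares branch
#' lengths (clamped at zero) fit to pairwise mean-difference distances;
#' score is the residual sum of squares.  Ties are flagged and broken by
#' the lowest canonical id; an all-invariant window ties across all 15
#' topologies and is flagged uninformative.
#'
#' @param x numeric matrix, 5 taxa in rows (row names = taxon names),
#'   sites in columns, values in `{0, 0.5, 1}`.
#' @param method `"parsimony"` (default) or `"me_ls"`.
#' @param taxa taxon order fixing the canonical enumeration (default row
#'   names of `x`).
#' @return list: `topology` (id 1..15), `score`, `tie` (logical),
#'   `uninformative` (tie across all 15).
#' @export
infer_window_topology <- function(x, method = c("parsimony", "me_ls"),
                                  taxa = rownames(x)) {
  method <- match.arg(method)
  stopifnot(nrow(x) == 5, !is.null(taxa))
  x <- x[taxa, , drop = FALSE]
  if (method == "parsimony") {
    tab <- phylo_tables(taxa)
    codes <- round(2 * x)  # 0, 1 (= het), 2
    pat <- 1L + as.integer(codes[1, ] + 3 * codes[2, ] + 9 * codes[3, ] +
                             27 * codes[4, ] + 81 * codes[5, ])
    counts <- tabulate(pat, nbins = 243)
    scores <- as.vector(counts %*% tab$fitch)
  } else {
    tab <- phylo_tables(taxa)
    d <- apply(tab$pairs, 2, function(pr)
      mean(abs(x[pr[1], ] - x[pr[2], ])))
    scores <- vapply(tab$paths, function(P) {
      b <- pmax(qr.solve(crossprod(P), crossprod(P, d)), 0)
      sum((d - P %*% b)^2)
    }, numeric(1))
  }
  best <- min(scores)
  hits <- which(scores <= best + 1e-9)
  list(topology = hits[1], score = best, tie = length(hits) > 1,
       uninformative = length(hits) == 15L)
}

#' Infer topologies for all windows
#'
#' Applies [infer_window_topology()] to every window of a
#' [split_windows()] table.
#'
#' @param windows a [split_windows()] result.
#' @param x 5 x total-loci matrix of taxon calls (`{0, 0.5, 1}`), columns
#'   in locus order.
#' @param method passed to [infer_window_topology()].
#' @return the `windows` data frame of class `window_topology_table` with
#'   added columns `topology`, `score`, `tie`, `uninformative`.
#' @export
infer_topologies <- function(windows, x, method = "parsimony") {
  res <- lapply(seq_len(nrow(windows)), function(k) {
    cols <- seq.int(windows$start[k] + 1L, windows$end[k])
    infer_window_topology(x[, cols, drop = FALSE], method = method)
  })
  windows$topology <- vapply(res, `[[`, numeric(1), "topology")
  windows$score <- vapply(res, `[[`, numeric(1), "score")
  windows$tie <- vapply(res, `[[`, logical(1), "tie")
  windows$uninformative <- vapply(res, `[[`, logical(1), "uninformative")
  class(windows) <- c("window_topology_table", "data.frame")
  windows
}

#' Topology excess/deficit randomization test by window class
#'
#' Observed statistic is the count of `target_topology` among the class
#' windows (e.g. Z-chromosome windows, barrier-locus windows); the null
#' permutes topology labels across all windows.
#'
#' @param table an [infer_topologies()] result (needs `window_id`,
#'   `topology`).
#' @param target_topology canonical topology id.
#' @param class_members window ids (or logical over rows) defining the
#'   class.
#' @param n_perm permutations (default 1000).
#' @param direction `"excess"` or `"deficit"`.
#' @param seed optional integer seed.
#' @return an `enrichment_result`.
#' @export
topology_class_test <- function(table, target_topology, class_members,
                                n_perm = 1000,
                                direction = c("excess", "deficit"),
                                seed = NULL) {
  direction <- match.arg(direction)
  if (is.logical(class_members)) class_members <-
      table$window_id[class_members]
  idx <- match(class_members, table$window_id)
  if (!length(idx) || anyNA(idx)) stop("empty or unknown window class")
  if (!any(table$topology == target_topology))
    stop("target topology absent genome-wide: x-fold undefined")
  if (!is.null(seed)) set.seed(seed)
  labels <- table$topology
  observed <- sum(labels[idx] == target_topology)
  null <- vapply(seq_len(n_perm),
                 function(i) sum(sample(labels)[idx] == target_topology),
                 numeric(1))
  x_fold <- observed / mean(null)
  p <- if (direction == "excess")
    (1 + sum(null >= observed)) / (n_perm + 1)
  else
    (1 + sum(null <= observed)) / (n_perm + 1)
  new_enrichment_result(observed, null, x_fold, p, n_perm, direction)
}

#' f_d admixture proportion
#'
#' ABBA-BABA-based estimator of the admixture proportion between the
#' candidate donor P3 and recipient P2 given the quartet (((P1, P2), P3),
#' O).  Per site, `ABBA = (1-p1) p2 p3 (1-pO)` and
#' `BABA = p1 (1-p2) p3 (1-pO)`; the numerator is `sum(ABBA - BABA)` and
#' the denominator is the same sum recomputed with the donor frequency
#' `pD = max(p2, p3)` substituted for both P2 and P3 (the complete-sharing
#' scenario), so `f_d = 1` in the complete-sharing limit.  Sites with any
#' missing value are skipped.
#'
#' @param p1,p2,p3,pO derived-allele frequencies (or single-genome calls in
#'   `{0, 0.5, 1}`) for the four roles.
#' @return list of class `fd_result`: `fd`, `s_num`, `s_den`, `abba`,
#'   `baba` (summed), `n_sites`, `undefined` flag.
#' @export
fd_statistic <- function(p1, p2, p3, pO) {
  n <- length(p1)
  stopifnot(length(p2) == n, length(p3) == n, length(pO) == n)
  keep <- !(is.na(p1) | is.na(p2) | is.na(p3) | is.na(pO))
  p1 <- p1[keep]; p2 <- p2[keep]; p3 <- p3[keep]; pO <- pO[keep]
  abba <- (1 - p1) * p2 * p3 * (1 - pO)
  baba <- p1 * (1 - p2) * p3 * (1 - pO)
  pD <- pmax(p2, p3)
  abba_d <- (1 - p1) * pD * pD * (1 - pO)
  baba_d <- p1 * (1 - pD) * pD * (1 - pO)
  s_num <- sum(abba - baba)
  s_den <- sum(abba_d - baba_d)
  undefined <- s_den == 0
  structure(list(fd = if (undefined) NA_real_ else s_num / s_den,
                 s_num = s_num, s_den = s_den,
                 abba = sum(abba), baba = sum(baba),
                 n_sites = length(p1), undefined = undefined),
            class = "fd_result")
}

#' f_d per window or chromosome
#'
#' Convenience wrapper evaluating [fd_statistic()] over groups of loci.
#'
#' @param x 5 x loci matrix of taxon calls.
#' @param roles named list/vector mapping `P1`, `P2`, `P3`, `O` to row
#'   names of `x` (roles must be passed explicitly).
#' @param groups factor/vector over columns of `x` (e.g. chromosome, or
#'   window id).
#' @return `data.frame`: `group`, `fd`, `s_num`, `s_den`, `n_sites`,
#'   `undefined`.
#' @export
fd_by_group <- function(x, roles, groups) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(roles)))
  rows <- lapply(split(seq_len(ncol(x)), groups), function(cols) {
    r <- fd_statistic(x[roles[["P1"]], cols], x[roles[["P2"]], cols],
                      x[roles[["P3"]], cols], x[roles[["O"]], cols])
    data.frame(fd = r$fd, s_num = r$s_num, s_den = r$s_den,
               n_sites = r$n_sites, undefined = r$undefined)
  })
  out <- do.call(rbind, rows)
  out <- cbind(group = names(rows), out)
  rownames(out) <- NULL
  out
}

#' Null test for reduced admixture in a candidate window set
#'
#' Compares the mean f_d over a candidate set of windows against the mean
#' over repeated random draws of equally many windows.  The one-sided
#' P-value is for *reduced* admixture (lower tail), with ties between null
#' and observed split evenly so that a degenerate null (candidate set =
#' all windows) yields P near 0.5.  Windows with undefined f_d are
#' excluded from both the candidate set and the null pool (reported).
#'
#' @param fd_window numeric vector of per-window f_d values.
#' @param candidate indices (or logical) of the candidate windows.
#' @param n_draws random draws (default 1000).
#' @param seed optional integer seed.
#' @return an `enrichment_result` (with `x_fold` = observed mean / null
#'   mean of means).
#' @export
fd_window_set_test <- function(fd_window, candidate, n_draws = 1000,
                               seed = NULL) {
  if (is.logical(candidate)) candidate <- which(candidate)
  ok <- which(!is.na(fd_window))
  n_bad <- sum(is.na(fd_window[candidate]))
  if (n_bad > 0)
    message(n_bad, " candidate window(s) with undefined f_d excluded")
  candidate <- intersect(candidate, ok)
  k <- length(candidate)
  stopifnot(k >= 1, k <= length(ok))
  if (!is.null(seed)) set.seed(seed)
  observed <- mean(fd_window[candidate])
  pool <- fd_window[ok]
  null <- vapply(seq_len(n_draws),
                 function(i) mean(pool[sample.int(length(pool), k)]),
                 numeric(1))
  tol <- 1e-12
  p <- (1 + sum(null < observed - tol) +
          0.5 * sum(abs(null - observed) <= tol)) / (n_draws + 1)
  new_enrichment_result(observed, null, observed / mean(null), p,
                        n_draws, "deficit")
}

#' Correlation between a topology's per-chromosome frequency and size
#'
#' Delegates to [proportion_size_correlation()].
#'
#' @inheritParams proportion_size_correlation
#' @return list with `r`, `p_two_sided`, `n`.
#' @export
topology_size_correlation <- function(proportion, size_bp,
                                      chromosome = NULL, exclude = NULL) {
  proportion_size_correlation(proportion, size_bp, chromosome, exclude)
}
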