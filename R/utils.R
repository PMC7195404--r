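# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x, eps = 0) pmin(1 - eps, pmax(eps, x))

logit <- function(p) log(p / (1 - p))

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Standard split-R-hat convergence diagnostic: each chain is split in half
#' and the usual between/within variance ratio is computed on the resulting
#' half-chains.  Values near 1 indicate mixing; > 1.1 flags a problem.
#'
#' @param draws numeric matrix of posterior draws, iterations in rows and
#'   chains in columns (a vector is treated as a single chain).
#' @return a single numeric R-hat value.
#' @export
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  n <- nrow(draws)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  x <- cbind(draws[seq_len(half), , drop = FALSE],
             draws[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(x)
  nn <- nrow(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  w <- mean(s2)
  if (!is.finite(w) || w <= 0) return(1)
  b <- nn * stats::var(mu)
  sqrt(((nn - 1) / nn * w + b / nn) / w)
}

# Centered moving average with window `w` (odd), truncated at the ends of
# each chromosome: positions near an edge average over the loci actually
# available.  Used as the local prior mean of the ancestry model.
window_mean <- function(x, w, chromosome) {
  stopifnot(w >= 1L, w %% 2L == 1L)
  if (w == 1L) return(x)
  half <- (w - 1L) %/% 2L
  out <- numeric(length(x))
  for (chr in unique(chromosome)) {
    idx <- which(chromosome == chr)
    xi <- x[idx]
    n <- length(xi)
    cs <- cumsum(c(0, xi))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    out[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# Write a data frame as TSV with leading '#' comment lines recording the
# run configuration; read back with read_result_tsv().
write_result_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
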