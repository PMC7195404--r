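# Fixture builders shared across the suite.  Everything is generated in
# code; no stored data files.

# genotype-likelihood matrix with certain genotypes (triple = 1 at the true
# genotype, 0 elsewhere)
certain_gl <- function(geno, loci = NULL, individuals = NULL) {
  nl <- nrow(geno); n <- ncol(geno)
  if (is.null(loci))
    loci <- locus_map(paste0("l", seq_len(nl)), "chr1",
                      seq_len(nl) * 100L)
  if (is.null(individuals)) individuals <- paste0("i", seq_len(n))
  gl <- array(0, c(nl, n, 3))
  for (g in 0:2) gl[, , g + 1L][geno == g] <- 1
  gl_matrix(gl, loci, individuals)
}

# noisy triples: certain genotype contaminated with uniform noise
noisy_gl <- function(geno, noise = 0.2, loci = NULL, individuals = NULL) {
  nl <- nrow(geno); n <- ncol(geno)
  if (is.null(loci))
    loci <- locus_map(paste0("l", seq_len(nl)), "chr1",
                      seq_len(nl) * 100L)
  if (is.null(individuals)) individuals <- paste0("i", seq_len(n))
  gl <- array(runif(nl * n * 3, 0, noise), c(nl, n, 3))
  for (g in 0:2) gl[, , g + 1L][geno == g] <-
      gl[, , g + 1L][geno == g] + 1
  gl_matrix(gl, loci, individuals)
}

# brute-force marginal-likelihood grid search for a single locus's allele
# frequency (the EM oracle): GL triples in a 3-column matrix, one row per
# individual
grid_ml_freq <- function(tri, step = 1e-4) {
  p <- seq(0, 1, by = step)
  ll <- vapply(p, function(pp) {
    w <- c((1 - pp)^2, 2 * pp * (1 - pp), pp^2)
    sum(log(pmax(tri %*% w, 1e-300)))
  }, numeric(1))
  p[which.max(ll)]
}

# brute-force hybrid-index grid search for one individual (the oracle for
# estimate_hybrid_index): tri is loci x 3
grid_ml_h <- function(tri, p0, p1, step = 1e-4) {
  h <- seq(0, 1, by = step)
  ll <- vapply(h, function(hh) {
    pi <- hh * p1 + (1 - hh) * p0
    sum(log(pmax(tri[, 1] * (1 - pi)^2 + tri[, 2] * 2 * pi * (1 - pi) +
                   tri[, 3] * pi^2, 1e-300)))
  }, numeric(1))
  h[which.max(ll)]
}

# minimal VCF with PL genotype likelihoods, written to a temp file
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled likelihoods\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampA\tsampB",
    "chr1\t100\t.\tA\tT\t50\tPASS\t.\tGT:PL\t0/0:0,30,60\t1/1:60,30,0",
    "chr1\t200\t.\tG\tC\t50\tPASS\t.\tGT:PL\t0/1:20,0,20\t./.:.",
    "chr1\t300\t.\tT\tTA\t50\tPASS\t.\tGT:PL\t0/0:0,10,20\t0/0:0,10,20",
    "chr2\t100\t.\tC\tG\t50\tPASS\t.\tGT:PL\t0/0:0,40,80\t0/1:10,0,10")
  writeLines(lines, path)
  path
}

# quadrature oracle for the Balding-Nichols mixture: P(|p0 - p1| >= d)
# with ancestral frequency uniform on (lo, hi), via pbeta/dbeta integration
bn_diff_prob <- function(f, d = 0.3, lo = 0.05, hi = 0.95) {
  s <- (1 - f) / f
  inner <- function(pi) {
    a <- pi * s; b <- (1 - pi) * s
    g <- function(x) dbeta(x, a, b) *
      (pbeta(x - d, a, b) + 1 - pbeta(x + d, a, b))
    integrate(g, 0, 1, rel.tol = 1e-6, stop.on.error = FALSE)$value
  }
  integrate(Vectorize(inner), lo, hi, rel.tol = 1e-5,
            stop.on.error = FALSE)$value / (hi - lo)
}
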