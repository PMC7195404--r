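# Input containers and readers: locus/population maps, genotype-likelihood
# matrices (BEAGLE text and a minimal VCF GL/PL subset), BED-like feature
# tables.  Loci are 1-based (VCF convention); features are 0-based half-open
# (BED convention); the conversion happens only inside near_feature().

#' Construct a locus map
#'
#' A locus map names every biallelic SNP and places it on a chromosome
#' (linkage group), with a flag for the Z sex chromosome.  Positions must be
#' strictly increasing within a chromosome and locus ids unique.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome character vector of chromosome / linkage-group names.
#' @param position integer vector of 1-based bp positions.
#' @param is_Z logical; `TRUE` for Z-linked loci (recycled).
#' @return a `data.frame` of class `locus_map`.
#' @export
locus_map <- function(locus_id, chromosome, position, is_Z = FALSE) {
  df <- data.frame(locus_id = as.character(locus_id),
                   chromosome = as.character(chromosome),
                   position = as.integer(position),
                   is_Z = rep_len(as.logical(is_Z), length(locus_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$locus_id))
    stop("locus ids must be unique")
  for (chr in unique(df$chromosome)) {
    p <- df$position[df$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  class(df) <- c("locus_map", "data.frame")
  df
}

#' Construct a population map
#'
#' Assigns individuals to populations and taxon roles.  Roles follow the
#' parental/hybrid design: `parent0` and `parent1` mark the two reference
#' gene pools, `hybrid` the admixed population(s) under study.
#'
#' @param individual_id unique individual identifiers.
#' @param population_id population identifiers.
#' @param role one of `"parent0"`, `"parent1"`, `"hybrid"`, `"other"`
#'   (recycled).
#' @param sex one of `"male"`, `"female"`, `"unknown"` (recycled).
#' @return a `data.frame` of class `population_map`.
#' @export
population_map <- function(individual_id, population_id, role = "other",
                           sex = "unknown") {
  role <- match.arg(rep_len(role, length(individual_id)),
                    c("parent0", "parent1", "hybrid", "other"),
                    several.ok = TRUE)
  sex <- match.arg(rep_len(sex, length(individual_id)),
                   c("male", "female", "unknown"), several.ok = TRUE)
  df <- data.frame(individual_id = as.character(individual_id),
                   population_id = as.character(population_id),
                   role = role, sex = sex, stringsAsFactors = FALSE)
  if (anyDuplicated(df$individual_id))
    stop("individual ids must be unique")
  class(df) <- c("population_map", "data.frame")
  df
}

#' Construct a genotype-likelihood matrix
#'
#' Holds, for every (locus, individual) pair, the three likelihoods of
#' carrying 0, 1 or 2 copies of the counted allele.  Triples are normalized
#' to sum to one internally, so input may be rescaled by any positive
#' constant without changing downstream results.  An all-equal triple encodes
#' missing data; it is never dropped, downstream methods marginalize over it.
#'
#' @param gl numeric array `loci x individuals x 3` of nonnegative
#'   likelihoods.
#' @param loci a [locus_map()] with one row per slice of `gl`.
#' @param individuals character vector of individual ids.
#' @return a list of class `gl_matrix` with elements `loci`, `individuals`,
#'   `gl` (normalized array).
#' @export
gl_matrix <- function(gl, loci, individuals) {
  stopifnot(length(dim(gl)) == 3L, dim(gl)[3] == 3L)
  if (dim(gl)[1] != nrow(loci))
    stop("gl has ", dim(gl)[1], " loci but the locus map has ", nrow(loci))
  if (dim(gl)[2] != length(individuals))
    stop("gl has ", dim(gl)[2], " individuals but ", length(individuals),
         " ids were given")
  if (any(gl < 0) || any(!is.finite(gl)))
    stop("genotype likelihoods must be finite and nonnegative")
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  if (any(tot <= 0))
    stop("every genotype-likelihood triple needs at least one positive entry")
  gl <- gl / as.vector(tot)  # recycles over the genotype dimension
  structure(list(loci = loci, individuals = as.character(individuals),
                 gl = gl),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat("gl_matrix:", nrow(x$loci), "loci x", length(x$individuals),
      "individuals\n")
  cat("chromosomes:", length(unique(x$loci$chromosome)),
      " (Z loci:", sum(x$loci$is_Z), ")\n")
  invisible(x)
}

# TRUE where the (normalized) triple is uninformative (all entries equal).
gl_is_flat <- function(gl) {
  g <- gl$gl
  f <- abs(g[, , 1] - g[, , 2]) < 1e-9 & abs(g[, , 2] - g[, , 3]) < 1e-9
  if (is.null(dim(f))) f <- matrix(f, dim(g)[1], dim(g)[2])
  f
}

#' Subset a genotype-likelihood matrix
#'
#' Restrict a [gl_matrix()] to named loci and/or individuals (order taken
#' from the arguments).
#'
#' @param gl a [gl_matrix()].
#' @param locus_ids,individuals ids to keep (`NULL` keeps all).
#' @return a [gl_matrix()].
#' @export
gl_subset <- function(gl, locus_ids = NULL, individuals = NULL) {
  li <- if (is.null(locus_ids)) seq_len(nrow(gl$loci)) else
    match(locus_ids, gl$loci$locus_id)
  ii <- if (is.null(individuals)) seq_along(gl$individuals) else
    match(individuals, gl$individuals)
  if (anyNA(li)) stop("unknown locus id(s) in subset")
  if (anyNA(ii)) stop("unknown individual id(s) in subset")
  loci <- gl$loci[li, , drop = FALSE]
  rownames(loci) <- NULL
  class(loci) <- class(gl$loci)
  structure(list(loci = loci,
                 individuals = gl$individuals[ii],
                 gl = gl$gl[li, ii, , drop = FALSE]),
            class = "gl_matrix")
}

#' Read genotype likelihoods
#'
#' Reads a BEAGLE-style genotype-likelihood text table (three columns per
#' individual) or a minimal VCF carrying GL or PL tags.  PL values are
#' converted by `10^(-PL/10)`; non-biallelic VCF records are skipped with a
#' message.
#'
#' @param path file to read.
#' @param dialect `"beagle_gl"` or `"vcf_gl"`.
#' @param loci optional [locus_map()] overriding positions parsed from
#'   marker names (BEAGLE dialect only).
#' @return a [gl_matrix()].
#' @export
read_genotype_likelihoods <- function(path,
                                      dialect = c("beagle_gl", "vcf_gl"),
                                      loci = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
         beagle_gl = read_beagle_gl(path, loci = loci),
         vcf_gl = read_vcf_gl(path))
}

#' @rdname read_genotype_likelihoods
#' @export
read_beagle_gl <- function(path, loci = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("BEAGLE file has no data rows: ", path)
  header <- strsplit(lines[1], "[ \t]+")[[1]]
  if (length(header) < 6L || (length(header) - 3L) %% 3L != 0L)
    stop("malformed BEAGLE header: expected marker, two alleles, ",
         "then three columns per individual")
  inds <- header[seq(4L, length(header), by = 3L)]
  n <- length(inds)
  nl <- length(lines) - 1L
  gl <- array(NA_real_, dim = c(nl, n, 3L))
  markers <- character(nl)
  for (r in seq_len(nl)) {
    f <- strsplit(lines[r + 1L], "[ \t]+")[[1]]
    if (length(f) != 3L + 3L * n)
      stop("malformed BEAGLE row at line ", r + 1L, ": expected ",
           3L + 3L * n, " fields, found ", length(f))
    v <- suppressWarnings(as.numeric(f[-(1:3)]))
    if (anyNA(v))
      stop("non-numeric genotype likelihood at line ", r + 1L)
    markers[r] <- f[1]
    gl[r, , ] <- matrix(v, ncol = 3L, byrow = TRUE)
  }
  if (is.null(loci)) {
    m <- regmatches(markers, regexec("^(.+)[:_]([0-9]+)$", markers))
    ok <- lengths(m) == 3L
    chrom <- ifelse(ok, vapply(m, function(z) z[2] %||% "un", ""), "un")
    pos <- ifelse(ok, as.integer(vapply(m, function(z) z[3] %||% "0", "")),
                  seq_len(nl))
    loci <- locus_map(markers, chrom, pos)
  }
  gl_matrix(gl, loci, inds)
}

#' Write a BEAGLE-style genotype-likelihood table
#'
#' Inverse of [read_beagle_gl()]; locus ids are written as
#' `chromosome_position` markers so a round trip reproduces the matrix.
#'
#' @param gl a [gl_matrix()].
#' @param path output file.
#' @export
write_beagle_gl <- function(gl, path) {
  n <- length(gl$individuals)
  header <- c("marker", "allele1", "allele2", rep(gl$individuals, each = 3L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  markers <- paste0(gl$loci$chromosome, "_", gl$loci$position)
  for (r in seq_len(nrow(gl$loci))) {
    row <- c(markers[r], "A", "T",
             format(as.vector(t(gl$gl[r, , ])), digits = 17))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname read_genotype_likelihoods
#' @export
read_vcf_gl <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  nskip <- sum(!biallelic)
  if (nskip > 0)
    message("skipped ", nskip, " non-biallelic VCF record(s)")
  if (!any(biallelic)) stop("no biallelic SNP records in ", path)
  fmt <- v@gt[biallelic, 1, drop = TRUE]
  has_gl <- all(grepl("(^|:)GL($|:)", fmt))
  has_pl <- all(grepl("(^|:)PL($|:)", fmt))
  if (!has_gl && !has_pl) stop("VCF records carry neither GL nor PL")
  tag <- if (has_gl) "GL" else "PL"
  gt <- vcfR::extract.gt(v, element = tag)[biallelic, , drop = FALSE]
  nl <- nrow(gt); n <- ncol(gt)
  gl <- array(1, dim = c(nl, n, 3L))  # missing entries stay flat
  for (j in seq_len(n)) {
    parts <- strsplit(gt[, j], ",", fixed = TRUE)
    ok <- lengths(parts) == 3L
    if (any(ok)) {
      vals <- matrix(suppressWarnings(as.numeric(unlist(parts[ok]))),
                     ncol = 3L, byrow = TRUE)
      vals[!is.finite(vals)] <- NA
      tri <- if (tag == "PL") 10^(-vals / 10) else 10^vals
      tri[is.na(tri)] <- 1
      gl[which(ok), j, ] <- tri
    }
  }
  fixb <- fix[biallelic, , drop = FALSE]
  ids <- fixb[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fixb[, "CHROM"], "_",
                                         fixb[, "POS"])[is.na(ids) | ids == "."]
  loci <- locus_map(ids, fixb[, "CHROM"], as.integer(fixb[, "POS"]))
  gl_matrix(gl, loci, colnames(gt))
}

#' Read a BED-like feature table
#'
#' Four or more whitespace-separated columns: chromosome, start, end (0-based
#' half-open) and feature class (e.g. gene, CDS, TE, protein_motif).  Records
#' are sorted by (chromosome, start); overlapping records are retained as-is.
#'
#' @param path file to read.
#' @return a `data.frame` of class `feature_table` with columns `chromosome`,
#'   `start`, `end`, `feature_class`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("feature table needs at least 4 columns")
  df <- df[, 1:4]
  names(df) <- c("chromosome", "start", "end", "feature_class")
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- which(!(df$start < df$end))
  if (length(bad))
    stop("feature with start >= end: ", df$chromosome[bad[1]], ":",
         df$start[bad[1]], "-", df$end[bad[1]])
  df <- df[order(df$chromosome, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Proximity of loci to annotated features
#'
#' A locus counts as "in or near" a feature class if its (0-based) position
#' lies within `[start - window, end + window)` for any feature of that
#' class on the same chromosome.  The default window of 1000 bp mirrors the
#' usual "within 1000 bp of an annotated feature" rule.
#'
#' @param loci a [locus_map()] (1-based positions).
#' @param features a [read_feature_table()] result.
#' @param window nonnegative flank, bp.
#' @return logical matrix, loci in rows, one column per feature class.
#' @export
near_feature <- function(loci, features, window = 1000) {
  stopifnot(window >= 0)
  classes <- sort(unique(features$feature_class))
  out <- matrix(FALSE, nrow(loci), length(classes),
                dimnames = list(loci$locus_id, classes))
  pos0 <- loci$position - 1L
  for (cl in classes) {
    fc <- features[features$feature_class == cl, , drop = FALSE]
    for (chr in unique(fc$chromosome)) {
      i <- which(loci$chromosome == chr)
      if (!length(i)) next
      f <- fc[fc$chromosome == chr, , drop = FALSE]
      lo <- f$start - window
      hi <- f$end + window
      out[i, cl] <- vapply(pos0[i],
                           function(p) any(lo <= p & p < hi), logical(1))
    }
  }
  out
}
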