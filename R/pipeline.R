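# End-to-end synthetic pipeline: simulate the full study design (parental
# reference populations, ancient hybrid populations, a contemporary hybrid
# zone and a five-lineage window panel), run every analysis stage, and
# write the result tables.

#' Simulate the full study design
#'
#' Three parental reference populations (two parent-0, one parent-1), two
#' ancient hybrid populations, one contemporary hybrid zone, all typed as
#' GBS-like genotype likelihoods at every simulated AIM, plus the
#' five-lineage topology-window panel.  Every locus is an AIM by
#' construction (parental difference >= 0.3).
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_study`: `truth`, `gl` (one [gl_matrix()]
#'   covering all populations), `pops` ([population_map()]), `ancient`
#'   (list of per-population truth), `zone` (zone truth), `windows_panel`
#'   ([simulate_topology_windows()] output), `coords` (synthetic
#'   population coordinates for the isolation-by-distance stage).
#' @export
simulate_study <- function(cfg = sim_config()) {
  truth <- simulate_parental_frequencies(cfg, min_diff = 0.3)
  nl <- nrow(truth$loci)
  pops_def <- data.frame(
    population = c("mel1", "mel2", "idas1", "anc1", "anc2", "zone"),
    role = c("parent0", "parent0", "parent1", "hybrid", "hybrid",
             "hybrid"),
    stringsAsFactors = FALSE)
  geno <- list()
  ancient <- list()
  zone <- NULL
  for (k in seq_len(nrow(pops_def))) {
    pop <- pops_def$population[k]
    geno[[pop]] <- switch(
      pop,
      mel1 = ,
      mel2 = simulate_parental_population(cfg, truth, parent = 0)$genotypes,
      idas1 = simulate_parental_population(cfg, truth, parent = 1)$genotypes,
      anc1 = ,
      anc2 = {
        a <- simulate_ancient_hybrid(cfg, truth)
        ancient[[pop]] <- a
        a$genotypes
      },
      zone = {
        zone <- simulate_contemporary_zone(cfg, truth)
        zone$genotypes
      })
  }
  all_geno <- do.call(cbind, geno)
  n_each <- vapply(geno, ncol, integer(1))
  ind_ids <- unlist(lapply(names(geno), function(p)
    paste0(p, "_", seq_len(ncol(geno[[p]])))))
  gl <- simulate_gbs_likelihoods(all_geno, truth$loci, ind_ids,
                                 depth = cfg$depth, error = cfg$error)
  pops <- population_map(ind_ids,
                         rep(pops_def$population, n_each),
                         role = rep(pops_def$role, n_each))
  windows_panel <- simulate_topology_windows(cfg)
  coords <- data.frame(
    population = pops_def$population,
    lat = c(41.3, 41.8, 44.1, 43.5, 43.9, 43.54),
    lon = c(-105.6, -106.2, -110.7, -110.3, -110.8, -109.63),
    taxon = c("melissa", "melissa", "idas", "jackson", "jackson",
              "jackson"),
    stringsAsFactors = FALSE)
  structure(list(truth = truth, gl = gl, pops = pops, ancient = ancient,
                 zone = zone, windows_panel = windows_panel,
                 coords = coords, cfg = cfg),
            class = "sim_study")
}

#' Run the full analysis pipeline on a simulated study
#'
#' Executes every stage on the output of [simulate_study()] and writes the
#' result tables as TSV (with `#` comment headers recording the seed) to
#' `out_dir`: allele frequencies, AIM designation, ancestry-frequency
#' tracks and fixation summaries for the ancient populations, hybrid
#' indexes and genomic clines for the zone, the consistency grid and
#' Z-chromosome category tests, polarized LD summaries, pairwise F_ST with
#' the isolation-by-distance fit, and the window-topology and f_d tables.
#'
#' MCMC problem sizes are reduced relative to the per-function defaults so
#' the whole pipeline stays desk-scale; pass `cline_cfg` / `ancestry_cfg`
#' to override.
#'
#' @param study a [simulate_study()] result.
#' @param out_dir output directory (created if needed).
#' @param cline_cfg a [cline_mcmc_config()].
#' @param ancestry_cfg an [ancestry_model_config()].
#' @param ld_max_loci cap on the number of AIMs entering the pairwise LD
#'   matrix.
#' @param quantiles quantile ladder for the consistency grid.
#' @param seed integer seed for the analysis stages.
#' @return (invisibly) a list with every stage's in-memory result.
#' @export
run_pipeline <- function(study, out_dir,
                         cline_cfg = cline_mcmc_config(chains = 2,
                                                       n_iter = 3000,
                                                       burnin = 1000,
                                                       thin = 5),
                         ancestry_cfg = ancestry_model_config(n_iter = 4000,
                                                              burnin = 1500,
                                                              thin = 5),
                         ld_max_loci = 400,
                         quantiles = seq(0.10, 0.01, by = -0.01),
                         seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  stamp <- c(paste0("seed=", seed), paste0("generated=", "clinemosaic"))
  emit <- function(df, name) write_result_tsv(df, file.path(out_dir, name),
                                              comments = stamp)
  gl <- study$gl
  pops <- study$pops

  ## 1. allele frequencies + AIMs
  freqs <- em_allele_frequencies(gl, pops)
  emit(freqs, "allele_frequencies.tsv")
  aims <- designate_aims(freqs,
                         parent0 = c("mel1", "mel2"), parent1 = "idas1")
  aim_tab <- data.frame(locus_id = names(aims$d), d = aims$d,
                        is_aim = names(aims$d) %in% aims$loci,
                        row.names = NULL)
  emit(aim_tab, "aims.tsv")
  p0 <- aims$p0[aims$loci]
  p1 <- aims$p1[aims$loci]

  ## 2. ancestry frequencies in the ancient hybrid populations
  tracks <- list()
  fixation <- list()
  for (pop in names(study$ancient)) {
    ids <- pops$individual_id[pops$population_id == pop]
    glh <- gl_subset(gl, locus_ids = aims$loci, individuals = ids)
    tr <- fit_ancestry_frequencies(glh, p0, p1, cfg = ancestry_cfg)
    tracks[[pop]] <- tr
    fx <- summarize_fixation(tr)
    fx <- cbind(population = pop, fx)
    fixation[[pop]] <- fx
    emit(tr, paste0("ancestry_", pop, ".tsv"))
  }
  emit(do.call(rbind, fixation), "fixation_summary.tsv")
  mean_track <- tracks[[1]]
  mean_track$q_hat <- rowMeans(sapply(tracks, `[[`, "q_hat"))

  ## 3. hybrid indexes + genomic clines in the zone
  zone_ids <- pops$individual_id[pops$population_id == "zone"]
  glz <- gl_subset(gl, locus_ids = aims$loci, individuals = zone_ids)
  hyb <- estimate_hybrid_index(glz, p0, p1)
  emit(hyb, "hybrid_index.tsv")
  clines <- fit_genomic_clines(glz, hyb, p0, p1, cfg = cline_cfg)
  emit(clines, "genomic_clines.tsv")

  ## 4. Z-chromosome category tests on the credible classes
  is_Z <- clines$is_Z
  names(is_Z) <- clines$locus_id
  cat_tests <- list()
  for (cls in c("restricted", "directional_parent1",
                "directional_parent0")) {
    members <- clines$locus_id[clines[[cls]]]
    if (length(members) == 0) next
    dir <- if (cls == "directional_parent0") "deficit" else "excess"
    r <- category_enrichment_test(members, is_Z, universe = clines$locus_id,
                                  n_perm = 1000, direction = dir)
    cat_tests[[cls]] <- data.frame(class = cls, n_set = length(members),
                                   observed_on_Z = r$observed,
                                   null_mean = r$null_mean,
                                   x_fold = r$x_fold,
                                   p_one_sided = r$p_one_sided,
                                   direction = dir)
  }
  emit(do.call(rbind, cat_tests), "z_enrichment.tsv")

  ## chromosome-size correlation of restricted introgression
  chr_sizes <- tapply(gl$loci$position, gl$loci$chromosome, max)
  prop_beta <- tapply(clines$restricted, clines$chromosome, mean)
  chr_common <- intersect(names(chr_sizes), names(prop_beta))
  size_cor <- tryCatch(
    proportion_size_correlation(prop_beta[chr_common],
                                chr_sizes[chr_common],
                                chromosome = chr_common),
    error = function(e) list(r = NA_real_, p_two_sided = NA_real_,
                             n = length(chr_common)))
  emit(data.frame(statistic = "prop_restricted_vs_chrom_size",
                  r = size_cor$r, p_two_sided = size_cor$p_two_sided,
                  n = size_cor$n),
       "chromosome_size_correlation.tsv")

  ## 5. consistency grid: zone clines vs ancient ancestry
  grid <- consistency_suite(clines, mean_track, quantiles = quantiles,
                            n_perm = 1000)
  emit(grid, "consistency_grid.tsv")

  ## 6. polarized LD (zone + one parental population)
  ld_loci <- aims$loci[seq_len(min(ld_max_loci, length(aims$loci)))]
  ld_rows <- list()
  for (pop in c("zone", "mel1")) {
    ids <- pops$individual_id[pops$population_id == pop]
    glp <- gl_subset(gl, locus_ids = ld_loci, individuals = ids)
    ld <- polarized_ld(glp, aims$p0[ld_loci], aims$p1[ld_loci])
    ld_rows[[pop]] <- data.frame(population = pop, n_ind = ld$n_ind,
                                 n_loci = length(ld_loci),
                                 mean_r = ld$mean_r)
  }
  emit(do.call(rbind, ld_rows), "ld_summary.tsv")

  ## 7. pairwise F_ST + isolation by distance
  pair_tbl <- ibd_pair_table(freqs, study$coords)
  emit(pair_tbl, "fst_pairs.tsv")
  ibd <- fit_ibd_model(pair_tbl, chains = 3, n_iter = 4000, burnin = 1000,
                       thin = 5)
  dic_tab <- data.frame(model = names(ibd$dic), dic = as.numeric(ibd$dic))
  emit(cbind(model = "full", ibd$full$coef), "ibd_coefficients.tsv")
  emit(dic_tab, "ibd_dic.tsv")

  ## 8. phylogenomic windows + f_d
  wp <- study$windows_panel
  topo <- infer_topologies(wp$windows, wp$x)
  emit(topo, "window_topologies.tsv")
  topo_tests <- list()
  for (k in seq_along(wp$topology_ids)) {
    tid <- wp$topology_ids[k]
    for (dir in c("excess", "deficit")) {
      r <- tryCatch(
        topology_class_test(topo, tid, topo$is_Z, n_perm = 1000,
                            direction = dir),
        error = function(e) NULL)
      if (is.null(r)) next
      topo_tests[[paste(k, dir)]] <-
        data.frame(topology = names(wp$topology_ids)[k],
                   topology_id = tid, class = "Z_windows",
                   direction = dir, observed = r$observed,
                   null_mean = r$null_mean, x_fold = r$x_fold,
                   p_one_sided = r$p_one_sided)
    }
  }
  emit(do.call(rbind, topo_tests), "topology_class_tests.tsv")

  taxa <- rownames(wp$x)
  roles <- c(P1 = taxa[5], P2 = taxa[4], P3 = taxa[2], O = taxa[1])
  fd_lg <- fd_by_group(wp$x, roles, wp$loci$chromosome)
  emit(fd_lg, "fd_by_chromosome.tsv")
  fd_win <- fd_by_group(wp$x, roles,
                        rep(topo$window_id, each = study$cfg$window_snps))
  cand <- sample.int(nrow(topo), min(49L, nrow(topo)))
  fd_test <- fd_window_set_test(fd_win$fd, cand, n_draws = 1000)
  emit(data.frame(statistic = "candidate_window_fd",
                  n_windows = length(cand), observed_mean = fd_test$observed,
                  null_mean = fd_test$null_mean,
                  p_lower = fd_test$p_one_sided),
       "fd_candidate_windows.tsv")
  fd_size_cor <- tryCatch({
    sz <- tapply(wp$loci$position, wp$loci$chromosome, max)
    ok <- !is.na(fd_lg$fd)
    r <- topology_size_correlation(fd_lg$fd[ok],
                                   sz[as.character(fd_lg$group[ok])])
    data.frame(statistic = "fd_vs_chrom_size", r = r$r,
               p_two_sided = r$p_two_sided, n = r$n)
  }, error = function(e)
    data.frame(statistic = "fd_vs_chrom_size", r = NA_real_,
               p_two_sided = NA_real_, n = NA_integer_))
  emit(fd_size_cor, "fd_size_correlation.tsv")

  invisible(list(freqs = freqs, aims = aims, tracks = tracks,
                 fixation = do.call(rbind, fixation), hybrid_index = hyb,
                 clines = clines, consistency = grid,
                 z_enrichment = do.call(rbind, cat_tests),
                 ld = do.call(rbind, ld_rows), ibd = ibd,
                 topologies = topo, fd = fd_lg))
}
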