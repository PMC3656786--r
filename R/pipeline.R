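#' Pipeline configuration
#'
#' Bundles inputs and the conventional analysis constants for
#' [run_pipeline()]: neutrality pre-filter before everything else, MAF 0.05
#' and LD-thinning r2 0.4 ahead of the structure stage, Q-threshold 0.70,
#' LD significance 0.05 and decay block threshold r2 = 0.1.
#'
#' @param genotypes A [geno_matrix()], or a file path.
#' @param format File format when `genotypes` is a path.
#' @param map Optional linkage map tibble or TSV path.
#' @param grouping Optional named vector individual -> population (defaults
#'   to the matrix labels).
#' @param scan_groups Optional [group_pair()] for the selection scan and
#'   bottleneck stages.
#' @param out_dir Report directory (created if needed).
#' @param seed Base seed; each stochastic stage derives its own from it.
#' @param ew_prefilter Drop loci failing the Ewens-Watterson neutrality
#'   screen before the diversity/phylogeny/structure stages.
#' @param ew_alpha,ew_dh EW significance threshold and Dh/sd cutoff.
#' @param maf_min,ld_r2max Structure-stage thinning constants.
#' @param k_range,k_reps,burn_in,iters Admixture-sampler settings.
#' @param q_threshold Membership assignment cutoff.
#' @param ld_alpha,ld_block_r2 LD summary and decay constants.
#' @param n_boot NJ bootstrap replicates (0 skips supports).
#' @param scan_n_sim,bottleneck_n_sim Simulation sizes.
#' @param k_within Hierarchical-scan sub-group count.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, format = "csv", map = NULL,
                            grouping = NULL, scan_groups = NULL,
                            out_dir = "ssrpopkit_report", seed = 1,
                            ew_prefilter = TRUE, ew_alpha = 0.05,
                            ew_dh = -2.5, maf_min = 0.05, ld_r2max = 0.4,
                            k_range = 1:4, k_reps = 2, burn_in = 500,
                            iters = 1000, q_threshold = 0.70,
                            ld_alpha = 0.05, ld_block_r2 = 0.1, n_boot = 100,
                            scan_n_sim = 2000, bottleneck_n_sim = 500,
                            k_within = 2) {
  stopifnot(maf_min >= 0, maf_min <= 1, ld_r2max >= 0, ld_r2max <= 1,
            q_threshold >= 0, q_threshold <= 1, ld_block_r2 > 0,
            ld_alpha > 0, ld_alpha < 1)
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes, format)
  if (is.character(map)) map <- read_linkage_map(map)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' All scalar fields of [pipeline_config()] can be given in a YAML file;
#' `genotypes` and `map` are file paths.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$k_range)) vals$k_range <- eval(parse(text = vals$k_range))
  if (!is.null(vals$scan_groups)) {
    vals$scan_groups <- group_pair(vals$scan_groups$a, vals$scan_groups$b)
  }
  do.call(pipeline_config, vals)
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  res
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the conventional order -- Ewens-Watterson
#' neutrality pre-filter, diversity table, Nei-distance NJ tree and PCoA,
#' admixture structure scan with delta-K and Q-threshold assignment,
#' molecular coancestry, linkage disequilibrium with decay fit, the
#' four-test divergent-selection scan and the bottleneck tests -- writing
#' every intermediate table plus a machine-readable provenance log (seeds,
#' parameters, locus counts after each filter) to `out_dir`. Reruns with an
#' identical configuration produce identical output files.
#'
#' @param cfg A [pipeline_config()].
#' @return The provenance log, invisibly; files under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- cfg$genotypes
  grouping <- .pop_of(gm, cfg$grouping)
  log <- list(seed = cfg$seed,
              package_version = as.character(utils::packageVersion("ssrpopkit")),
              n_individuals = nrow(gm$a1),
              locus_counts = list(input = ncol(gm$a1)),
              parameters = cfg[!(names(cfg) %in% c("genotypes", "map",
                                                   "grouping", "scan_groups",
                                                   "out_dir"))])
  tsv <- function(x, name) {
    utils::write.table(x, file.path(cfg$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # 1. neutrality pre-filter
  neutral_loci <- loci(gm)
  if (cfg$ew_prefilter) {
    ew <- .stage("ew_prefilter", log, {
      pooled <- allele_frequencies(gm, setNames(rep("all", nrow(gm$a1)),
                                                individuals(gm)))
      cache <- new.env(parent = emptyenv())
      set.seed(cfg$seed)
      purrr::map_dfr(loci(gm), function(l) {
        res <- ew_test(pooled$count[pooled$locus == l & pooled$defined],
                       n_sim = 1000, cache = cache)
        res$locus <- l
        res
      })
    })
    flagged <- ew$locus[!is.na(ew$dh_sd) & ew$dh_sd < cfg$ew_dh &
                          ew$p < cfg$ew_alpha]
    neutral_loci <- setdiff(loci(gm), flagged)
    tsv(ew, "ew_prefilter.tsv")
  }
  gm_neutral <- gm[, neutral_loci]
  log$locus_counts$neutral <- length(neutral_loci)

  # 2. diversity
  div <- .stage("diversity", log, diversity_table(gm_neutral, grouping))
  tsv(div, "diversity.tsv")

  # 3. phylogeny + PCoA
  dm <- .stage("distance", log, nei_minimum_distance(gm_neutral))
  tree <- .stage("phylogeny", log, {
    if (cfg$n_boot > 0) bootstrap_support(gm_neutral, n_reps = cfg$n_boot,
                                          seed = cfg$seed + 1L)
    else neighbor_joining(dm)
  })
  ape::write.tree(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  pc <- .stage("pcoa", log, pcoa(dm))
  tsv(pc$coords, "pcoa_coords.tsv")
  tsv(pc$eig, "pcoa_eig.tsv")

  # 4. structure on the LD- and MAF-thinned neutral set
  thinned <- if (!is.null(cfg$map)) {
    .stage("ld_thinning", log,
           thin_by_ld(gm_neutral, cfg$map, r2_max = cfg$ld_r2max,
                      maf_min = cfg$maf_min))
  } else neutral_loci
  log$locus_counts$structure_set <- length(thinned)
  scan <- .stage("structure", log,
                 structure_scan(gm_neutral[, thinned], k_range = cfg$k_range,
                                n_reps = cfg$k_reps, burn_in = cfg$burn_in,
                                iters = cfg$iters, seed = cfg$seed + 2L))
  tsv(scan$runs, "structure_lnpd.tsv")
  ev <- .stage("evanno", log, evanno_delta_k(scan))
  tsv(ev, "evanno_delta_k.tsv")
  best_k <- if (all(is.na(ev$delta_k))) {
    ev$K[which.max(ev$mean_ln_pd)]  # degenerate delta-K: fall back to lnP(D)
  } else {
    ev$K[which.max(ev$delta_k)]
  }
  qm <- scan$q[[paste0("K", best_k)]]
  assign <- assign_groups(qm, threshold = cfg$q_threshold)
  tsv(assign, "group_assignment.tsv")
  log$best_k <- best_k
  fst <- .stage("pairwise_fst", log,
                pairwise_fst(gm_neutral, grouping, n_perm = 99,
                             seed = cfg$seed + 3L))
  tsv(fst, "pairwise_fst.tsv")

  # 5. coancestry on all input loci (not pre-filtered)
  cm <- .stage("coancestry", log, coancestry_matrix(gm))
  tsv(tidy(cm), "coancestry_pairs.tsv")
  tsv(cm$histogram, "coancestry_histogram.tsv")
  tsv(group_coancestry_summary(cm, grouping), "coancestry_groups.tsv")

  # 6. linkage disequilibrium
  if (!is.null(cfg$map)) {
    ldt <- .stage("ld", log, ld_table(gm_neutral, cfg$map,
                                      maf_min = cfg$maf_min))
    tsv(ldt, "ld_pairs.tsv")
    lds <- .stage("ld_summary", log, ld_summary(ldt, alpha = cfg$ld_alpha))
    tsv(lds, "ld_summary.tsv")
    fitres <- tryCatch(
      fit_decay(ldt, n_individuals = nrow(gm$a1),
                threshold = cfg$ld_block_r2),
      error = function(e) NULL)
    if (!is.null(fitres)) {
      tsv(glance(fitres), "ld_decay.tsv")
      log$ld_block_cm <- fitres$distance_at_threshold
    }
  }

  # 7. selection scan + 8. bottleneck, when a contrast is configured
  if (!is.null(cfg$scan_groups)) {
    rep_scan <- .stage("selection_scan", log,
                       scan_outliers(gm, cfg$scan_groups, map = cfg$map,
                                     k_within = cfg$k_within,
                                     n_sim_fdist = cfg$scan_n_sim,
                                     seed = cfg$seed + 4L))
    tsv(rep_scan, "outlier_scan.tsv")
    log$n_consensus_outliers <- sum(rep_scan$outlier)
    for (side in c("a", "b")) {
      bt <- .stage(paste0("bottleneck_", side), log,
                   bottleneck_test(gm, cfg$scan_groups[[side]],
                                   n_sim = cfg$bottleneck_n_sim,
                                   seed = cfg$seed + 5L))
      tsv(glance(bt), sprintf("bottleneck_%s.tsv", side))
    }
  }

  jsonlite::write_json(log, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(log)
}
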