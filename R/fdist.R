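# Simulate a batch of neutral loci under the (possibly hierarchical)
# finite island model via the structured coalescent, returning per-locus
# pooled unbiased gene diversity and Weir-Cockerham theta for two sampled
# demes. Gene copies are paired into diploids within each deme so that the
# same theta estimator as for observed data applies.
.sim_neutral_batch <- function(n_loci, n_demes, deme_group, mig_within,
                               mig_between, n_a, n_b, sample_demes,
                               theta_range = c(0.05, 10), p_smm = 1,
                               geom_p = 0.5, state_cap = 30L) {
  thetas <- exp(stats::runif(n_loci, log(theta_range[1]), log(theta_range[2])))
  states <- .coalescent_island_cpp(
    sample_sizes = c(2L * n_a, 2L * n_b),
    sample_demes = as.integer(sample_demes),
    n_demes = as.integer(n_demes),
    deme_group = as.integer(deme_group),
    mig_within = mig_within, mig_between = mig_between,
    theta = thetas, p_smm = p_smm, geom_p = geom_p
  )
  # k-allele cap: wrap the stepwise ladder onto `state_cap` states
  states <- ((states %% state_cap) + state_cap) %% state_cap
  grp <- rep(c("A", "B"), c(n_a, n_b))
  i1 <- seq(1, 2 * (n_a + n_b), by = 2)  # copies 1,3,5,... = slot 1
  out <- matrix(NA_real_, n_loci, 2, dimnames = list(NULL, c("he", "theta")))
  for (l in seq_len(n_loci)) {
    g1 <- states[i1, l]
    g2 <- states[i1 + 1L, l]
    n_copies <- 2 * length(g1)
    p <- tabulate(c(g1, g2) + 1L, state_cap) / n_copies
    he <- n_copies / (n_copies - 1) * (1 - sum(p^2))
    codes <- sort(unique(c(g1, g2)))
    ld <- list(ok = seq_along(g1), c1 = match(g1, codes), c2 = match(g2, codes),
               het = g1 != g2, n_alleles = length(codes))
    comp <- .wc_locus(ld, grp)
    out[l, "he"] <- min(he, 1)
    out[l, "theta"] <- if (sum(comp) == 0) NA_real_ else comp["a"] / sum(comp)
  }
  tibble::tibble(he = out[, "he"], theta = out[, "theta"])
}

# Tune the migration scale so that the simulated mean theta matches the
# observed (trimmed-mean) target; multiplicative update on (1-F)/F.
.tune_migration <- function(target, n_demes, deme_group, mig_ratio,
                            n_a, n_b, sample_demes, n_tune = 400L,
                            max_iter = 20L, tol = 0.01, ...) {
  alpha_d <- (n_demes / (n_demes - 1))^2
  M <- (1 / target - 1) / alpha_d  # island-model starting point
  achieved <- NA_real_
  for (it in seq_len(max_iter)) {
    b <- .sim_neutral_batch(n_tune, n_demes, deme_group,
                            mig_within = M, mig_between = M / mig_ratio,
                            n_a = n_a, n_b = n_b, sample_demes = sample_demes,
                            ...)
    achieved <- mean(b$theta, na.rm = TRUE)
    if (is.finite(achieved) && abs(achieved - target) <= tol) {
      return(list(M = M, achieved = achieved, iter = it))
    }
    achieved <- max(min(achieved, 0.99), 1e-4)
    M <- M * ((1 / target - 1) / (1 / achieved - 1))
  }
  stop(sprintf(paste0("FST recentering did not converge: target %.3f, ",
                      "achieved %.3f after %d iterations"),
               target, achieved, max_iter), call. = FALSE)
}

# observed per-locus pooled unbiased He and pairwise theta for a group pair
.obs_he_theta <- function(gm, pair) {
  ind <- c(pair$a, pair$b)
  grouping <- setNames(rep(c("A", "B"), c(length(pair$a), length(pair$b))), ind)
  sub <- gm[ind, ]
  est <- wc_fst(sub, grouping)
  pooled <- allele_frequencies(sub, setNames(rep("all", length(ind)), ind))
  he <- pooled |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(he = unbiased_gene_diversity(.data$freq, .data$n_genes[1]),
                     .groups = "drop")
  dplyr::left_join(est$per_locus, he, by = "locus")
}

# empirical conditional quantile of each observed theta within
# heterozygosity-matched bins of the simulated null
.conditional_quantile <- function(obs, sim, min_bin = 50L) {
  sim <- dplyr::filter(sim, !is.na(.data$theta))
  n_bins <- max(1L, min(30L, floor(nrow(sim) / max(min_bin, 50L))))
  edges <- stats::quantile(sim$he, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 7)
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  edges <- unique(edges)  # ties in simulated He collapse bins
  sim$bin <- cut(sim$he, edges, labels = FALSE, include.lowest = TRUE)
  vapply(seq_len(nrow(obs)), function(i) {
    if (is.na(obs$theta[i]) || is.na(obs$he[i])) return(NA_real_)
    b <- cut(obs$he[i], edges, labels = FALSE, include.lowest = TRUE)
    th <- sim$theta[sim$bin == b]
    if (length(th) < 10) th <- sim$theta
    (sum(th < obs$theta[i]) + 0.5 * sum(th == obs$theta[i])) / length(th)
  }, numeric(1))
}

#' Validate a two-group contrast
#'
#' @param a,b Character vectors of individual ids for the two groups
#'   (disjoint, each with at least 2 individuals).
#' @return A `group_pair` list.
#' @export
group_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(intersect(a, b))) stop("groups must be disjoint", call. = FALSE)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 individuals", call. = FALSE)
  structure(list(a = a, b = b), class = "group_pair")
}

#' FDIST-style FST outlier scan
#'
#' Simulates the neutral joint distribution of heterozygosity and FST for
#' two demes sampled from a `demes`-island coalescent with stepwise
#' mutation (allele ladder wrapped onto 30 states), with the migration rate
#' recentred iteratively until the simulated mean Weir-Cockerham theta
#' matches the observed trimmed-mean theta (tolerance 0.01, at most 20
#' rounds). Each observed locus is placed at its empirical quantile of the
#' simulated theta distribution conditional on heterozygosity (bins of at
#' least 50 simulated loci); loci above the 0.95 conditional quantile are
#' flagged as divergent-selection candidates.
#'
#' @param gm A [geno_matrix()].
#' @param pair A [group_pair()].
#' @param n_sim Simulated neutral loci for the null distribution.
#' @param demes Number of demes in the island model (2 are sampled).
#' @param seed Optional RNG seed.
#' @param trim Fraction of extreme per-locus theta values dropped from each
#'   tail when computing the target mean FST.
#' @param quantile_flag Conditional-quantile cutoff for flagging (0.95).
#' @return Tibble `locus`, `he`, `fst`, `quantile`, `flagged`; attributes
#'   `target_fst`, `achieved_fst`, `migration`.
#' @export
fdist_scan <- function(gm, pair, n_sim = 20000, demes = 100, seed = NULL,
                       trim = 0.05, quantile_flag = 0.95) {
  stopifnot(inherits(pair, "group_pair"))
  if (ncol(gm$a1) < 20) stop("need >= 20 loci to estimate the target mean FST", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- .obs_he_theta(gm, pair)
  target <- mean(obs$theta, trim = trim, na.rm = TRUE)
  target <- max(min(target, 0.95), 0.002)
  tune <- .tune_migration(target, n_demes = demes, deme_group = rep(1L, demes),
                          mig_ratio = Inf,
                          n_a = length(pair$a), n_b = length(pair$b),
                          sample_demes = c(1L, 2L))
  sim <- .sim_neutral_batch(n_sim, demes, rep(1L, demes),
                            mig_within = tune$M, mig_between = 0,
                            n_a = length(pair$a), n_b = length(pair$b),
                            sample_demes = c(1L, 2L))
  q <- .conditional_quantile(obs, sim)
  out <- tibble::tibble(locus = obs$locus, he = obs$he, fst = obs$theta,
                        quantile = q,
                        flagged = !is.na(q) & q > quantile_flag)
  attr(out, "target_fst") <- target
  attr(out, "achieved_fst") <- tune$achieved
  attr(out, "migration") <- tune$M
  out
}

#' Hierarchical island-model outlier scan
#'
#' Same machinery as [fdist_scan()] but with the demes arranged in two
#' groups of `k_within` demes exchanging `ratio` times more migrants within
#' groups than between; the two sampled demes come from different groups.
#' This null accounts for hierarchical structure that inflates plain
#' island-model FST outliers.
#'
#' @inheritParams fdist_scan
#' @param k_within Demes per group (the sub-group count found by the
#'   structure analysis of each side).
#' @param ratio Within:between migration ratio (default 10).
#' @export
hierarchical_scan <- function(gm, pair, k_within = 2, ratio = 10,
                              n_sim = 20000, seed = NULL, trim = 0.05,
                              quantile_flag = 0.95) {
  stopifnot(inherits(pair, "group_pair"))
  if (ncol(gm$a1) < 20) stop("need >= 20 loci to estimate the target mean FST", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_demes <- 2L * k_within
  deme_group <- rep(1:2, each = k_within)
  obs <- .obs_he_theta(gm, pair)
  target <- mean(obs$theta, trim = trim, na.rm = TRUE)
  target <- max(min(target, 0.95), 0.002)
  tune <- .tune_migration(target, n_demes = n_demes, deme_group = deme_group,
                          mig_ratio = ratio,
                          n_a = length(pair$a), n_b = length(pair$b),
                          sample_demes = c(1L, k_within + 1L))
  sim <- .sim_neutral_batch(n_sim, n_demes, deme_group,
                            mig_within = tune$M, mig_between = tune$M / ratio,
                            n_a = length(pair$a), n_b = length(pair$b),
                            sample_demes = c(1L, k_within + 1L))
  q <- .conditional_quantile(obs, sim)
  out <- tibble::tibble(locus = obs$locus, he = obs$he, fst = obs$theta,
                        quantile = q,
                        flagged = !is.na(q) & q > quantile_flag)
  attr(out, "target_fst") <- target
  attr(out, "achieved_fst") <- tune$achieved
  attr(out, "migration") <- tune$M
  out
}
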