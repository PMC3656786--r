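#' Select a random subset capturing the average allele count
#'
#' Draws `n_candidate_sets` random subsets of the requested size from a
#' pool of individuals, computes each subset's total distinct-allele count,
#' and returns the subset whose count is closest to the candidates' mean
#' (ties resolved by draw order). This balances an arbitrary contrast group
#' against a reference group without cherry-picking diversity.
#'
#' @param gm A [geno_matrix()].
#' @param pool Character vector of candidate individual ids.
#' @param size Subset size (`<= length(pool)`).
#' @param n_candidate_sets Number of random candidate subsets.
#' @param seed Optional RNG seed.
#' @return Character vector of selected ids, with attributes
#'   `candidate_counts`, `target_mean`, `chosen_index` and `candidates`.
#' @export
select_balanced_subset <- function(gm, pool, size, n_candidate_sets = 100,
                                   seed = NULL) {
  if (size > length(pool)) stop("size exceeds the pool", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  count_alleles <- function(ind) {
    sub <- gm[ind, ]
    sum(vapply(seq_len(ncol(sub$a1)), function(j) {
      length(unique(stats::na.omit(c(sub$a1[, j], sub$a2[, j]))))
    }, integer(1)))
  }
  if (size == length(pool)) {
    out <- pool
    attr(out, "candidate_counts") <- count_alleles(pool)
    attr(out, "target_mean") <- count_alleles(pool)
    attr(out, "chosen_index") <- 1L
    return(out)
  }
  candidates <- lapply(seq_len(n_candidate_sets),
                       function(i) sort(sample(pool, size)))
  counts <- vapply(candidates, count_alleles, numeric(1))
  target <- mean(counts)
  chosen <- which.min(abs(counts - target))
  out <- candidates[[chosen]]
  attr(out, "candidate_counts") <- counts
  attr(out, "target_mean") <- target
  attr(out, "chosen_index") <- chosen
  attr(out, "candidates") <- candidates
  out
}

# shared cache-aware Ewens null simulation: F values conditional on (n, k)
.ewens_null <- function(n, k, n_sim, cache = NULL) {
  key <- paste0(n, ":", k)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  # theta such that the expected allele count under the Ewens formula is k
  ek <- function(theta) sum(theta / (theta + 0:(n - 1)))
  theta <- if (k >= n) {
    1e5
  } else if (k <= 1) {
    1e-4
  } else {
    stats::uniroot(function(t) ek(t) - k, c(1e-4, 1e5), tol = 1e-8)$root
  }
  Fnull <- .ewens_urn_F_cpp(as.integer(n), as.integer(k), theta,
                            as.integer(n_sim), 1e7)
  if (!is.null(cache)) cache[[key]] <- Fnull
  Fnull
}

#' Ewens-Watterson neutrality test
#'
#' Compares the observed homozygosity `F = sum(p^2)` of an allele
#' configuration with its neutral sampling distribution conditional on the
#' sample size and allele count, simulated from the Ewens urn (rejection on
#' the observed allele number, urn parameter tuned so that the expected
#' allele count matches). Reports the two-tailed rank p-value and the
#' standardised gene-diversity deviation `Dh/sd = (H_obs - mean H_null) /
#' sd(H_null)`; a locus is flagged when `Dh/sd < -2.5` and `p < 0.05`
#' (diversity deficit, the sweep signature).
#'
#' @param counts Integer vector of allele copy counts at one locus (one
#'   population or pooled group).
#' @param n_sim Null-simulation size.
#' @param seed Optional RNG seed.
#' @param cache Optional environment for memoising null distributions
#'   across loci sharing (n, k).
#' @return One-row tibble `f_obs`, `dh_sd`, `p`, `significant`,
#'   `applicable` (monomorphic or tiny samples are inapplicable and
#'   neutral-by-default).
#' @export
ew_test <- function(counts, n_sim = 1000, seed = NULL, cache = NULL) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  k <- length(counts)
  f_obs <- sum((counts / n)^2)
  if (k < 2 || n < 5) {
    return(tibble::tibble(f_obs = f_obs, dh_sd = NA_real_, p = NA_real_,
                          significant = FALSE, applicable = FALSE))
  }
  if (!is.null(seed)) set.seed(seed)
  Fnull <- .ewens_null(n, k, n_sim, cache)
  eps <- 1e-12
  p_low <- (sum(Fnull <= f_obs + eps) + 1) / (n_sim + 1)
  p_high <- (sum(Fnull >= f_obs - eps) + 1) / (n_sim + 1)
  p <- min(1, 2 * min(p_low, p_high))
  Hnull <- 1 - Fnull
  s <- stats::sd(Hnull)
  dh_sd <- if (s > 0) ((1 - f_obs) - mean(Hnull)) / s else NA_real_
  tibble::tibble(f_obs = f_obs, dh_sd = dh_sd, p = p,
                 significant = !is.na(dh_sd) && dh_sd < -2.5 && p < 0.05,
                 applicable = TRUE)
}

#' ln RH test of locus-specific variability differences
#'
#' Schloetterer's variability ratio between two groups,
#' `RH = [(1/(1 - He_A))^2 - 1] / [(1/(1 - He_B))^2 - 1]`, log-transformed
#' and standardised across loci; under neutrality about 95% of loci fall
#' in `[-1.96, 1.96]`, so larger |z| marks candidate loci.
#'
#' @param he_a,he_b Per-locus gene diversities of the two groups (same
#'   order and length, `0 <= He < 1`).
#' @param loci Optional locus names.
#' @param mode `"two_sided"` (default) flags `|z| > 1.96`; `"one_sided"`
#'   flags `z > 1.96` only.
#' @param n_a,n_b Optional gene-copy sample sizes. When given, loci
#'   monomorphic in one group are assigned the heterozygosity of a single
#'   allele difference in the sample (the usual monomorphic correction, so
#'   that complete sweeps remain testable); without them such loci are
#'   excluded.
#' @return Tibble `locus`, `he_a`, `he_b`, `ln_rh`, `z`, `flagged`,
#'   `usable`; loci where either theta estimate is 0 or He = 1 are
#'   excluded (`usable = FALSE`, warned).
#' @export
lnrh_test <- function(he_a, he_b, loci = NULL, mode = c("two_sided", "one_sided"),
                      n_a = NULL, n_b = NULL) {
  mode <- match.arg(mode)
  if (length(he_a) != length(he_b)) stop("he_a and he_b must align", call. = FALSE)
  loci <- loci %||% paste0("locus_", seq_along(he_a))
  if (!is.null(n_a)) {
    he_a[!is.na(he_a) & he_a == 0] <- 2 * (n_a - 1) / n_a^2
  }
  if (!is.null(n_b)) {
    he_b[!is.na(he_b) & he_b == 0] <- 2 * (n_b - 1) / n_b^2
  }
  th <- function(he) (1 / (1 - he))^2 - 1
  ta <- th(he_a); tb <- th(he_b)
  usable <- is.finite(ta) & is.finite(tb) & ta > 0 & tb > 0 &
    he_a < 1 & he_b < 1 & !is.na(he_a) & !is.na(he_b)
  if (sum(usable) < 10) {
    stop("ln RH needs at least 10 loci variable in both groups", call. = FALSE)
  }
  if (any(!usable)) {
    warning(sum(!usable), " loci excluded from ln RH (monomorphic or He = 1)")
  }
  ln_rh <- rep(NA_real_, length(he_a))
  ln_rh[usable] <- log(ta[usable] / tb[usable])
  mu <- mean(ln_rh[usable])
  s <- stats::sd(ln_rh[usable])
  z <- rep(NA_real_, length(he_a))
  flagged <- rep(FALSE, length(he_a))
  if (is.na(s) || s == 0) {
    warning("ln RH values have zero spread; z-scores undefined")
  } else {
    z[usable] <- (ln_rh[usable] - mu) / s
    flagged[usable] <- if (mode == "two_sided") abs(z[usable]) > 1.96
                       else z[usable] > 1.96
  }
  tibble::tibble(locus = loci, he_a = he_a, he_b = he_b,
                 ln_rh = ln_rh, z = z, flagged = flagged, usable = usable)
}

#' Consensus outlier call
#'
#' A locus is a consensus outlier when at least two of the four neutrality
#' tests flag it (inapplicable tests count as not significant).
#'
#' @param flags A logical matrix/data frame of per-test flags (loci x
#'   tests), or a tibble containing the columns named in `tests`.
#' @param tests Column names holding the per-test flags.
#' @param min_tests Minimum number of significant tests (default 2).
#' @return Logical vector of consensus calls.
#' @export
consensus_outliers <- function(flags,
                               tests = c("ew_sig", "lnrh_sig", "fdist_sig",
                                         "hier_sig"),
                               min_tests = 2L) {
  if (is.data.frame(flags)) flags <- as.matrix(flags[, tests, drop = FALSE])
  flags[is.na(flags)] <- FALSE
  rowSums(flags) >= min_tests
}

#' Four-test divergent-selection scan
#'
#' Runs, per locus, the Ewens-Watterson test (on the pooled pair), the
#' ln RH test, the FDIST island-model scan and the hierarchical
#' island-model scan between two predefined groups, and calls consensus
#' outliers (significant in at least two tests). Pairwise Weir-Cockerham
#' theta per locus is reported alongside; with a linkage map the linkage
#' group of each locus is annotated.
#'
#' @param gm A [geno_matrix()].
#' @param pair A [group_pair()].
#' @param map Optional linkage map tibble.
#' @param k_within Sub-group count per side for the hierarchical null.
#' @param n_sim_fdist Simulated loci per coalescent null.
#' @param n_sim_ew Ewens null simulations per (n, k) configuration.
#' @param seed RNG seed governing every stochastic stage.
#' @param lnrh_mode Passed to [lnrh_test()].
#' @return An `outlier_report` tibble: per-locus test statistics, per-test
#'   flags, `n_sig`, `outlier` (consensus), `fst`, and `linkage_group` when
#'   mapped.
#' @export
scan_outliers <- function(gm, pair, map = NULL, k_within = 2,
                          n_sim_fdist = 5000, n_sim_ew = 1000, seed = 1,
                          lnrh_mode = "two_sided") {
  stopifnot(inherits(pair, "group_pair"))
  ind <- c(pair$a, pair$b)
  grouping <- setNames(rep(c("A", "B"), c(length(pair$a), length(pair$b))), ind)
  sub <- gm[ind, ]

  # per-group gene diversities for ln RH
  freqs <- allele_frequencies(sub, grouping)
  he_by <- freqs |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(he = gene_diversity(.data$freq), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "population", values_from = "he")
  he_by <- he_by[match(loci(sub), he_by$locus), ]

  set.seed(seed)
  # Ewens-Watterson on the pooled groups, memoised across loci
  pooled <- allele_frequencies(sub, setNames(rep("all", length(ind)), ind))
  cache <- new.env(parent = emptyenv())
  ew <- purrr::map_dfr(loci(sub), function(l) {
    cts <- pooled$count[pooled$locus == l & pooled$defined]
    ew_test(cts, n_sim = n_sim_ew, cache = cache)
  })

  lnrh <- lnrh_test(he_by$A, he_by$B, loci = he_by$locus, mode = lnrh_mode,
                    n_a = 2L * length(pair$a), n_b = 2L * length(pair$b))
  fd <- fdist_scan(sub, pair, n_sim = n_sim_fdist, seed = seed + 1L)
  hi <- hierarchical_scan(sub, pair, k_within = k_within,
                          n_sim = n_sim_fdist, seed = seed + 2L)

  out <- tibble::tibble(
    locus = loci(sub),
    he_a = he_by$A, he_b = he_by$B,
    ew_f = ew$f_obs, ew_dh_sd = ew$dh_sd, ew_p = ew$p,
    ew_sig = ew$significant,
    lnrh_z = lnrh$z, lnrh_sig = lnrh$flagged,
    fdist_q = fd$quantile, fdist_sig = fd$flagged,
    hier_q = hi$quantile, hier_sig = hi$flagged,
    fst = fd$fst
  )
  out$n_sig <- rowSums(cbind(out$ew_sig, out$lnrh_sig, out$fdist_sig,
                             out$hier_sig), na.rm = TRUE)
  out$outlier <- consensus_outliers(out)
  if (!is.null(map)) {
    out <- dplyr::left_join(out,
                            dplyr::select(map, locus = "marker",
                                          "linkage_group"),
                            by = "locus")
  }
  class(out) <- c("outlier_report", class(out))
  out
}

#' Candidate-gene window arithmetic around an outlier locus
#'
#' Converts the local physical-to-genetic distance ratio into a search
#' window: when the outlier and its neighbour sit on the same sequence
#' scaffold and are in strong LD (`r2 > 0.4`), the window is
#' `ratio x genetic span`; with moderate LD (`0.2 <= r2 <= 0.4`) the span
#' is replaced by the distance at which LD in the contrasted groups decays
#' to 0.4 (`decay_cm`, from [fit_decay()]); with different scaffolds or
#' weak LD (`r2 < 0.2`) a fixed 10 kb on each side of the outlier is used.
#'
#' @param outlier,neighbor Marker names.
#' @param r2 LD between the two markers.
#' @param map Linkage map tibble (both markers must be mapped).
#' @param scaffolds Scaffold coordinate tibble (`marker`, `scaffold`, `bp`).
#' @param decay_cm Genetic distance (cM) at which group LD decays to 0.4;
#'   required only in the moderate-LD branch.
#' @return One-row tibble `outlier`, `neighbor`, `method`, `ratio_kb_per_cm`,
#'   `span_cm`, `window_kb`.
#' @export
candidate_window <- function(outlier, neighbor, r2, map, scaffolds,
                             decay_cm = NULL) {
  get_row <- function(tbl, m, what) {
    i <- match(m, tbl$marker)
    if (is.na(i)) stop("marker '", m, "' missing from ", what, call. = FALSE)
    tbl[i, ]
  }
  m1 <- get_row(map, outlier, "map"); m2 <- get_row(map, neighbor, "map")
  s1 <- get_row(scaffolds, outlier, "scaffold table")
  s2 <- get_row(scaffolds, neighbor, "scaffold table")
  span_cm <- if (m1$linkage_group == m2$linkage_group) abs(m1$cM - m2$cM) else NA_real_
  same_scaf <- s1$scaffold == s2$scaffold
  ratio <- NA_real_
  if (same_scaf && !is.na(span_cm) && span_cm > 0) {
    ratio <- abs(s1$bp - s2$bp) / 1000 / span_cm  # kb per cM
  }
  fallback <- function(method) {
    tibble::tibble(outlier = outlier, neighbor = neighbor, method = method,
                   ratio_kb_per_cm = ratio, span_cm = span_cm,
                   window_kb = 20)
  }
  if (!same_scaf || r2 < 0.2) return(fallback("fixed_10kb"))
  if (is.na(ratio)) {
    warning("zero genetic span on a shared scaffold; falling back to +/-10 kb")
    return(fallback("fixed_10kb_degenerate"))
  }
  if (r2 > 0.4) {
    window <- ratio * span_cm
    method <- "ratio_x_span"
  } else {
    if (is.null(decay_cm)) {
      stop("moderate LD (0.2 <= r2 <= 0.4) needs `decay_cm` from fit_decay()",
           call. = FALSE)
    }
    window <- ratio * decay_cm
    method <- "ratio_x_decay"
  }
  tibble::tibble(outlier = outlier, neighbor = neighbor, method = method,
                 ratio_kb_per_cm = ratio, span_cm = span_cm,
                 window_kb = window)
}
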