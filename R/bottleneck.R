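#' Equilibrium heterozygosity distribution for a given allele count
#'
#' Coalescent simulation of `n_genes` gene copies in a single panmictic
#' population mutating under the two-phase model (single steps with
#' probability `p_smm`, otherwise geometric multi-step jumps with the given
#' variance; `p_smm = 1` is the strict stepwise model). The scaled mutation
#' rate is tuned by bracketed search so that the mean simulated allele
#' count matches `k` (Ewens' formula provides the starting point), and
#' simulated loci are then accepted conditionally on showing exactly `k`
#' alleles. Heterozygosity uses the unbiased `n/(n-1)` correction.
#'
#' @param k Observed allele count (`2 <= k <= n_genes`).
#' @param n_genes Sampled gene copies.
#' @param p_smm Single-step probability of the TPM.
#' @param variance Variance of the multi-step jump distribution.
#' @param n_sim Accepted equilibrium loci to simulate.
#' @param seed Optional RNG seed.
#' @return List `mean`, `sd`, `heq` (accepted equilibrium He values),
#'   `theta` (tuned mutation parameter).
#' @export
heq_simulate <- function(k, n_genes, p_smm = 0.7, variance = 30,
                         n_sim = 1000, seed = NULL) {
  if (k < 2 || k > n_genes) stop("need 2 <= k <= n_genes", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  geom_p <- (sqrt(1 + 4 * variance) - 1) / (2 * variance)
  sim_k_he <- function(theta, n_loci) {
    states <- .coalescent_island_cpp(
      sample_sizes = as.integer(n_genes), sample_demes = 1L, n_demes = 1L,
      deme_group = 0L, mig_within = 0, mig_between = 0,
      theta = rep(theta, n_loci), p_smm = p_smm, geom_p = geom_p)
    ks <- apply(states, 2, function(s) length(unique(s)))
    he <- apply(states, 2, function(s) {
      p <- table(s) / n_genes
      n_genes / (n_genes - 1) * (1 - sum(p^2))
    })
    list(k = ks, he = he)
  }
  # starting point: infinite-alleles (Ewens) theta with E[K] = k
  ek <- function(theta) sum(theta / (theta + 0:(n_genes - 1)))
  theta <- if (k >= n_genes) 100 else
    stats::uniroot(function(t) ek(t) - k, c(1e-4, 1e6), tol = 1e-8)$root
  # refine on the log scale against the simulated mean allele count (the
  # SMM/TPM produce fewer alleles than IAM at equal theta)
  lo <- theta / 64; hi <- theta * 64
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    mk <- mean(sim_k_he(mid, 150L)$k)
    if (abs(mk - k) < 0.15) { theta <- mid; break }
    if (mk > k) hi <- mid else lo <- mid
    theta <- mid
  }
  heq <- numeric(0)
  tries <- 0L
  while (length(heq) < n_sim) {
    tries <- tries + 1L
    if (tries > 400L) {
      stop(sprintf("allele count k = %d unattainable at n = %d under this model",
                   k, n_genes), call. = FALSE)
    }
    b <- sim_k_he(theta, 500L)
    heq <- c(heq, b$he[b$k == k])
  }
  heq <- heq[seq_len(n_sim)]
  list(mean = mean(heq), sd = stats::sd(heq), heq = heq, theta = theta)
}

# Poisson-binomial pmf by dynamic programming
.poisbinom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Heterozygosity-excess sign test
#'
#' A locus shows heterozygosity excess when its observed gene diversity
#' exceeds the mean of its simulated equilibrium distribution (matched on
#' allele count and sample size). Under mutation-drift equilibrium the
#' per-locus excess probability is estimated from the same simulations as
#' `P(Heq_sim > mean(Heq_sim))`; the test compares the observed number of
#' excess loci with this Poisson-binomial reference exactly (dynamic
#' programming), two-tailed.
#'
#' @param he_obs Numeric vector of observed per-locus gene diversities.
#' @param heq_sims List of simulated equilibrium He vectors, one per locus
#'   (e.g. the `heq` element of [heq_simulate()]).
#' @return List `p`, `n_excess`, `expected_excess`, `per_locus` tibble.
#' @export
sign_test <- function(he_obs, heq_sims) {
  stopifnot(length(he_obs) == length(heq_sims))
  if (length(he_obs) < 10) {
    warning("sign test on fewer than 10 informative loci is weak")
  }
  mu <- vapply(heq_sims, mean, numeric(1))
  p_exc <- vapply(heq_sims, function(h) mean(h > mean(h)), numeric(1))
  excess <- he_obs > mu
  d <- sum(excess)
  pmf <- .poisbinom_pmf(p_exc)
  counts <- seq_along(pmf) - 1L
  p <- min(1, 2 * min(sum(pmf[counts >= d]), sum(pmf[counts <= d])))
  list(p = p, n_excess = d, expected_excess = sum(p_exc),
       per_locus = tibble::tibble(he_obs = he_obs, heq_mean = mu,
                                  excess = excess, p_excess = p_exc))
}

#' Allele-frequency mode-shift test
#'
#' Bins pooled allele frequencies into ten classes of width 0.1. At
#' mutation-drift equilibrium rare alleles are numerous and the lowest
#' class `(0, 0.1]` is modal (an "L-shaped" distribution); a recently
#' bottlenecked population shifts the mode into an intermediate class.
#'
#' @param freqs Numeric vector of allele frequencies pooled over the loci
#'   of one group.
#' @return List `verdict` (`"L-shaped"` or `"shifted"`) and `classes`
#'   tibble (`bin_low`, `bin_high`, `count`).
#' @export
mode_shift <- function(freqs) {
  freqs <- freqs[!is.na(freqs) & freqs > 0]
  if (length(freqs) < 30) {
    warning("mode-shift test on fewer than 30 pooled alleles is unreliable")
  }
  cls <- cut(freqs, breaks = seq(0, 1, by = 0.1), include.lowest = FALSE)
  counts <- as.integer(table(cls))
  verdict <- if (counts[1] > max(counts[-1])) "L-shaped" else "shifted"
  list(verdict = verdict,
       classes = tibble::tibble(bin_low = seq(0, 0.9, 0.1),
                                bin_high = seq(0.1, 1, 0.1),
                                count = counts))
}

#' Bottleneck analysis of one group
#'
#' Per-locus equilibrium heterozygosity simulation under the two-phase
#' mutation model (memoised over shared allele-count/sample-size
#' configurations), the heterozygosity-excess sign test and the
#' mode-shift test.
#'
#' @param gm A [geno_matrix()].
#' @param group Character vector of individual ids (default: everyone).
#' @param p_smm,variance TPM parameters (defaults 0.70 and 30).
#' @param n_sim Equilibrium simulations per configuration.
#' @param seed RNG seed.
#' @return A `bottleneck_result`: `per_locus` tibble (`locus`, `k`,
#'   `n_genes`, `he_obs`, `heq_mean`, `heq_sd`, `dh_sd`, `excess`),
#'   `sign_p`, `n_excess`, `expected_excess`, `mode_shift` verdict and
#'   class counts.
#' @export
bottleneck_test <- function(gm, group = NULL, p_smm = 0.7, variance = 30,
                            n_sim = 1000, seed = 1) {
  group <- group %||% individuals(gm)
  sub <- gm[group, ]
  set.seed(seed)
  freqs <- allele_frequencies(sub, setNames(rep("g", length(group)), group))
  per <- freqs |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(k = dplyr::n(), n_genes = .data$n_genes[1],
                     he_obs = unbiased_gene_diversity(.data$freq, .data$n_genes[1]),
                     .groups = "drop")
  per <- dplyr::filter(per, .data$k >= 2, .data$n_genes >= 4)
  cache <- new.env(parent = emptyenv())
  sims <- vector("list", nrow(per))
  for (i in seq_len(nrow(per))) {
    key <- paste0(per$k[i], ":", per$n_genes[i])
    if (is.null(cache[[key]])) {
      cache[[key]] <- heq_simulate(per$k[i], per$n_genes[i], p_smm = p_smm,
                                   variance = variance, n_sim = n_sim)
    }
    sims[[i]] <- cache[[key]]
  }
  per$heq_mean <- vapply(sims, `[[`, numeric(1), "mean")
  per$heq_sd <- vapply(sims, `[[`, numeric(1), "sd")
  per$dh_sd <- (per$he_obs - per$heq_mean) / per$heq_sd
  per$excess <- per$he_obs > per$heq_mean
  st <- sign_test(per$he_obs, lapply(sims, `[[`, "heq"))
  ms <- mode_shift(freqs$freq[freqs$defined])
  structure(list(per_locus = per, sign_p = st$p, n_excess = st$n_excess,
                 expected_excess = st$expected_excess,
                 mode_shift = ms$verdict, classes = ms$classes,
                 model = list(p_smm = p_smm, variance = variance,
                              n_sim = n_sim, seed = seed)),
            class = "bottleneck_result")
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat(sprintf(paste0("<bottleneck_result> %d loci; excess at %d ",
                     "(expected %.1f); sign-test p = %.3g; mode shift: %s\n"),
              nrow(x$per_locus), x$n_excess, x$expected_excess, x$sign_p,
              x$mode_shift))
  invisible(x)
}

#' @export
tidy.bottleneck_result <- function(x, ...) x$per_locus

#' @export
glance.bottleneck_result <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x$per_locus), n_excess = x$n_excess,
                 expected_excess = x$expected_excess, sign_p = x$sign_p,
                 mode_shift = x$mode_shift)
}
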