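#' Thin loci by linkage disequilibrium
#'
#' Greedy scan along each linkage group (in map order): a locus is dropped
#' when its r2 with any already retained locus on the same group exceeds
#' `r2_max`. Loci failing the minor-allele-frequency filter are dropped
#' first.
#'
#' @param gm A [geno_matrix()].
#' @param map Linkage map tibble.
#' @param r2_max Maximum tolerated pairwise r2 (conventionally 0.4).
#' @param maf_min Pooled minor-allele-frequency cutoff (0.05).
#' @param unmapped `"drop"` (default) excludes unmapped loci, `"keep"`
#'   passes them through untested.
#' @return Character vector of retained locus names.
#' @export
thin_by_ld <- function(gm, map, r2_max = 0.4, maf_min = 0.05,
                       unmapped = c("drop", "keep")) {
  unmapped <- match.arg(unmapped)
  pooled <- setNames(rep("all", nrow(gm$a1)), individuals(gm))
  mafs <- minor_allele_frequency(allele_frequencies(gm, pooled))
  pass_maf <- mafs$locus[mafs$maf >= maf_min]
  H <- .haplotype_matrix(gm)
  kept <- character()
  for (lgname in unique(map$linkage_group)) {
    lg_loci <- map |>
      dplyr::filter(.data$linkage_group == lgname,
                    .data$marker %in% colnames(H),
                    .data$marker %in% pass_maf) |>
      dplyr::arrange(.data$cM)
    kept_lg <- character()
    for (m in lg_loci$marker) {
      ok <- TRUE
      for (k in kept_lg) {
        r2 <- .pair_r2_impl(H[, k], H[, m], k, m, p_value = FALSE)$r2
        if (!is.na(r2) && r2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) kept_lg <- c(kept_lg, m)
    }
    kept <- c(kept, kept_lg)
  }
  if (unmapped == "keep") {
    kept <- c(kept, setdiff(intersect(loci(gm), pass_maf), map$marker))
  }
  intersect(loci(gm), kept)  # original locus order
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-d^2/2` followed by eigendecomposition; axes
#' are ordered by eigenvalue and the reported percent variation is each
#' positive eigenvalue's share.
#'
#' @param dm Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to return.
#' @return A `pcoa_result`: `coords` tibble (`individual`, `axis_1`, ...),
#'   `eig` tibble (`axis`, `eigenvalue`, `pct_variation`).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- .check_distance(dm)
  n <- nrow(dm)
  if (sum(dm^2) == 0) {
    coords <- matrix(0, n, n_axes)
    eig <- tibble::tibble(axis = seq_len(n_axes), eigenvalue = 0,
                          pct_variation = NA_real_)
  } else {
    J <- diag(n) - matrix(1 / n, n, n)
    B <- -0.5 * J %*% (dm^2) %*% J
    e <- eigen((B + t(B)) / 2, symmetric = TRUE)
    pos <- e$values > 1e-10
    shares <- ifelse(pos, 100 * e$values / sum(e$values[pos]), NA_real_)
    n_axes <- min(n_axes, n)
    coords <- e$vectors[, seq_len(n_axes), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(n_axes)], 0)), n_axes)
    eig <- tibble::tibble(axis = seq_len(n_axes),
                          eigenvalue = e$values[seq_len(n_axes)],
                          pct_variation = shares[seq_len(n_axes)])
  }
  coords <- as.data.frame(coords)
  names(coords) <- paste0("axis_", seq_len(ncol(coords)))
  out <- list(coords = tibble::as_tibble(cbind(
    tibble::tibble(individual = rownames(dm) %||% as.character(seq_len(n))),
    coords)), eig = eig)
  class(out) <- "pcoa_result"
  out
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d points; axis shares: %s\n",
              nrow(x$coords),
              paste(sprintf("%.1f%%", x$eig$pct_variation), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.pcoa_result <- function(x, ...) x$coords

#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- object$coords
  if (!is.null(colour)) df$colour <- colour[df$individual]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis_1, .data$axis_2)) +
    ggplot2::labs(
      x = sprintf("PCo 1 (%.1f%%)", object$eig$pct_variation[1]),
      y = sprintf("PCo 2 (%.1f%%)", object$eig$pct_variation[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour))
}

#' Reduced STRUCTURE-style admixture Gibbs sampler
#'
#' Bayesian clustering of multiallelic genotypes under the admixture model:
#' cluster allele frequencies get a symmetric Dirichlet(lambda = 1) prior,
#' individual admixture proportions a symmetric Dirichlet(alpha) prior with
#' alpha itself sampled by a Metropolis step (uniform prior on (0, 10)),
#' and each allele copy carries a latent cluster-of-origin updated by
#' Gibbs. No linkage model or prior population information is used. The
#' model log-likelihood estimator is `mean(lnL) - var(lnL)/2` over kept
#' sweeps (the usual harmonic-variance estimator of lnP(D)).
#'
#' @param gm A [geno_matrix()].
#' @param K Number of clusters (>= 1; must not exceed the individuals).
#' @param burn_in Burn-in sweeps.
#' @param iters Post-burn-in sweeps used for posterior means.
#' @param seed Optional RNG seed; fixing it makes runs bit-identical.
#' @return A `q_matrix`: posterior-mean membership matrix `Q` (individuals
#'   x K, rows summing to 1), `ln_pd`, `alpha` (posterior mean), and run
#'   metadata.
#' @export
admixture_gibbs <- function(gm, K, burn_in = 10000, iters = 100000,
                            seed = NULL) {
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  n <- nrow(gm$a1)
  if (K > n) stop("K exceeds the number of individuals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- individuals(gm)

  # flatten non-missing allele copies: individual, locus, global allele slot
  L <- ncol(gm$a1)
  alleles <- lapply(seq_len(L), function(j) sort(unique(stats::na.omit(c(gm$a1[, j], gm$a2[, j])))))
  n_all <- vapply(alleles, length, integer(1))
  offset <- c(0L, cumsum(n_all))[seq_len(L)]
  S <- sum(n_all)
  slot_locus <- rep(seq_len(L), n_all)

  obs_ind <- integer(0); obs_slot <- integer(0)
  for (j in seq_len(L)) {
    ok <- which(!is.na(gm$a1[, j]))
    s1 <- offset[j] + match(gm$a1[ok, j], alleles[[j]])
    s2 <- offset[j] + match(gm$a2[ok, j], alleles[[j]])
    obs_ind <- c(obs_ind, ok, ok)
    obs_slot <- c(obs_slot, s1, s2)
  }
  M <- length(obs_ind)
  lambda <- 1

  Z <- sample.int(K, M, replace = TRUE)
  alpha <- 1
  Qsum <- matrix(0, n, K)
  lnL_kept <- numeric(iters)
  alpha_sum <- 0
  total <- burn_in + iters

  for (sweep in seq_len(total)) {
    # P | Z: Dirichlet(lambda + slot counts) per cluster and locus
    Pmat <- matrix(0, S, K)
    for (k in seq_len(K)) {
      cnt <- tabulate(obs_slot[Z == k], nbins = S)
      gam <- stats::rgamma(S, shape = lambda + cnt)
      Pmat[, k] <- gam / rep(rowsum(gam, slot_locus)[, 1], n_all)
    }
    # Q | Z: Dirichlet(alpha + per-individual cluster counts)
    mik <- matrix(0, n, K)
    for (k in seq_len(K)) mik[, k] <- tabulate(obs_ind[Z == k], nbins = n)
    gamq <- matrix(stats::rgamma(n * K, shape = alpha + mik), n, K)
    Q <- gamq / rowSums(gamq)
    # alpha: Metropolis with symmetric normal proposal, uniform(0,10) prior
    if (K > 1) {
      prop <- alpha + stats::rnorm(1, 0, 0.25)
      if (prop > 0 && prop < 10) {
        lr <- n * (lgamma(K * prop) - K * lgamma(prop) -
                   lgamma(K * alpha) + K * lgamma(alpha)) +
          (prop - alpha) * sum(log(Q))
        if (log(stats::runif(1)) < lr) alpha <- prop
      }
    }
    # Z | P, Q: categorical per allele copy
    W <- Q[obs_ind, , drop = FALSE] * Pmat[obs_slot, , drop = FALSE]
    rs <- rowSums(W)
    if (K > 1) {
      cum <- W %*% upper.tri(diag(K), diag = TRUE)
      u <- stats::runif(M) * rs
      Z <- max.col(cum >= u, ties.method = "first")
    }
    if (sweep > burn_in) {
      kept <- sweep - burn_in
      Qsum <- Qsum + Q
      lnL_kept[kept] <- sum(log(rs))
      alpha_sum <- alpha_sum + alpha
    }
  }
  Qbar <- Qsum / iters
  if (K == 1) Qbar <- matrix(1, n, 1)
  dimnames(Qbar) <- list(ids, paste0("cluster_", seq_len(K)))
  ln_pd <- mean(lnL_kept) - stats::var(lnL_kept) / 2
  structure(list(Q = Qbar, ln_pd = ln_pd,
                 alpha = alpha_sum / iters,
                 meta = list(K = K, seed = seed, burn_in = burn_in,
                             iters = iters)),
            class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat(sprintf("<q_matrix> K = %d, %d individuals, lnP(D) = %.1f\n",
              x$meta$K, nrow(x$Q), x$ln_pd))
  invisible(x)
}

#' @export
tidy.q_matrix <- function(x, ...) {
  tibble::as_tibble(x$Q, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "cluster",
                        names_prefix = "cluster_", values_to = "q") |>
    dplyr::mutate(cluster = as.integer(.data$cluster))
}

#' @export
glance.q_matrix <- function(x, ...) {
  tibble::tibble(K = x$meta$K, ln_pd = x$ln_pd, alpha = x$alpha,
                 burn_in = x$meta$burn_in, iters = x$meta$iters)
}

#' @export
autoplot.q_matrix <- function(object, order_by = NULL, ...) {
  df <- tidy(object)
  if (!is.null(order_by)) {
    df$individual <- factor(df$individual, levels = order_by)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$individual, .data$q,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "membership Q", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Run the admixture sampler over a range of K
#'
#' Replicated [admixture_gibbs()] runs per K, collecting lnP(D) for Evanno
#' delta-K model choice.
#'
#' @inheritParams admixture_gibbs
#' @param k_range Integer vector of K values (e.g. `1:12`).
#' @param n_reps Replicate runs per K.
#' @param seed Base seed; run r of K k uses `seed + 1000 * k + r`.
#' @param keep_q Keep each run's Q matrix (default only the best-lnP(D) run
#'   per K).
#' @return A `structure_scan`: tibble `runs` (`K`, `rep`, `ln_pd`, `seed`)
#'   and list `q` of retained `q_matrix` objects indexed by K.
#' @export
structure_scan <- function(gm, k_range, n_reps = 3, burn_in = 1000,
                           iters = 2000, seed = 1, keep_q = FALSE) {
  runs <- list(); qs <- list()
  for (k in k_range) {
    best <- NULL
    for (r in seq_len(n_reps)) {
      s <- seed + 1000L * k + r
      fit <- admixture_gibbs(gm, K = k, burn_in = burn_in, iters = iters,
                             seed = s)
      runs[[length(runs) + 1L]] <- tibble::tibble(K = k, rep = r,
                                                  ln_pd = fit$ln_pd, seed = s)
      if (keep_q) qs[[paste0("K", k, "_r", r)]] <- fit
      if (is.null(best) || fit$ln_pd > best$ln_pd) best <- fit
    }
    qs[[paste0("K", k)]] <- best
  }
  structure(list(runs = dplyr::bind_rows(runs), q = qs),
            class = "structure_scan")
}

#' Evanno delta-K statistic
#'
#' From replicate lnP(D) values per K: `L'(K) = mean L(K) - mean L(K-1)`,
#' `|L''(K)| = |L'(K+1) - L'(K)|`, `delta_K = |L''(K)| / sd(L(K))`.
#' Defined only for interior K with replicate spread; zero replicate
#' standard deviation flags the value undefined.
#'
#' @param scan A `structure_scan` or a tibble with columns `K`, `ln_pd`.
#' @return Tibble `K`, `mean_ln_pd`, `sd_ln_pd`, `l_prime`, `l_double`,
#'   `delta_k`.
#' @export
evanno_delta_k <- function(scan) {
  runs <- if (inherits(scan, "structure_scan")) scan$runs else tibble::as_tibble(scan)
  agg <- runs |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(mean_ln_pd = mean(.data$ln_pd),
                     sd_ln_pd = stats::sd(.data$ln_pd),
                     n_reps = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(agg) < 3 || any(agg$n_reps < 2)) {
    stop("delta-K needs >= 3 consecutive K values with >= 2 replicates each",
         call. = FALSE)
  }
  lp <- c(NA, diff(agg$mean_ln_pd))  # L'(K)
  ldd <- rep(NA_real_, nrow(agg))    # |L''(K)| = |L'(K+1) - L'(K)|
  for (i in 2:(nrow(agg) - 1)) ldd[i] <- abs(lp[i + 1] - lp[i])
  agg |>
    dplyr::mutate(l_prime = lp,
                  l_double = ldd,
                  delta_k = ifelse(.data$sd_ln_pd > 0, ldd / .data$sd_ln_pd,
                                   NA_real_)) |>
    dplyr::select(-"n_reps")
}

#' @export
autoplot.structure_scan <- function(object, ...) {
  ev <- evanno_delta_k(object)
  ggplot2::ggplot(ev, ggplot2::aes(.data$K, .data$delta_k)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = expression(Delta * K)) +
    ggplot2::theme_minimal()
}

#' Assign individuals to groups by membership threshold
#'
#' The conventional Q-threshold rule: an individual joins its argmax
#' cluster when the maximum membership reaches `threshold`, otherwise it is
#' `"admixed"`.
#'
#' @param q A `q_matrix` (or bare Q matrix).
#' @param threshold Membership cutoff (0.70 by convention).
#' @return Tibble `individual`, `cluster` (argmax), `max_q`, `group`.
#' @export
assign_groups <- function(q, threshold = 0.70) {
  Q <- if (inherits(q, "q_matrix")) q$Q else as.matrix(q)
  cl <- max.col(Q, ties.method = "first")
  mx <- Q[cbind(seq_len(nrow(Q)), cl)]
  tibble::tibble(
    individual = rownames(Q) %||% as.character(seq_len(nrow(Q))),
    cluster = cl,
    max_q = mx,
    group = ifelse(mx >= threshold, paste0("cluster_", cl), "admixed")
  )
}
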