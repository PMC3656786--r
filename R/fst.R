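# per-locus data prepared once so that permutation tests only reshuffle
# group labels: called-individual indices, allele codes of both slots, and
# heterozygosity flags
.fst_locus_data <- function(gm) {
  lapply(seq_len(ncol(gm$a1)), function(j) {
    ok <- which(!is.na(gm$a1[, j]))
    g1 <- gm$a1[ok, j]
    g2 <- gm$a2[ok, j]
    codes <- sort(unique(c(g1, g2)))
    list(ok = ok,
         c1 = match(g1, codes), c2 = match(g2, codes),
         het = g1 != g2, n_alleles = length(codes))
  })
}

# Weir-Cockerham (1984) variance components summed over alleles, one locus
.wc_locus <- function(ld, grp) {
  g <- grp[ld$ok]
  pops <- sort(unique(g))
  r <- length(pops)
  if (r < 2) return(c(a = 0, b = 0, c = 0))
  gi <- match(g, pops)
  n_i <- tabulate(gi, r)
  if (any(n_i == 0) || sum(n_i) == 0) return(c(a = 0, b = 0, c = 0))
  A <- ld$n_alleles
  # allele copy counts and het-carrier counts per (pop, allele)
  cnt <- matrix(tabulate(gi + r * (ld$c1 - 1L), r * A) +
                tabulate(gi + r * (ld$c2 - 1L), r * A), r, A)
  hets <- which(ld$het)
  hcnt <- matrix(tabulate(gi[hets] + r * (ld$c1[hets] - 1L), r * A) +
                 tabulate(gi[hets] + r * (ld$c2[hets] - 1L), r * A), r, A)
  p <- cnt / (2 * n_i)
  h <- hcnt / n_i
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  if (nc <= 0) return(c(a = 0, b = 0, c = 0))
  asum <- bsum <- csum <- 0
  for (al in seq_len(A)) {
    pbar <- sum(n_i * p[, al]) / (r * nbar)
    s2 <- sum(n_i * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h[, al]) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    asum <- asum + a; bsum <- bsum + b; csum <- csum + cc
  }
  c(a = asum, b = bsum, c = csum)
}

# Nei G_ST components for one locus: (Hs, Ht), unweighted over populations
.gst_locus <- function(ld, grp) {
  g <- grp[ld$ok]
  pops <- sort(unique(g))
  if (length(pops) < 2) return(c(hs = NA_real_, ht = NA_real_))
  gi <- match(g, pops)
  r <- length(pops)
  cnt <- matrix(tabulate(gi + r * (ld$c1 - 1L), r * ld$n_alleles) +
                tabulate(gi + r * (ld$c2 - 1L), r * ld$n_alleles),
                r, ld$n_alleles)
  pm <- cnt / rowSums(cnt)
  hs <- mean(1 - rowSums(pm^2))
  pbar <- colMeans(pm)
  ht <- 1 - sum(pbar^2)
  c(hs = hs, ht = ht)
}

#' Weir-Cockerham and Nei F-statistics
#'
#' Multiallelic Weir-Cockerham theta (variance components summed over
#' alleles and loci) as the primary estimator of population
#' differentiation, with Nei's `G_ST = (Ht - Hs)/Ht` as a cross-check.
#'
#' @param gm A [geno_matrix()].
#' @param grouping Named character vector individual -> group (>= 2 groups).
#' @return List with `theta`, `gst` and `per_locus` (tibble `locus`,
#'   `theta`, `hs`, `ht`).
#' @export
wc_fst <- function(gm, grouping = NULL) {
  grouping <- .pop_of(gm, grouping)
  grp <- unname(grouping[individuals(gm)])
  if (length(unique(grp)) < 2) stop("need at least 2 groups", call. = FALSE)
  lds <- .fst_locus_data(gm)
  comps <- vapply(lds, .wc_locus, numeric(3), grp = grp)
  gsts <- vapply(lds, .gst_locus, numeric(2), grp = grp)
  theta_per <- ifelse(colSums(comps) == 0, NA_real_,
                      comps["a", ] / (comps["a", ] + comps["b", ] + comps["c", ]))
  tot <- rowSums(comps)
  hs_m <- mean(gsts["hs", ], na.rm = TRUE)
  ht_m <- mean(gsts["ht", ], na.rm = TRUE)
  list(
    theta = if (sum(tot) == 0) NA_real_ else unname(tot["a"] / sum(tot)),
    gst = if (is.finite(ht_m) && ht_m > 0) (ht_m - hs_m) / ht_m else NA_real_,
    per_locus = tibble::tibble(locus = loci(gm),
                               theta = theta_per,
                               hs = gsts["hs", ], ht = gsts["ht", ])
  )
}

#' Pairwise FST with permutation significance
#'
#' Weir-Cockerham theta for every pair of groups, with Nei G\\_ST alongside;
#' significance from permuting individuals across the pair (add-one rule
#' `p = (b + 1)/(n_perm + 1)`).
#'
#' @inheritParams wc_fst
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Optional RNG seed.
#' @return Tibble `group_1`, `group_2`, `theta`, `gst`, `p`, `n_1`, `n_2`.
#'   Pairs monomorphic across all loci are flagged with `NA` theta.
#' @export
pairwise_fst <- function(gm, grouping = NULL, n_perm = 999, seed = NULL) {
  grouping <- .pop_of(gm, grouping)
  if (!is.null(seed)) set.seed(seed)
  groups <- unique(unname(grouping))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(unname(grouping))
  if (any(sizes < 2)) stop("each group needs at least 2 individuals", call. = FALSE)
  idx <- utils::combn(length(groups), 2)
  purrr::map_dfr(seq_len(ncol(idx)), function(cp) {
    ga <- groups[idx[1, cp]]; gb <- groups[idx[2, cp]]
    ind <- names(grouping)[grouping %in% c(ga, gb)]
    sub <- gm[ind, ]
    sub_grp <- grouping[ind]
    est <- wc_fst(sub, sub_grp)
    p <- NA_real_
    if (n_perm > 0 && is.finite(est$theta)) {
      lds <- .fst_locus_data(sub)
      grp_vec <- unname(sub_grp[individuals(sub)])
      obs <- est$theta
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(grp_vec)
        comps <- vapply(lds, .wc_locus, numeric(3), grp = perm)
        tot <- rowSums(comps)
        th <- if (sum(tot) == 0) NA_real_ else tot["a"] / sum(tot)
        if (!is.na(th) && th >= obs) hits <- hits + 1L
      }
      p <- (hits + 1) / (n_perm + 1)
    }
    tibble::tibble(group_1 = ga, group_2 = gb, theta = est$theta,
                   gst = est$gst, p = p,
                   n_1 = sum(grouping == ga), n_2 = sum(grouping == gb))
  })
}
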