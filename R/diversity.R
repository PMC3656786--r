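#' Unbiased gene diversity
#'
#' Nei's unbiased expected heterozygosity for one (population, locus):
#' `(n/(n-1)) * (1 - sum(p^2))`, where `n` is the number of sampled allele
#' copies (the GenAlEx convention), clipped at 1. `n < 2` is undefined and
#' returns `NA`.
#'
#' @param p Numeric vector of allele frequencies (must sum to 1).
#' @param n_genes Number of allele copies behind `p`.
#' @return A value in `[0, 1]`, or `NA` when undefined.
#' @examples
#' unbiased_gene_diversity(c(0.5, 0.5), 8)  # 4/7
#' @export
unbiased_gene_diversity <- function(p, n_genes) {
  if (is.na(n_genes) || n_genes < 2) return(NA_real_)
  min(1, n_genes / (n_genes - 1) * (1 - sum(p^2)))
}

#' Plain (biased) gene diversity
#' @inheritParams unbiased_gene_diversity
#' @export
gene_diversity <- function(p) 1 - sum(p^2)

#' Observed heterozygosity
#'
#' Fraction of non-missing individuals whose two allele slots differ, per
#' (population, locus).
#'
#' @param gm A [geno_matrix()].
#' @param grouping Optional individual -> population labels (see
#'   [allele_frequencies()]).
#' @return Tibble `population`, `locus`, `ho`, `n` (called individuals).
#' @export
observed_heterozygosity <- function(gm, grouping = NULL) {
  grouping <- .pop_of(gm, grouping)
  sub <- gm[names(grouping), ]
  het <- !is.na(sub$a1) & sub$a1 != sub$a2
  called <- !is.na(sub$a1)
  tibble::tibble(
    population = rep(unname(grouping), times = ncol(sub$a1)),
    locus = rep(colnames(sub$a1), each = nrow(sub$a1)),
    het = as.vector(het), called = as.vector(called)
  ) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(n = sum(.data$called),
                     ho = ifelse(sum(.data$called) > 0,
                                 sum(.data$het) / sum(.data$called), NA_real_),
                     .groups = "drop") |>
    dplyr::select("population", "locus", "ho", "n")
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' `FIS = 1 - Ho/He`; undefined (`NA`) when `He` is 0.
#'
#' @param ho,he Observed and expected (gene diversity) heterozygosity.
#' @export
fis <- function(ho, he) ifelse(is.na(he) | he <= 0, NA_real_, 1 - ho / he)

#' Polymorphism information content
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p Allele frequency vector.
#' @return PIC in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(p) {
  s2 <- sum(p^2)
  # sum_{i<j} p_i^2 p_j^2 = ((sum p^2)^2 - sum p^4) / 2
  1 - s2 - (s2^2 - sum(p^4))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed hypergeometrically from the observed allele counts:
#' `sum_a [1 - C(n - n_a, g)/C(n, g)]`.
#'
#' @param counts Integer vector of allele copy counts at one
#'   (population, locus).
#' @param g Standardised number of gene copies (`g <= sum(counts)`).
#' @return Expected allele number (>= 1 for any locus with data and g >= 1).
#' @examples
#' rarefied_allelic_richness(c(A = 3, B = 1), g = 2)  # 1.5
#' @export
rarefied_allelic_richness <- function(counts, g) {
  n <- sum(counts)
  if (g > n) {
    stop("rarefaction size g = ", g, " exceeds the ", n,
         " sampled gene copies; lower g", call. = FALSE)
  }
  sum(1 - exp(lchoose(n - counts, g) - lchoose(n, g)))
}

#' Rarefied private allelic richness
#'
#' Kalinowski's hypergeometric estimator of the expected number of alleles
#' that a subsample of `g` gene copies from population `j` contains and that
#' equally sized subsamples from every other population lack:
#' `sum_a P(a in j's subsample) * prod_{k != j} P(a not in k's subsample)`.
#'
#' @param count_matrix Integer matrix populations x alleles of allele copy
#'   counts at one locus (zero rows/columns allowed).
#' @param g Standardised gene copies; must not exceed any population's total.
#' @return Named numeric vector: expected private-allele count per population.
#' @export
rarefied_private_alleles <- function(count_matrix, g) {
  count_matrix <- as.matrix(count_matrix)
  n <- rowSums(count_matrix)
  if (any(g > n)) {
    stop("rarefaction size g = ", g, " exceeds the smallest population's ",
         min(n), " gene copies; lower g", call. = FALSE)
  }
  # p_in[k, a] = P(allele a appears in a g-subsample from population k)
  p_in <- 1 - exp(lchoose(n - count_matrix, g) - lchoose(n, g))
  out <- vapply(seq_len(nrow(count_matrix)), function(j) {
    others <- p_in[-j, , drop = FALSE]
    sum(p_in[j, ] * apply(1 - others, 2, prod))
  }, numeric(1))
  stats::setNames(out, rownames(count_matrix))
}

#' Per-population diversity summary table
#'
#' One row per population plus a pooled row (`population = "total"`):
#' sample size `n`, mean unbiased gene diversity `uhe`, mean observed
#' heterozygosity `ho`, total allele count `na` (and mean per locus),
#' rarefied allelic richness `rs` (mean per locus at `g` gene copies),
#' rarefied private allelic richness `pi_private` (summed over loci; `NA`
#' for the pooled row and single-population inputs rate it against zero
#' competitors, i.e. every allele is private), rare-allele count `ra`
#' (frequency below `maf_rare_threshold` on the population's own
#' frequencies), multilocus `fis` (per-locus 1 - Ho/UHe averaged over
#' polymorphic loci), percent polymorphic loci (strict >= 2 alleles) and
#' mean `pic`. Per-statistic undefined loci are dropped pairwise.
#'
#' @inheritParams observed_heterozygosity
#' @param maf_rare_threshold Rare-allele frequency cutoff (default 0.05).
#' @param g Rarefaction size in gene copies; default twice the smallest
#'   population sample (individuals with any data), capped by the smallest
#'   per-locus gene count actually available.
#' @return A tibble, one row per population plus the pooled `"total"` row;
#'   populations of fewer than 2 individuals are flagged `unreliable`.
#' @export
diversity_table <- function(gm, grouping = NULL, maf_rare_threshold = 0.05,
                            g = NULL) {
  grouping <- .pop_of(gm, grouping)
  pops <- unique(unname(grouping))
  pooled <- stats::setNames(rep("total", length(grouping)), names(grouping))

  freqs <- allele_frequencies(gm, grouping)
  freqs_pool <- allele_frequencies(gm, pooled)
  ho <- dplyr::bind_rows(observed_heterozygosity(gm, grouping),
                         observed_heterozygosity(gm, pooled))
  all_freqs <- dplyr::bind_rows(freqs, freqs_pool)

  if (is.null(g)) {
    g_default <- 2L * min(table(grouping))
    min_genes <- all_freqs |>
      dplyr::filter(.data$defined) |>
      dplyr::group_by(.data$population, .data$locus) |>
      dplyr::summarise(n_genes = .data$n_genes[1], .groups = "drop")
    g <- max(2L, min(g_default, min(min_genes$n_genes)))
  }

  per_locus <- all_freqs |>
    dplyr::filter(.data$defined) |>
    dplyr::group_by(.data$population, .data$locus) |>
    dplyr::summarise(
      n_genes = .data$n_genes[1],
      n_alleles = dplyr::n(),
      uhe = unbiased_gene_diversity(.data$freq, .data$n_genes[1]),
      pic = pic(.data$freq),
      rs = if (.data$n_genes[1] >= g) rarefied_allelic_richness(.data$count, g) else NA_real_,
      n_rare = sum(.data$freq < maf_rare_threshold),
      .groups = "drop"
    ) |>
    dplyr::left_join(ho, by = c("population", "locus")) |>
    dplyr::mutate(fis_locus = fis(.data$ho, .data$uhe))

  # private-allele rarefaction needs cross-population counts per locus;
  # with a single population every allele is trivially private
  priv <- NULL
  if (length(pops) >= 1) {
    priv_by_locus <- freqs |>
      dplyr::filter(.data$defined) |>
      dplyr::group_by(.data$locus) |>
      dplyr::group_map(function(df, key) {
        cm <- tidyr::pivot_wider(df[, c("population", "allele", "count")],
                                 names_from = "allele", values_from = "count",
                                 values_fill = 0L)
        mat <- as.matrix(cm[, -1, drop = FALSE])
        rownames(mat) <- cm$population
        if (nrow(mat) < length(pops) || any(rowSums(mat) < g)) return(NULL)
        tibble::tibble(locus = key$locus,
                       population = rownames(mat),
                       pi_locus = rarefied_private_alleles(mat, g))
      })
    priv <- dplyr::bind_rows(priv_by_locus) |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(pi_private = sum(.data$pi_locus), .groups = "drop")
  }

  pop_sizes <- c(table(grouping), total = length(grouping))
  out <- per_locus |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      uhe = mean(.data$uhe, na.rm = TRUE),
      ho = mean(.data$ho, na.rm = TRUE),
      na = sum(.data$n_alleles),
      na_per_locus = mean(.data$n_alleles),
      rs = mean(.data$rs, na.rm = TRUE),
      ra = sum(.data$n_rare),
      fis = mean(.data$fis_locus[.data$n_alleles > 1], na.rm = TRUE),
      pct_polymorphic = 100 * mean(.data$n_alleles > 1),
      pic = mean(.data$pic, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(n = as.integer(pop_sizes[.data$population]),
                  unreliable = .data$n < 2,
                  g = g)
  if (!is.null(priv)) out <- dplyr::left_join(out, priv, by = "population")
  else out$pi_private <- NA_real_
  out$pi_private[out$population == "total"] <- NA_real_
  out |>
    dplyr::arrange(.data$population != "total", .data$population) |>
    dplyr::select("population", "n", "n_loci", "uhe", "ho", "na",
                  "na_per_locus", "rs", "pi_private", "ra", "fis",
                  "pct_polymorphic", "pic", "g", "unreliable")
}
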