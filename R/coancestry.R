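#' Per-locus molecular coancestry of two genotypes
#'
#' Caballero-Toro identity-by-state score for one locus:
#' `f = 1/4 (I11 + I12 + I21 + I22)` over the four ordered allele
#' cross-comparisons, so the achievable values are exactly
#' {0, 1/4, 1/2, 1}. Two null alleles are identical by state; a null vs a
#' sized allele is not. Either cell missing returns `NA` (the locus is
#' excluded from averaging, not scored 0).
#'
#' @param cell_i,cell_j Length-2 integer vectors of allele codes
#'   (0 = null, `NA` = missing).
#' @return One of 0, 0.25, 0.5, 1, or `NA`.
#' @examples
#' locus_coancestry(c(100, 120), c(100, 140))  # 0.25
#' @export
locus_coancestry <- function(cell_i, cell_j) {
  if (anyNA(cell_i) || anyNA(cell_j)) return(NA_real_)
  ((cell_i[1] == cell_j[1]) + (cell_i[1] == cell_j[2]) +
   (cell_i[2] == cell_j[1]) + (cell_i[2] == cell_j[2])) / 4
}

#' Molecular coancestry matrix
#'
#' Pairwise molecular coancestry `f_ij`: the per-locus identity-by-state
#' score averaged over the loci at which both individuals are called
#' (pairwise deletion of missing loci). The diagonal is the self-coancestry
#' `f_ii = 1 - Ho_i/2`. A histogram of the off-diagonal values (bin width
#' 0.05) is attached for distribution-style reporting.
#'
#' @param gm A [geno_matrix()].
#' @return A `coancestry_matrix`: list with `f` (symmetric matrix),
#'   `n_loci` (matrix of shared called loci; pairs sharing none are `NA` in
#'   `f`) and `histogram` (tibble `bin_low`, `bin_high`, `count`).
#' @export
coancestry_matrix <- function(gm) {
  n <- nrow(gm$a1)
  ids <- individuals(gm)
  f <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  nl <- matrix(0L, n, n, dimnames = list(ids, ids))
  a1 <- gm$a1; a2 <- gm$a2
  for (i in seq_len(n)) {
    for (j in i:n) {
      score <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
               (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      ok <- !is.na(score)
      nl[i, j] <- nl[j, i] <- sum(ok)
      if (any(ok)) f[i, j] <- f[j, i] <- mean(score[ok]) / 4
    }
  }
  off <- f[upper.tri(f)]
  brk <- seq(0, 1, by = 0.05)
  h <- graphics::hist(off[!is.na(off)], breaks = brk, plot = FALSE,
                      right = TRUE, include.lowest = TRUE)
  structure(list(
    f = f, n_loci = nl,
    histogram = tibble::tibble(bin_low = brk[-length(brk)],
                               bin_high = brk[-1],
                               count = h$counts)
  ), class = "coancestry_matrix")
}

#' @export
print.coancestry_matrix <- function(x, ...) {
  off <- x$f[upper.tri(x$f)]
  cat(sprintf("<coancestry_matrix> %d individuals; mean pairwise f = %.3f\n",
              nrow(x$f), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.coancestry_matrix <- function(x, ...) {
  ids <- rownames(x$f)
  idx <- which(upper.tri(x$f, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(individual_1 = ids[idx[, 1]],
                 individual_2 = ids[idx[, 2]],
                 f = x$f[idx],
                 n_loci = x$n_loci[idx])
}

#' @export
glance.coancestry_matrix <- function(x, ...) {
  off <- x$f[upper.tri(x$f)]
  tibble::tibble(n_individuals = nrow(x$f),
                 mean_f = mean(off, na.rm = TRUE),
                 median_f = stats::median(off, na.rm = TRUE),
                 n_undefined_pairs = sum(is.na(off)))
}

#' @export
autoplot.coancestry_matrix <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 0.045) +
    ggplot2::labs(x = "pairwise molecular coancestry f",
                  y = "number of pairs") +
    ggplot2::theme_minimal()
}

#' Within- and between-group coancestry means
#'
#' Mean pairwise coancestry over within-group pairs (i < j) and over
#' between-group pairs, for each group pair. Singleton groups have an
#' undefined intra-group mean (flagged `NA`).
#'
#' @param cm A [coancestry_matrix()].
#' @param grouping Named character vector individual -> group.
#' @return Tibble `group_1`, `group_2`, `type` (`"intra"`/`"inter"`),
#'   `mean_f`, `n_pairs`.
#' @export
group_coancestry_summary <- function(cm, grouping) {
  ids <- rownames(cm$f)
  if (is.null(names(grouping))) names(grouping) <- ids
  g <- grouping[ids]
  if (anyNA(g)) stop("grouping must cover all individuals", call. = FALSE)
  groups <- unique(unname(g))
  pairs <- tidyr::expand_grid(group_1 = groups, group_2 = groups) |>
    dplyr::filter(match(.data$group_1, groups) <= match(.data$group_2, groups))
  purrr::pmap_dfr(pairs, function(group_1, group_2) {
    i <- which(g == group_1)
    j <- which(g == group_2)
    if (identical(group_1, group_2)) {
      vals <- cm$f[i, i][upper.tri(cm$f[i, i])]
    } else {
      vals <- as.vector(cm$f[i, j, drop = FALSE])
    }
    tibble::tibble(group_1, group_2,
                   type = if (identical(group_1, group_2)) "intra" else "inter",
                   mean_f = if (length(vals)) mean(vals, na.rm = TRUE) else NA_real_,
                   n_pairs = length(vals))
  })
}
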