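#' Multiallelic pairwise linkage disequilibrium r-squared
#'
#' For highly selfing material each homozygous individual carries one
#' directly observable two-locus haplotype; heterozygous and missing calls
#' are excluded rather than phased. The multiallelic r2 is the
#' frequency-weighted average of allele-pair r2 values:
#' `r2 = sum_ij p_i q_j D_ij^2 / (p_i (1 - p_i) q_j (1 - q_j))` with
#' `D_ij = P_ij - p_i q_j`. For biallelic loci this reduces exactly to the
#' classical 2x2 r2. Significance comes from a chi-square test on the
#' haplotype contingency table, with a Monte-Carlo p-value when any
#' expected cell is below 5.
#'
#' @param gm A [geno_matrix()].
#' @param locus_a,locus_b Locus identifiers.
#' @param p_value Compute the significance test (default `TRUE`).
#' @return A one-row tibble `locus_a`, `locus_b`, `r2`, `n` (haplotypes
#'   used), `p`. `r2` is `NA` (flagged) when fewer than 2 usable
#'   individuals remain or either locus is monomorphic in the retained set.
#' @export
pair_r2 <- function(gm, locus_a, locus_b, p_value = TRUE) {
  H <- .haplotype_matrix(gm)
  .pair_r2_impl(H[, locus_a], H[, locus_b], locus_a, locus_b, p_value)
}

# homozygote haplotype calls: NA for heterozygous or missing cells
.haplotype_matrix <- function(gm) {
  H <- gm$a1
  H[gm$a1 != gm$a2] <- NA_integer_
  H
}

.pair_r2_impl <- function(ha, hb, locus_a, locus_b, p_value = TRUE) {
  ok <- !is.na(ha) & !is.na(hb)
  n <- sum(ok)
  out <- tibble::tibble(locus_a = locus_a, locus_b = locus_b,
                        r2 = NA_real_, n = n, p = NA_real_)
  if (n < 2) return(out)
  tab <- table(factor(ha[ok]), factor(hb[ok]))
  if (nrow(tab) < 2 || ncol(tab) < 2) return(out)
  P <- tab / n
  p <- rowSums(P)
  q <- colSums(P)
  D <- P - outer(p, q)
  W <- outer(p * (1 - p), q * (1 - q))
  out$r2 <- sum(outer(p, q) * D^2 / W)
  if (p_value) {
    expected <- outer(p, q) * n
    out$p <- suppressWarnings(
      if (any(expected < 5)) {
        stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)$p.value
      } else {
        stats::chisq.test(tab, correct = FALSE)$p.value
      }
    )
  }
  out
}

#' Classify locus pairs as linked or unlinked
#'
#' Pairs on the same linkage group are linked, with genetic distance
#' `|cM_a - cM_b|`; pairs on different groups are unlinked (no distance).
#' Pairs involving unmapped loci are excluded.
#'
#' @param map Linkage map tibble (`marker`, `linkage_group`, `cM`), e.g.
#'   from [read_linkage_map()].
#' @param loci Character vector of locus identifiers to pair up.
#' @return Tibble `locus_a`, `locus_b`, `linked`, `dist_cM` (`NA` for
#'   unlinked pairs).
#' @export
classify_pairs <- function(map, loci) {
  mapped <- map[map$marker %in% loci, ]
  if (nrow(mapped) < 2) {
    return(tibble::tibble(locus_a = character(), locus_b = character(),
                          linked = logical(), dist_cM = numeric()))
  }
  idx <- utils::combn(nrow(mapped), 2)
  tibble::tibble(
    locus_a = mapped$marker[idx[1, ]],
    locus_b = mapped$marker[idx[2, ]],
    linked = mapped$linkage_group[idx[1, ]] == mapped$linkage_group[idx[2, ]],
    dist_cM = ifelse(mapped$linkage_group[idx[1, ]] == mapped$linkage_group[idx[2, ]],
                     abs(mapped$cM[idx[1, ]] - mapped$cM[idx[2, ]]), NA_real_)
  )
}

#' All-pairs LD table
#'
#' Computes the multiallelic r2 of [pair_r2()] for every locus pair
#' (restricted to mapped loci and annotated with linked/unlinked status and
#' cM distance when a map is supplied).
#'
#' @inheritParams pair_r2
#' @param map Optional linkage map tibble.
#' @param maf_min Drop loci whose pooled minor allele frequency is below
#'   this before pairing (0 keeps everything).
#' @return Tibble with one row per pair: `locus_a`, `locus_b`, `r2`, `n`,
#'   `p`, and with a map also `linked`, `dist_cM`.
#' @export
ld_table <- function(gm, map = NULL, maf_min = 0, p_value = TRUE) {
  keep <- loci(gm)
  if (maf_min > 0) {
    mafs <- minor_allele_frequency(
      allele_frequencies(gm, setNames(rep("all", nrow(gm$a1)), individuals(gm))))
    keep <- intersect(keep, mafs$locus[mafs$maf >= maf_min])
  }
  if (!is.null(map)) keep <- intersect(keep, map$marker)
  if (length(keep) < 2) {
    stop("fewer than 2 usable loci for LD", call. = FALSE)
  }
  H <- .haplotype_matrix(gm[, keep])
  idx <- utils::combn(length(keep), 2)
  res <- purrr::map_dfr(seq_len(ncol(idx)), function(c2) {
    .pair_r2_impl(H[, idx[1, c2]], H[, idx[2, c2]],
                  keep[idx[1, c2]], keep[idx[2, c2]], p_value)
  })
  if (!is.null(map)) {
    res <- dplyr::left_join(res, classify_pairs(map, keep),
                            by = c("locus_a", "locus_b"))
  }
  res
}

#' Summary block of an LD table
#'
#' Mean r2 of linked and unlinked pairs, the 95th percentile of the
#' unlinked r2 distribution (linear-interpolation quantile; the empirical
#' threshold separating physical-linkage LD from background), and the
#' percentage of pairs significant at `alpha`.
#'
#' @param ld_tbl Output of [ld_table()] including map annotation.
#' @param alpha Significance level for the percent-significant summary.
#' @return One-row tibble; `percentile_unstable` flags fewer than 20
#'   unlinked pairs behind the percentile.
#' @export
ld_summary <- function(ld_tbl, alpha = 0.05) {
  if (!"linked" %in% names(ld_tbl)) {
    stop("ld_tbl must carry linked/unlinked classification (pass a map)", call. = FALSE)
  }
  def <- dplyr::filter(ld_tbl, !is.na(.data$r2))
  unl <- def$r2[!def$linked]
  tibble::tibble(
    n_pairs = nrow(def),
    n_linked = sum(def$linked),
    n_unlinked = length(unl),
    mean_r2_linked = mean(def$r2[def$linked]),
    mean_r2_unlinked = mean(unl),
    p95_unlinked = stats::quantile(unl, 0.95, type = 7, names = FALSE),
    pct_significant = 100 * mean(def$p <= alpha, na.rm = TRUE),
    percentile_unstable = length(unl) < 20
  )
}

# Hill-Weir drift-recombination expectation of r2 at C = rho * d for a
# sample of n haplotypes
.hill_weir_er2 <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit an LD decay curve
#'
#' Nonlinear least squares of linked-pair (distance, r2) observations to
#' the Hill-Weir drift-recombination expectation
#' `E[r2] = ((10+C)/((2+C)(11+C))) (1 + ((3+C)(12+12C+C^2))/(n(2+C)(11+C)))`
#' with `C = rho * d` (the Breseghello-Sorrells decay-curve approach), and
#' the map distance at which the fitted curve crosses a threshold
#' (`r2 = 0.1` by convention for the genome-wide LD block size).
#'
#' @param ld_tbl LD table with `linked` and `dist_cM` columns.
#' @param n_individuals Number of haplotypes behind each r2 estimate.
#' @param threshold r2 level defining the decay distance.
#' @return An `ld_decay_fit` list: `rho` (per cM), `n`, `threshold`,
#'   `distance_at_threshold` (cM; 0 if the curve starts below the
#'   threshold, `Inf` if it never crosses), `data`, `poor_fit`.
#' @export
fit_decay <- function(ld_tbl, n_individuals, threshold = 0.1) {
  pts <- dplyr::filter(ld_tbl, .data$linked, !is.na(.data$r2), !is.na(.data$dist_cM))
  if (nrow(pts) < 10) stop("need at least 10 linked pairs with distances", call. = FALSE)
  poor <- FALSE
  if (stats::cor(pts$dist_cM, pts$r2) >= 0) {
    warning("r2 does not decrease with distance; decay fit is unreliable")
    poor <- TRUE
  }
  n <- n_individuals
  fit <- minpack.lm::nlsLM(
    r2 ~ .hill_weir_er2(rho * dist_cM, n),
    data = pts, start = list(rho = 1),
    lower = 1e-9, upper = 1e6,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  rho <- unname(stats::coef(fit)["rho"])
  f <- function(d) .hill_weir_er2(rho * d, n)
  dist_thr <- if (f(0) <= threshold) {
    0
  } else {
    hi <- 1
    while (f(hi) > threshold && hi < 1e9) hi <- hi * 2
    if (f(hi) > threshold) Inf
    else stats::uniroot(function(d) f(d) - threshold, c(0, hi), tol = 1e-10)$root
  }
  structure(list(rho = rho, n = n, threshold = threshold,
                 distance_at_threshold = dist_thr,
                 data = pts, poor_fit = poor,
                 rss = sum(stats::resid(fit)^2)),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat(sprintf("<ld_decay_fit> rho = %.4g /cM; r2 = %.2g at %.3g cM%s\n",
              x$rho, x$threshold, x$distance_at_threshold,
              if (x$poor_fit) " [poor fit]" else ""))
  invisible(x)
}

#' @export
tidy.ld_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("rho", "distance_at_threshold"),
                 estimate = c(x$rho, x$distance_at_threshold))
}

#' @export
glance.ld_decay_fit <- function(x, ...) {
  tibble::tibble(rho = x$rho, threshold = x$threshold,
                 distance_at_threshold = x$distance_at_threshold,
                 n_pairs = nrow(x$data), rss = x$rss, poor_fit = x$poor_fit)
}

#' @export
autoplot.ld_decay_fit <- function(object, ...) {
  dmax <- max(object$data$dist_cM)
  curve <- tibble::tibble(dist_cM = seq(0, dmax, length.out = 200))
  curve$r2 <- .hill_weir_er2(object$rho * curve$dist_cM, object$n)
  ggplot2::ggplot(object$data, ggplot2::aes(.data$dist_cM, .data$r2)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = curve, colour = "red") +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2,
                        colour = "blue") +
    ggplot2::labs(x = "genetic distance (cM)", y = expression(r^2)) +
    ggplot2::theme_minimal()
}

#' Bin linked-pair LD by distance
#'
#' Averages linked-pair r2 in distance bins of a given width (conventionally
#' the genome-wide LD block estimate), for comparing decay trends across
#' groups.
#'
#' @param ld_tbl LD table with `linked` and `dist_cM`.
#' @param width Bin width in cM.
#' @return Tibble `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay_bins <- function(ld_tbl, width) {
  pts <- dplyr::filter(ld_tbl, .data$linked, !is.na(.data$r2))
  pts |>
    dplyr::mutate(bin = floor(.data$dist_cM / width)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bin_mid = (.data$bin[1] + 0.5) * width,
                     mean_r2 = mean(.data$r2),
                     n_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"bin")
}
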