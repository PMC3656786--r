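#' Nei minimum genetic distance between individuals
#'
#' Treats each individual's genotype as an allele-frequency vector with
#' entries 0, 1/2 or 1 (the null allele is an allele like any other) and
#' averages, over the loci at which both individuals are called,
#' `D_l = (sum(x^2) + sum(y^2))/2 - sum(x * y)`.
#'
#' @param gm A [geno_matrix()].
#' @return A symmetric distance matrix with zero diagonal (class `matrix`);
#'   pairs sharing no called locus are `NA`. Use [stats::as.dist()] or
#'   [neighbor_joining()] downstream.
#' @examples
#' res <- sim_flaxlike(seed = 1, n_loci = 20, sample_sizes = 4)
#' d <- nei_minimum_distance(res$genotypes)
#' @export
nei_minimum_distance <- function(gm) {
  n <- nrow(gm$a1)
  ids <- individuals(gm)
  a1 <- gm$a1; a2 <- gm$a2
  sx <- ifelse(a1 == a2, 1, 0.5)  # sum of squared 0/0.5/1 frequencies
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      score <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
               (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      ok <- !is.na(score)
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        dl <- (sx[i, ok] + sx[j, ok]) / 2 - score[ok] / 4
        d[i, j] <- d[j, i] <- mean(dl)
      }
    }
  }
  d
}

.check_distance <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm) || !isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (any(dm < -1e-12, na.rm = TRUE)) {
    stop("distance matrix has negative entries", call. = FALSE)
  }
  if (any(abs(diag(dm)) > 1e-12)) stop("distance diagonal must be zero", call. = FALSE)
  dm
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration of a distance matrix (via [ape::nj()]).
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' clamped to zero; the clamped total is recorded in the
#' `"negative_length_clamped"` attribute.
#'
#' @param dm Symmetric distance matrix (>= 3 labels) from e.g.
#'   [nei_minimum_distance()].
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- .check_distance(dm)
  if (anyNA(dm)) stop("distance matrix has undefined entries", call. = FALSE)
  if (nrow(dm) < 3) stop("neighbour joining needs at least 3 labels", call. = FALSE)
  tr <- ape::nj(stats::as.dist(dm))
  deficit <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_length_clamped") <- deficit
  tr
}

#' Locus-bootstrap support for a neighbour-joining tree
#'
#' Resamples loci with replacement, rebuilds the Nei-distance NJ tree for
#' each replicate, and annotates each internal edge of the point-estimate
#' tree with the percentage of replicates containing the same bipartition.
#'
#' @param gm A [geno_matrix()].
#' @param n_reps Number of bootstrap replicates (the conventional choice is
#'   1000).
#' @param seed Optional RNG seed for reproducible resampling.
#' @return The point-estimate `phylo` tree with `node.label` set to the
#'   support percentages (root label `NA`).
#' @export
bootstrap_support <- function(gm, n_reps = 1000, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (ncol(gm$a1) < 2) stop("bootstrap needs at least 2 loci", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  point <- neighbor_joining(nei_minimum_distance(gm))
  reps <- vector("list", n_reps)
  L <- ncol(gm$a1)
  for (b in seq_len(n_reps)) {
    keep <- sample.int(L, L, replace = TRUE)
    b1 <- gm$a1[, keep, drop = FALSE]
    b2 <- gm$a2[, keep, drop = FALSE]
    colnames(b1) <- colnames(b2) <- make.unique(colnames(b1))
    reps[[b]] <- neighbor_joining(nei_minimum_distance(geno_matrix(b1, b2)))
  }
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  support <- round(100 * counts / n_reps)
  point$node.label <- support
  point
}
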