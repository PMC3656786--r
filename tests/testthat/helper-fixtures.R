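# small genotype-matrix builders used across the suite

# build a geno_matrix from a list of individuals, each a list of length-2
# allele vectors (one per locus); NA = missing, 0 = null
gm_from_cells <- function(cells, ids = NULL, loci = NULL, pop = NULL) {
  n <- length(cells)
  L <- length(cells[[1]])
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      a1[i, j] <- cells[[i]][[j]][1]
      a2[i, j] <- cells[[i]][[j]][2]
    }
  }
  rownames(a1) <- if (is.null(ids)) paste0("i", seq_len(n)) else ids
  colnames(a1) <- if (is.null(loci)) paste0("L", seq_len(L)) else loci
  dimnames(a2) <- dimnames(a1)
  geno_matrix(a1, a2, pop = pop)
}

# single-locus matrix from genotype strings like "AA", "AB" (letters are
# mapped to allele sizes 100, 110, 120, ...)
gm_1locus <- function(genos, pop = NULL) {
  code <- function(ch) 100L + 10L * (utf8ToInt(ch) - utf8ToInt("A"))
  cells <- lapply(genos, function(g) {
    list(c(code(substr(g, 1, 1)), code(substr(g, 2, 2))))
  })
  gm_from_cells(cells, pop = pop)
}

# random valid genotype matrix (with missing, null alleles, populations)
random_gm <- function(n = 12, L = 6, seed = 1, pops = c("pop1", "pop2")) {
  set.seed(seed)
  sizes <- seq(100L, 140L, by = 2L)
  draw <- function() {
    if (runif(1) < 0.05) return(c(NA_integer_, NA_integer_))
    a <- c(sample(c(0L, sizes), 1, prob = c(0.08, rep(1, length(sizes)))),
           sample(c(0L, sizes), 1, prob = c(0.08, rep(1, length(sizes)))))
    sort(a)
  }
  cells <- lapply(seq_len(n), function(i) lapply(seq_len(L), function(j) draw()))
  gm_from_cells(cells, pop = sort(rep(pops, length.out = n)))
}

# exhaustive rarefaction oracle: expected allele count over all g-subsets
# of the sampled gene copies
rarefaction_oracle <- function(counts, g) {
  genes <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(genes), g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# exhaustive private-allele oracle: mean count of alleles present in pop
# j's subsample and absent from every other population's subsample,
# averaged over all combinations of independent g-subsets
private_oracle <- function(count_matrix, g) {
  npop <- nrow(count_matrix)
  genes <- lapply(seq_len(npop), function(i) {
    rep(seq_len(ncol(count_matrix)), count_matrix[i, ])
  })
  subsets <- lapply(genes, function(gn) utils::combn(length(gn), g, simplify = FALSE))
  grids <- do.call(expand.grid, lapply(subsets, seq_along))
  out <- numeric(npop)
  for (r in seq_len(nrow(grids))) {
    seen <- lapply(seq_len(npop), function(i) {
      unique(genes[[i]][subsets[[i]][[grids[r, i]]]])
    })
    for (j in seq_len(npop)) {
      others <- unlist(seen[-j])
      out[j] <- out[j] + length(setdiff(seen[[j]], others))
    }
  }
  out / nrow(grids)
}

# least-squares branch lengths of a fixed topology; returns list(tree, rss)
ls_fit_topology <- function(topo, dm) {
  labs <- rownames(dm)
  topo <- ape::unroot(topo)
  ne <- nrow(topo$edge)
  # indicator columns: distance contribution of each edge to each pair
  cols <- lapply(seq_len(ne), function(e) {
    t2 <- topo
    t2$edge.length <- replace(rep(0, ne), e, 1)
    as.vector(as.dist(ape::cophenetic.phylo(t2)[labs, labs]))
  })
  A <- do.call(cbind, cols)
  y <- as.vector(as.dist(dm))
  beta <- qr.solve(A, y)
  rss <- sum((A %*% beta - y)^2)
  t2 <- topo
  t2$edge.length <- as.vector(beta)
  list(tree = t2, rss = rss)
}

# all-topology least-squares oracle: best-fitting unrooted tree
nj_oracle <- function(dm) {
  labs <- rownames(dm)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  fits <- lapply(topos, ls_fit_topology, dm = dm)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# additive distance matrix from a tree
tree_dm <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

# direct 2x2 biallelic r^2 from two haplotype vectors
r2_biallelic_direct <- function(ha, hb) {
  ok <- !is.na(ha) & !is.na(hb)
  ha <- ha[ok]; hb <- hb[ok]
  ua <- sort(unique(ha)); ub <- sort(unique(hb))
  stopifnot(length(ua) == 2, length(ub) == 2)
  p <- mean(ha == ua[1]); q <- mean(hb == ub[1])
  p11 <- mean(ha == ua[1] & hb == ub[1])
  (p11 - p * q)^2 / (p * (1 - p) * q * (1 - q))
}
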