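test_that("PCoA embeds exact configurations", {
  # points on a line: axis 1 recovers spacing, axis 2 share ~ 0
  x <- c(0, 1, 3, 6)
  d <- as.matrix(stats::dist(x))
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  pc <- pcoa(d, n_axes = 2)
  got <- pc$coords$axis_1
  expect_equal(as.matrix(stats::dist(got)), as.matrix(stats::dist(x)),
               ignore_attr = TRUE, tolerance = 1e-9)
  sh2 <- pc$eig$pct_variation[2]
  expect_true(is.na(sh2) || sh2 < 1e-6)  # degenerate second axis
  # distances from 2-D coordinates: first two shares sum to 100
  set.seed(40)
  xy <- matrix(rnorm(16), 8, 2)
  d2 <- as.matrix(stats::dist(xy))
  pc2 <- pcoa(d2, n_axes = 3)
  expect_equal(sum(pc2$eig$pct_variation[1:2]), 100, tolerance = 1e-8)
  # Euclidean-embeddable matrix: no meaningful negative eigenvalues
  J <- diag(8) - matrix(1 / 8, 8, 8)
  B <- -0.5 * J %*% d2^2 %*% J
  expect_true(all(eigen(B, symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  # two tight clusters separate on axis 1
  cl <- rbind(matrix(rnorm(10, 0, 0.05), 5), matrix(rnorm(10, 5, 0.05), 5))
  d3 <- as.matrix(stats::dist(cl))
  dimnames(d3) <- list(paste0("i", 1:10), paste0("i", 1:10))
  pc3 <- pcoa(d3)
  expect_gt(abs(mean(pc3$coords$axis_1[1:5]) - mean(pc3$coords$axis_1[6:10])), 3)
  # degenerate all-zero matrix
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pcz <- pcoa(z)
  expect_true(all(pcz$coords$axis_1 == 0))
  expect_true(all(is.na(pcz$eig$pct_variation)))
  # agreement with the standard Gower implementation
  ref <- ape::pcoa(stats::as.dist(d2))
  expect_equal(abs(pc2$coords$axis_1), unname(abs(ref$vectors[, 1])),
               tolerance = 1e-8)
})

test_that("admixture sampler honours its contracts", {
  # two populations fixed for disjoint alleles at 50 loci
  n_per <- 8
  a <- matrix(100L, n_per, 50); b <- matrix(200L, n_per, 50)
  m <- rbind(a, b)
  rownames(m) <- paste0("i", seq_len(2 * n_per))
  colnames(m) <- paste0("L", 1:50)
  gm <- geno_matrix(m, m)
  q <- admixture_gibbs(gm, K = 2, burn_in = 300, iters = 600, seed = 3)
  expect_true(all(abs(rowSums(q$Q) - 1) < 1e-6))
  cl <- assign_groups(q, threshold = 0.7)
  expect_equal(length(unique(cl$group[1:n_per])), 1)
  expect_equal(length(unique(cl$group[(n_per + 1):(2 * n_per)])), 1)
  expect_false(cl$group[1] == cl$group[n_per + 1])
  # K = 1 gives exact unit memberships
  q1 <- admixture_gibbs(gm, K = 1, burn_in = 50, iters = 100, seed = 1)
  expect_true(all(q1$Q == 1))
  # fixed seed -> bit-identical posterior means
  qa <- admixture_gibbs(gm, K = 2, burn_in = 100, iters = 150, seed = 11)
  qb <- admixture_gibbs(gm, K = 2, burn_in = 100, iters = 150, seed = 11)
  expect_identical(qa$Q, qb$Q)
  expect_identical(qa$ln_pd, qb$ln_pd)
  expect_error(admixture_gibbs(gm, K = 40), "exceeds")
})

test_that("posterior-mean Q entropy shrinks as loci grow on separable data", {
  ent <- vapply(c(10, 50, 200), function(L) {
    m <- rbind(matrix(100L, 6, L), matrix(200L, 6, L))
    rownames(m) <- paste0("i", 1:12); colnames(m) <- paste0("L", seq_len(L))
    gm <- geno_matrix(m, m)
    q <- admixture_gibbs(gm, K = 2, burn_in = 200, iters = 300, seed = 7)
    p <- pmin(pmax(q$Q, 1e-12), 1)
    mean(-rowSums(p * log(p)))
  }, numeric(1))
  expect_true(all(diff(ent) <= 1e-3))
  expect_lt(ent[3], 0.05)
})

test_that("Evanno delta-K reproduces hand-computed values", {
  runs <- tibble::tibble(K = rep(1:4, each = 2),
                         ln_pd = c(-1000, -1000, -500, -500, -490, -490,
                                   -480, -480) + rep(c(-0.5, 0.5), 4))
  ev <- evanno_delta_k(runs)
  # sd of each pair is sqrt(0.5); delta_k(2) = |10 - 500| / sd
  expect_equal(ev$delta_k[ev$K == 2], 490 / sqrt(0.5))
  expect_equal(ev$l_prime[ev$K == 2], 500)
  expect_equal(ev$l_double[ev$K == 2], 490)
  expect_true(is.na(ev$delta_k[ev$K == 1]) && is.na(ev$delta_k[ev$K == 4]))
  # perfectly linear lnP(D): delta_k = 0 at interior K
  lin <- tibble::tibble(K = rep(1:4, each = 2),
                        ln_pd = rep(c(-40, -30, -20, -10), each = 2) +
                          rep(c(-1, 1), 4))
  evl <- evanno_delta_k(lin)
  expect_true(all(evl$delta_k[2:3] == 0))
  # invariant to adding a constant
  shift <- runs; shift$ln_pd <- shift$ln_pd + 500
  expect_equal(evanno_delta_k(shift)$delta_k, ev$delta_k)
  # zero replicate sd flags undefined
  flat <- tibble::tibble(K = rep(1:3, each = 2), ln_pd = rep(c(-3, -2, -1), each = 2))
  expect_true(all(is.na(evanno_delta_k(flat)$delta_k)))
  expect_error(evanno_delta_k(runs[runs$K < 3, ]), ">= 3")
})

test_that("delta-K recovers the true cluster number on structured data", {
  hits <- vapply(1:6, function(s) {
    m <- rbind(matrix(100L, 8, 25), matrix(200L, 8, 25))
    set.seed(s)
    # mild within-group noise so K > 2 does not fit better
    noise <- matrix(sample(c(0L, 2L, 4L), length(m), TRUE), nrow(m))
    m <- m + noise
    rownames(m) <- paste0("i", 1:16); colnames(m) <- paste0("L", 1:25)
    gm <- geno_matrix(m, m)
    sc <- structure_scan(gm, k_range = 1:4, n_reps = 2, burn_in = 150,
                         iters = 300, seed = 100 * s)
    ev <- evanno_delta_k(sc)
    ev$K[which.max(ev$delta_k)] == 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("Q-threshold assignment follows the 0.70 rule", {
  Q <- rbind(c(0.71, 0.29), c(0.5, 0.5), c(0.2, 0.8))
  rownames(Q) <- paste0("i", 1:3)
  a <- assign_groups(Q, threshold = 0.70)
  expect_equal(a$group, c("cluster_1", "admixed", "cluster_2"))
  expect_equal(assign_groups(Q, threshold = 0)$group,
               c("cluster_1", "cluster_1", "cluster_2"))
})

test_that("pairwise FST estimators behave at fixation and under the null", {
  # fixed for different alleles: theta = 1, minimal permutation p
  gm <- gm_from_cells(c(
    lapply(1:6, function(i) list(c(100L, 100L), c(140L, 140L))),
    lapply(1:6, function(i) list(c(120L, 120L), c(160L, 160L)))
  ), pop = rep(c("A", "B"), each = 6))
  fst <- pairwise_fst(gm, n_perm = 99, seed = 1)
  expect_equal(fst$theta, 1)
  expect_equal(fst$gst, 1)
  expect_equal(fst$p, 1 / 100)
  # random split of one population: theta near 0, p not small
  gm2 <- random_gm(n = 24, L = 10, seed = 61, pops = "one")
  lab <- setNames(rep(c("x", "y"), 12), individuals(gm2))
  fst2 <- pairwise_fst(gm2, lab, n_perm = 99, seed = 2)
  expect_lt(abs(fst2$theta), 0.08)
  expect_gt(fst2$p, 0.05)
  # theta and gst deviate from 0 in the same direction on structured data
  res <- sim_flaxlike(seed = 71, n_loci = 20, sample_sizes = 15)
  grp <- setNames(res$grouping$group, res$grouping$individual)
  fst3 <- pairwise_fst(res$genotypes, grp, n_perm = 0)
  expect_gt(fst3$theta, 0)
  expect_gt(fst3$gst, 0)
})

test_that("island simulation at target FST 0.10 is recovered by theta", {
  # two demes exchanging migrants; realized differentiation tracked by the
  # generator's own G_ST bookkeeping
  res <- simulate_ssr(sim_config(seed = 81, n_demes = 2, deme_size = 100,
                                 migration_rate = 0.022, selfing_rate = 0,
                                 n_generations = 120, n_loci = 100,
                                 founder_k = 6, mutation_rate = 1e-3,
                                 sample_sizes = 50))
  grp <- setNames(res$genotypes$pop, individuals(res$genotypes))
  est <- wc_fst(res$genotypes, grp)
  per <- est$per_locus$theta[!is.na(est$per_locus$theta)]
  se <- stats::sd(per) / sqrt(length(per))
  realized <- utils::tail(res$truth$fst_trajectory$gst, 1)
  expect_lt(abs(est$theta - realized), 3 * se + 0.02)
  expect_lt(abs(est$theta - 0.10), 0.06)
})
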