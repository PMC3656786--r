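# two-locus matrix from homozygous haplotype pairs (selfing-line style)
gm_haplo <- function(ha, hb) {
  cells <- lapply(seq_along(ha), function(i) {
    list(c(ha[i], ha[i]), c(hb[i], hb[i]))
  })
  gm_from_cells(cells, loci = c("La", "Lb"))
}

test_that("pair r2 hits the classical anchors", {
  # complete association, 50/50 haplotypes -> 1
  gm <- gm_haplo(rep(c(100L, 120L), each = 6), rep(c(200L, 220L), each = 6))
  expect_equal(pair_r2(gm, "La", "Lb")$r2, 1)
  # perfectly balanced independent counts -> 0
  gm0 <- gm_haplo(rep(c(100L, 100L, 120L, 120L), 3),
                  rep(c(200L, 220L, 200L, 220L), 3))
  expect_equal(pair_r2(gm0, "La", "Lb")$r2, 0)
  # heterozygotes and missing are excluded
  gmh <- gm_haplo(rep(c(100L, 120L), each = 4), rep(c(200L, 220L), each = 4))
  gmh$a2[1, 1] <- 150L  # heterozygote at La
  expect_equal(pair_r2(gmh, "La", "Lb")$n, 7)
  # monomorphic retained set is flagged
  gmm <- gm_haplo(rep(100L, 6), rep(c(200L, 220L), 3))
  expect_true(is.na(pair_r2(gmm, "La", "Lb")$r2))
})

test_that("3x2 toy table equals the brute-force weighted-average formula", {
  # counts {(A,x):4, (B,y):4, (C,x):2, (C,y):2}
  ha <- rep(c(100L, 110L, 120L, 120L), c(4, 4, 2, 2))
  hb <- rep(c(200L, 210L, 200L, 210L), c(4, 4, 2, 2))
  gm <- gm_haplo(ha, hb)
  got <- pair_r2(gm, "La", "Lb")$r2
  # direct evaluation: sum_ij p_i q_j D_ij^2 / (p_i(1-p_i) q_j(1-q_j))
  tab <- table(ha, hb) / 12
  p <- rowSums(tab); q <- colSums(tab)
  manual <- 0
  for (i in 1:3) for (j in 1:2) {
    D <- tab[i, j] - p[i] * q[j]
    manual <- manual + p[i] * q[j] * D^2 / (p[i] * (1 - p[i]) * q[j] * (1 - q[j]))
  }
  expect_equal(got, unname(manual), tolerance = 1e-12)
})

test_that("multiallelic r2 reduces to the direct 2x2 formula when biallelic", {
  set.seed(20)
  for (rep in 1:100) {
    ha <- sample(c(100L, 120L), 30, TRUE)
    hb <- sample(c(200L, 220L), 30, TRUE)
    if (length(unique(ha)) < 2 || length(unique(hb)) < 2) next
    gm <- gm_haplo(ha, hb)
    expect_equal(pair_r2(gm, "La", "Lb", p_value = FALSE)$r2,
                 r2_biallelic_direct(ha, hb), tolerance = 1e-9)
  }
})

test_that("r2 is symmetric in locus order and invariant to relabeling", {
  set.seed(21)
  ha <- sample(c(100L, 110L, 120L), 40, TRUE)
  hb <- sample(c(200L, 210L), 40, TRUE)
  gm <- gm_haplo(ha, hb)
  expect_equal(pair_r2(gm, "La", "Lb", p_value = FALSE)$r2,
               pair_r2(gm, "Lb", "La", p_value = FALSE)$r2)
  relab <- c("100" = 500L, "110" = 700L, "120" = 900L)
  gm2 <- gm_haplo(unname(relab[as.character(ha)]), hb)
  expect_equal(pair_r2(gm, "La", "Lb", p_value = FALSE)$r2,
               pair_r2(gm2, "La", "Lb", p_value = FALSE)$r2)
})

test_that("pairs classify by shared linkage group with cM distances", {
  map <- tibble::tibble(marker = c("m1", "m2", "m3", "m4"),
                        linkage_group = c("LG1", "LG1", "LG2", "LG2"),
                        cM = c(3.2, 7.7, 1.0, 50.0))
  cp <- classify_pairs(map, map$marker)
  expect_equal(nrow(cp), choose(4, 2))
  row <- cp[cp$locus_a == "m1" & cp$locus_b == "m2", ]
  expect_true(row$linked)
  expect_equal(row$dist_cM, 4.5)
  expect_false(cp$linked[cp$locus_a == "m1" & cp$locus_b == "m3"])
  # pair counts with unmapped loci excluded
  cp2 <- classify_pairs(map, c(map$marker, "unmapped"))
  expect_equal(nrow(cp2), choose(4, 2))
})

test_that("LD summary reports means, percentile and significant share", {
  ldt <- tibble::tibble(locus_a = letters[1:10], locus_b = LETTERS[1:10],
                        r2 = rep(0.3, 10), n = 20, p = rep(c(0.01, 0.5), 5),
                        linked = rep(c(TRUE, FALSE), 5),
                        dist_cM = rep(c(1, NA), 5))
  s <- ld_summary(ldt)
  expect_equal(s$mean_r2_linked, 0.3)
  expect_equal(s$mean_r2_unlinked, 0.3)
  expect_equal(s$p95_unlinked, 0.3)
  expect_equal(s$pct_significant, 50)
  expect_true(s$percentile_unstable)
  # percentile agrees with the analytic quantile of a known Beta sample
  set.seed(30)
  x <- stats::rbeta(4000, 1, 20)
  ldt2 <- tibble::tibble(locus_a = "x", locus_b = "y", r2 = x, n = 50,
                         p = 0.5, linked = FALSE, dist_cM = NA_real_)
  s2 <- ld_summary(ldt2)
  # within ~3 SE of the analytic quantile for this sample size
  expect_lt(abs(s2$p95_unlinked - stats::qbeta(0.95, 1, 20)), 0.01)
})

test_that("decay fit recovers rho exactly on noiseless Hill-Weir data", {
  n <- 100
  rho <- 2
  d <- seq(0.05, 20, length.out = 60)
  er2 <- ssrpopkit:::.hill_weir_er2(rho * d, n)
  ldt <- tibble::tibble(locus_a = "a", locus_b = "b", r2 = er2, n = n,
                        p = NA_real_, linked = TRUE, dist_cM = d)
  fit <- fit_decay(ldt, n_individuals = n, threshold = 0.1)
  expect_equal(fit$rho, rho, tolerance = 1e-6)
  # crossing distance agrees with an independent bisection oracle
  f <- function(x) ssrpopkit:::.hill_weir_er2(rho * x, n) - 0.1
  lo <- 0; hi <- 50
  for (i in 1:60) { mid <- (lo + hi) / 2; if (f(mid) > 0) lo <- mid else hi <- mid }
  expect_equal(fit$distance_at_threshold, (lo + hi) / 2, tolerance = 1e-6)
  # fitted curve strictly decreasing
  grid <- ssrpopkit:::.hill_weir_er2(fit$rho * seq(0, 30, 0.1), n)
  expect_true(all(diff(grid) < 0))
  # threshold at the curve's starting value -> distance 0
  thr0 <- ssrpopkit:::.hill_weir_er2(0, n)
  fit0 <- fit_decay(ldt, n_individuals = n, threshold = thr0 + 1e-6)
  expect_equal(fit0$distance_at_threshold, 0)
})

test_that("non-decaying input is flagged as a poor fit", {
  set.seed(31)
  ldt <- tibble::tibble(locus_a = "a", locus_b = "b",
                        r2 = 0.5 + seq(0, 0.01, length.out = 12), n = 50,
                        p = NA_real_, linked = TRUE,
                        dist_cM = seq(1, 12))
  expect_warning(fit <- fit_decay(ldt, n_individuals = 50), "unreliable")
  expect_true(fit$poor_fit)
  expect_error(fit_decay(ldt[1:5, ], 50), "at least 10")
})

test_that("map-structured simulation shows linked exceeding unlinked LD", {
  res <- simulate_ssr(sim_config(seed = 55, n_demes = 1, deme_size = 80,
                                 selfing_rate = 0.95, n_generations = 40,
                                 n_loci = 24, n_linkage_groups = 3,
                                 founder_k = 3, mutation_rate = 1e-4))
  ldt <- ld_table(res$genotypes, res$map, maf_min = 0.05, p_value = FALSE)
  # use close pairs (< 20 cM) as the linked signal
  close <- ldt[ldt$linked & !is.na(ldt$r2) & ldt$dist_cM < 20, ]
  unl <- ldt[!ldt$linked & !is.na(ldt$r2), ]
  expect_gt(mean(close$r2), mean(unl$r2))
})

test_that("thinning leaves no retained pair above the r2 ceiling", {
  res <- simulate_ssr(sim_config(seed = 56, n_demes = 1, deme_size = 60,
                                 selfing_rate = 0.95, n_generations = 30,
                                 n_loci = 20, n_linkage_groups = 2,
                                 founder_k = 4))
  gm <- res$genotypes
  # add a duplicated locus to force r2 = 1
  b1 <- cbind(gm$a1, dup = gm$a1[, 1])
  b2 <- cbind(gm$a2, dup = gm$a2[, 1])
  colnames(b1)[ncol(b1)] <- colnames(b2)[ncol(b2)] <- "Ldup"
  gm2 <- geno_matrix(b1, b2)
  map2 <- rbind(res$map,
                tibble::tibble(marker = "Ldup",
                               linkage_group = res$map$linkage_group[1],
                               cM = res$map$cM[1] + 0.01))
  kept <- thin_by_ld(gm2, map2, r2_max = 0.4, maf_min = 0.05)
  expect_false(all(c(res$map$marker[1], "Ldup") %in% kept))
  ldt <- ld_table(gm2[, kept], map2, p_value = FALSE)
  expect_true(all(ldt$r2[ldt$linked] <= 0.4 + 1e-12, na.rm = TRUE))
  # with a high ceiling everything passing MAF is retained
  pooled <- setNames(rep("all", nrow(gm2$a1)), individuals(gm2))
  pass <- minor_allele_frequency(allele_frequencies(gm2, pooled))
  pass <- pass$locus[pass$maf >= 0.05]
  kept_all <- thin_by_ld(gm2, map2, r2_max = 1, maf_min = 0.05)
  expect_setequal(kept_all, pass)
})
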