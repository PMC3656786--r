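test_that("balanced subset selection minimises distance to the mean count", {
  gm <- sim_flaxlike(seed = 91, n_loci = 12)$genotypes
  pool <- individuals(gm)[1:30]
  # size = pool returns the pool itself
  expect_identical(as.character(select_balanced_subset(gm, pool, length(pool))),
                   pool)
  sel <- select_balanced_subset(gm, pool, 10, n_candidate_sets = 40, seed = 2)
  counts <- attr(sel, "candidate_counts")
  target <- attr(sel, "target_mean")
  # re-enumeration: the chosen set's count is the closest to the mean
  count_alleles <- function(ind) {
    sub <- gm[ind, ]
    sum(vapply(seq_len(ncol(sub$a1)), function(j) {
      length(unique(na.omit(c(sub$a1[, j], sub$a2[, j]))))
    }, integer(1)))
  }
  expect_equal(count_alleles(as.character(sel)),
               counts[which.min(abs(counts - target))])
  expect_true(all(abs(counts - target) >=
                    abs(count_alleles(as.character(sel)) - target) - 1e-9))
  # identical genotypes: every subset equivalent, first candidate returned
  b <- matrix(100L, 10, 3, dimnames = list(paste0("i", 1:10), paste0("L", 1:3)))
  gmi <- geno_matrix(b, b)
  s2 <- select_balanced_subset(gmi, individuals(gmi), 4, n_candidate_sets = 10,
                               seed = 3)
  expect_equal(attr(s2, "chosen_index"), 1L)
  expect_error(select_balanced_subset(gm, pool, 50), "exceeds")
})

test_that("Ewens-Watterson boundary configurations behave as expected", {
  # all alleles distinct (k = n): observed F at its conditional minimum
  e <- ew_test(rep(1, 8), n_sim = 400, seed = 1)
  expect_equal(e$f_obs, 8 * (1 / 8)^2)
  expect_false(e$significant)
  # k = 2 with counts (n-1, 1): F at the conditional maximum
  e2 <- ew_test(c(19, 1), n_sim = 400, seed = 2)
  expect_gte(e2$f_obs, max(1 - e2$f_obs, 0))  # can't exceed the (n-1,1) config
  expect_true(e2$p <= 1)
  # monomorphic locus is inapplicable, neutral by default
  e3 <- ew_test(10)
  expect_false(e3$applicable)
  expect_false(e3$significant)
  # determinism
  ea <- ew_test(c(5, 3, 2), n_sim = 300, seed = 7)
  eb <- ew_test(c(5, 3, 2), n_sim = 300, seed = 7)
  expect_identical(ea, eb)
})

test_that("EW flag rate on neutral Ewens configurations stays below 5%", {
  set.seed(5)
  n <- 60
  # neutral configurations drawn from the unconditional Ewens urn
  draw_config <- function(theta = 3) {
    counts <- integer(0)
    for (i in 0:(n - 1)) {
      if (runif(1) < theta / (theta + i) || i == 0) {
        counts <- c(counts, 1L)
      } else {
        j <- sample.int(length(counts), 1, prob = counts)
        counts[j] <- counts[j] + 1L
      }
    }
    counts
  }
  cache <- new.env(parent = emptyenv())
  flags <- vapply(1:150, function(i) {
    ew_test(draw_config(), n_sim = 400, cache = cache)$significant
  }, logical(1))
  expect_lte(mean(flags), 0.05)
})

test_that("ln RH anchors, exclusions and degenerate spread", {
  he_a <- c(0.5, runif(20, 0.3, 0.7))
  he_b <- c(0.5, runif(20, 0.3, 0.7))
  r <- lnrh_test(he_a, he_b)
  expect_equal(r$ln_rh[1], 0)  # equal diversity -> lnRH = 0
  # monomorphic / He = 1 loci are excluded with a warning
  expect_warning(r2 <- lnrh_test(c(he_a, 0), c(he_b, 0.5)), "excluded")
  expect_false(r2$usable[length(he_a) + 1])
  # identical lnRH everywhere: zero sd flagged undefined
  expect_warning(r3 <- lnrh_test(rep(0.5, 12), rep(0.3, 12)), "zero spread")
  expect_true(all(is.na(r3$z)))
  expect_error(lnrh_test(c(0.5, 0.4), c(0.5, 0.4)), "at least 10")
})

test_that("consensus outlier call is a pure >= 2-of-4 rule", {
  flags <- rbind(c(TRUE, TRUE, FALSE, FALSE),
                 c(TRUE, FALSE, FALSE, FALSE),
                 c(FALSE, FALSE, FALSE, FALSE),
                 c(TRUE, TRUE, TRUE, TRUE),
                 c(FALSE, NA, TRUE, TRUE))
  colnames(flags) <- c("ew_sig", "lnrh_sig", "fdist_sig", "hier_sig")
  expect_equal(consensus_outliers(as.data.frame(flags)),
               c(TRUE, FALSE, FALSE, TRUE, TRUE))
})

test_that("FDIST recentering converges and zero-FST loci are never flagged", {
  res <- sim_flaxlike(seed = 101, n_loci = 30, sample_sizes = 15)
  grp <- split(res$grouping$individual, res$grouping$group)
  pair <- group_pair(grp$G1, grp$G2)
  fd <- fdist_scan(res$genotypes, pair, n_sim = 800, seed = 3)
  expect_lte(abs(attr(fd, "achieved_fst") - attr(fd, "target_fst")), 0.01)
  expect_false(any(fd$flagged[!is.na(fd$fst) & fd$fst <= 0], na.rm = TRUE))
  expect_true(all(fd$quantile >= 0 & fd$quantile <= 1, na.rm = TRUE))
})

test_that("a planted sweep dominates the FDIST conditional quantiles", {
  sweeps <- tibble::tibble(locus = c(5L, 12L), group = 1L,
                           start_gen = 40L, s = 3)
  res <- sim_flaxlike(seed = 103, n_loci = 40, sample_sizes = 20,
                      sweeps = sweeps, n_generations = 120)
  # the sweep fixed in the target group
  expect_gt(mean(res$truth$sweep_status$final_freq_target), 0.8)
  grp <- split(res$grouping$individual, res$grouping$group)
  pair <- group_pair(grp$G1, grp$G2)
  fd <- fdist_scan(res$genotypes, pair, n_sim = 1200, seed = 4)
  sweep_loci <- res$truth$sweep_status$locus_name
  top <- fd$locus[order(-fd$quantile)][1:6]
  expect_true(any(sweep_loci %in% top))
})

test_that("the hierarchical null reduces to the island null at ratio 1", {
  res <- sim_flaxlike(seed = 105, n_loci = 25, sample_sizes = 15)
  grp <- split(res$grouping$individual, res$grouping$group)
  pair <- group_pair(grp$G1, grp$G2)
  hi1 <- hierarchical_scan(res$genotypes, pair, k_within = 2, ratio = 1,
                           n_sim = 800, seed = 11)
  fd <- fdist_scan(res$genotypes, pair, demes = 4, n_sim = 800, seed = 11)
  ok <- !is.na(hi1$quantile) & !is.na(fd$quantile)
  # same machinery, matched deme count: quantiles agree to Monte-Carlo error
  expect_lt(mean(abs(hi1$quantile[ok] - fd$quantile[ok])), 0.12)
})

test_that("candidate windows reproduce the published arithmetic", {
  map <- tibble::tibble(marker = c("out", "nb", "far"),
                        linkage_group = c("LG4", "LG4", "LG9"),
                        cM = c(10.0, 11.3, 50))
  scaf <- tibble::tibble(marker = c("out", "nb", "far"),
                         scaffold = c("s98", "s98", "s12"),
                         bp = c(1e6, 1e6 + 364 * 1.3 * 1000, 5e5))
  # strong LD on a shared scaffold: ratio x genetic span ~ 474 kb
  w <- candidate_window("out", "nb", r2 = 1, map, scaf)
  expect_equal(w$ratio_kb_per_cm, 364, tolerance = 1e-6)
  expect_lt(abs(w$window_kb - 474), 1)
  expect_equal(w$method, "ratio_x_span")
  # different scaffolds with weak LD: +/-10 kb fallback = 20 kb
  w2 <- candidate_window("out", "far", r2 = 0.05, map, scaf)
  expect_equal(w2$window_kb, 20)
  # moderate LD: ratio x decay span (178 kb/cM x 0.2 cM ~ 36 kb)
  scaf3 <- scaf
  scaf3$bp[2] <- scaf3$bp[1] + 178 * 1.3 * 1000
  w3 <- candidate_window("out", "nb", r2 = 0.22, map, scaf3, decay_cm = 0.2)
  expect_lt(abs(w3$window_kb - 178 * 0.2), 1)
  expect_error(candidate_window("out", "nb", r2 = 0.3, map, scaf3), "decay_cm")
  # zero genetic span on a shared scaffold falls back with a warning
  map0 <- map; map0$cM[2] <- map0$cM[1]
  expect_warning(w4 <- candidate_window("out", "nb", 0.9, map0, scaf), "10 kb")
  expect_equal(w4$window_kb, 20)
  expect_error(candidate_window("oops", "nb", 1, map, scaf), "missing from")
})

test_that("the full scan produces a coherent outlier report", {
  sweeps <- tibble::tibble(locus = 3L, group = 1L, start_gen = 40L, s = 3)
  res <- sim_flaxlike(seed = 107, n_loci = 25, sample_sizes = 15,
                      sweeps = sweeps)
  grp <- split(res$grouping$individual, res$grouping$group)
  pair <- group_pair(grp$G1, grp$G2)
  rep <- suppressWarnings(
    scan_outliers(res$genotypes, pair, map = res$map, n_sim_fdist = 800,
                  n_sim_ew = 300, seed = 5))
  expect_equal(nrow(rep), 25)
  expect_true(all(rep$outlier == (rep$n_sig >= 2)))
  expect_true("linkage_group" %in% names(rep))
  # determinism of the whole report
  rep2 <- suppressWarnings(
    scan_outliers(res$genotypes, pair, map = res$map, n_sim_fdist = 800,
                  n_sim_ew = 300, seed = 5))
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
})
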