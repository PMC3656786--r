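test_that("constructor canonicalises cells and rejects invalid input", {
  gm <- gm_from_cells(list(list(c(120L, 100L), c(0L, 140L)),
                           list(c(NA, NA), c(100L, 100L))))
  # unordered heterozygote stored sorted ascending; null (0) sorts first
  expect_equal(unname(gm$a1[1, ]), c(100L, 0L))
  expect_equal(unname(gm$a2[1, ]), c(120L, 140L))
  expect_error(
    gm_from_cells(list(list(c(100L, NA)))),
    "half-missing"
  )
  expect_error(
    geno_matrix(matrix(1L, 2, 1, dimnames = list(c("a", "a"), "L")),
                matrix(1L, 2, 1)),
    "unique"
  )
  expect_error(gm_from_cells(list(list(c(-5L, 100L)))), ">= 0")
})

test_that("paper encodings parse per dialect: 0000, 999/999, -9, ?", {
  td <- withr::local_tempdir()
  # Genepop: "0000" -> both slots missing, 9999 (2-digit null code) -> nulls
  gen <- c("title", "L1", "L2", "Pop",
           "ind1 , 0102 0000",
           "ind2 , 9999 0101")
  pg <- file.path(td, "t.gen")
  writeLines(gen, pg)
  gm <- read_genotypes(pg, "genepop")
  expect_true(all(is.na(gm$a1["ind1", "L2"]), is.na(gm$a2["ind1", "L2"])))
  expect_equal(unname(c(gm$a1["ind2", "L1"], gm$a2["ind2", "L1"])), c(0L, 0L))
  expect_equal(unname(c(gm$a1["ind1", "L1"], gm$a2["ind1", "L1"])), c(1L, 2L))

  # CSV: 999 -> null, ? -> missing
  pc <- file.path(td, "t.csv")
  writeLines(c("id,population,L1,L2",
               "ind1,p1,999/999,?/?",
               "ind2,p1,100/120,140/140"), pc)
  gmc <- read_genotypes(pc, "csv")
  expect_equal(unname(c(gmc$a1["ind1", "L1"], gmc$a2["ind1", "L1"])), c(0L, 0L))
  expect_true(is.na(gmc$a1["ind1", "L2"]))

  # STRUCTURE: -9 -> missing
  ps <- file.path(td, "t.str")
  writeLines(c("L1 L2",
               "ind1 p1 100 -9",
               "ind1 p1 120 -9"), ps)
  gms <- read_genotypes(ps, "structure")
  expect_true(is.na(gms$a1["ind1", "L2"]))
  expect_equal(unname(gms$a2["ind1", "L1"]), 120L)
})

test_that("malformed lines raise parse errors naming the line", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.csv")
  writeLines(c("id,L1", "ind1,100/120/140"), p)
  expect_error(read_genotypes(p, "csv"), ":2")
  writeLines(c("id,L1,L2", "ind1,100/100"), p)
  expect_error(read_genotypes(p, "csv"), ":2")
})

test_that("write/read round-trips are the identity in all three dialects", {
  for (seed in 1:3) {
    gm <- random_gm(n = 10, L = 5, seed = seed)
    td <- withr::local_tempdir()
    for (fmt in c("csv", "genepop", "structure")) {
      p <- file.path(td, paste0("m", seed, ".", fmt))
      write_genotypes(gm, p, fmt)
      expect_true(isTRUE(all.equal(gm, read_genotypes(p, fmt))),
                  info = paste(fmt, "seed", seed))
    }
    # dialect cross-consistency
    gm_csv <- read_genotypes(file.path(td, paste0("m", seed, ".csv")), "csv")
    gm_gen <- read_genotypes(file.path(td, paste0("m", seed, ".genepop")),
                             "genepop")
    expect_true(isTRUE(all.equal(gm_csv, gm_gen)))
  }
})

test_that("genepop writer encodes sizes as codes with a sidecar table", {
  gm <- gm_from_cells(list(list(c(100L, 200L)), list(c(200L, 200L))),
                      ids = c("a", "b"), loci = "Lx")
  td <- withr::local_tempdir()
  p <- file.path(td, "x.gen")
  write_genotypes(gm, p, "genepop")
  lines <- readLines(p)
  expect_true(any(grepl("0102", lines)))  # 100/200 -> codes 01/02
  side <- read.delim(paste0(p, ".alleles.tsv"))
  expect_equal(side$allele[side$code == 1], 100L)
  expect_equal(side$allele[side$code == 2], 200L)
  # missing cell -> STRUCTURE -9 -9
  gm2 <- gm_from_cells(list(list(c(NA, NA))), ids = "a", loci = "Lx")
  ps <- file.path(td, "x.str")
  write_genotypes(gm2, ps, "structure")
  expect_true(all(grepl("-9", readLines(ps)[-1])))
})

test_that("empty matrix round-trips as a header-only file", {
  a <- matrix(integer(), 0, 2, dimnames = list(character(), c("L1", "L2")))
  gm <- geno_matrix(a, a)
  td <- withr::local_tempdir()
  for (fmt in c("csv", "genepop", "structure")) {
    p <- file.path(td, paste0("e.", fmt))
    write_genotypes(gm, p, fmt)
    back <- read_genotypes(p, fmt)
    expect_equal(dim(back), c(0L, 2L))
    expect_equal(loci(back), c("L1", "L2"))
  }
})

test_that("allele frequencies count null as an allele and flag empty cells", {
  # genotypes AA, AB, BB, BB -> p(A) = 3/8, p(B) = 5/8
  gm <- gm_1locus(c("AA", "AB", "BB", "BB"))
  f <- allele_frequencies(gm)
  expect_equal(f$freq[f$allele == 100], 3 / 8)
  expect_equal(f$freq[f$allele == 110], 5 / 8)
  expect_equal(unique(f$n_genes), 8L)

  # null homozygote contributes two null copies
  gmn <- gm_from_cells(list(list(c(0L, 0L)), list(c(100L, 100L))))
  fn <- allele_frequencies(gmn)
  expect_equal(fn$freq[fn$allele == 0], 0.5)

  # an all-missing locus is flagged, not an error
  gmm <- gm_from_cells(list(list(c(NA, NA), c(100L, 100L))))
  fm <- allele_frequencies(gmm)
  expect_false(fm$defined[fm$locus == "L1"])
  expect_equal(fm$n_genes[fm$locus == "L1"], 0L)

  # frequencies sum to 1 at every defined (population, locus)
  gmr <- random_gm(n = 15, L = 6, seed = 4)
  sums <- allele_frequencies(gmr) |>
    dplyr::filter(defined) |>
    dplyr::group_by(population, locus) |>
    dplyr::summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("estimated frequencies match generating frequencies at n = 500", {
  set.seed(11)
  p_true <- c(0.5, 0.3, 0.15, 0.05)
  sizes <- c(100L, 110L, 120L, 130L)
  n <- 500
  a1 <- matrix(sample(sizes, n, TRUE, p_true), n, 1)
  a2 <- matrix(sample(sizes, n, TRUE, p_true), n, 1)
  rownames(a1) <- paste0("i", 1:n); colnames(a1) <- "L1"
  dimnames(a2) <- dimnames(a1)
  f <- allele_frequencies(geno_matrix(a1, a2))
  for (i in seq_along(sizes)) {
    se <- sqrt(p_true[i] * (1 - p_true[i]) / (2 * n))
    expect_lt(abs(f$freq[f$allele == sizes[i]] - p_true[i]), 3 * se)
  }
})

test_that("minor allele frequency handles monomorphic and multiallelic loci", {
  gm <- gm_1locus(c("AA", "AA", "AA", "AA", "AA", "AB", "AB", "AB", "AB", "AB"))
  f <- allele_frequencies(gm)
  expect_equal(minor_allele_frequency(f)$maf, 0.25)
  gm_mono <- gm_1locus(c("AA", "AA"))
  expect_equal(minor_allele_frequency(allele_frequencies(gm_mono))$maf, 0)
  # p = (0.5, 0.3, 0.2) -> 0.2
  gm3 <- gm_1locus(c("AA", "AA", "AA", "AA", "AA", "BB", "BB", "BB", "CC", "CC"))
  expect_equal(minor_allele_frequency(allele_frequencies(gm3))$maf, 0.2)
  # undefined frequencies raise
  gmm <- gm_from_cells(list(list(c(NA, NA))))
  expect_error(minor_allele_frequency(allele_frequencies(gmm)), "undefined")
})
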