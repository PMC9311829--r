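test_that("heterozygosity statistics match closed forms and a recount oracle", {
  # monomorphic locus
  g <- gt_from(c(5, 5, 5), c(5, 5, 5))
  expect_equal(unname(het_stats(g, "L1")), c(0, 0))
  # two individuals both A/B: Ho = 1, He = (4/3)(1 - 1/2) = 2/3
  g2 <- gt_from(c(1, 1), c(2, 2))
  expect_equal(unname(het_stats(g2, "L1")), c(1, 2 / 3))
  # random table vs direct-count oracle
  set.seed(51)
  gt <- make_genotypes(40, F = 0.2, seed = 51)
  for (l in gt$loci[1:3]) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    n <- sum(!is.na(a1))
    ho <- sum(a1 != a2, na.rm = TRUE) / n
    freqs <- table(c(a1, a2)) / (2 * n)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
    expect_equal(unname(het_stats(gt, l)), c(ho, he))
  }
})

test_that("HWE enumeration equals the independent biallelic summation oracle", {
  # 5 individuals all heterozygous A/B
  g <- gt_from(rep(1, 5), rep(2, 5))
  p <- hwe_exact(g, "L1", method = "enumeration")
  expect_equal(p, hwe_biallelic_oracle(rep(1, 5), rep(2, 5)), tolerance = 1e-12)
  # assorted small biallelic samples
  cases <- list(list(a1 = c(1, 1, 1, 2, 2), a2 = c(1, 2, 2, 2, 2)),
                list(a1 = c(1, 1, 2, 2, 1, 1), a2 = c(1, 1, 2, 2, 2, 2)),
                list(a1 = c(1, 2, 1, 2, 1, 2, 1), a2 = c(2, 2, 2, 2, 2, 2, 1)))
  for (cs in cases) {
    g <- gt_from(cs$a1, cs$a2)
    expect_equal(hwe_exact(g, "L1", method = "enumeration"),
                 hwe_biallelic_oracle(cs$a1, cs$a2), tolerance = 1e-12)
  }
})

test_that("HWE handles monomorphic loci and near-equilibrium large samples", {
  g <- gt_from(rep(3, 10), rep(3, 10))
  expect_message(p <- hwe_exact(g, "L1"), "monomorphic")
  expect_equal(p, 1)
  # genotype counts at exact HW proportions: p should not be small
  a1 <- c(rep(1, 25), rep(1, 50), rep(2, 25))
  a2 <- c(rep(1, 25), rep(2, 50), rep(2, 25))
  g2 <- gt_from(a1, a2)
  expect_gt(hwe_exact(g2, "L1", method = "montecarlo", B = 4000, seed = 1), 0.5)
})

test_that("Monte-Carlo HWE converges to the enumeration value", {
  g <- gt_from(c(1, 1, 2, 3, 1, 2), c(2, 3, 3, 3, 1, 2))
  p_enum <- hwe_exact(g, "L1", method = "enumeration")
  B <- 10000
  p_mc <- hwe_exact(g, "L1", method = "montecarlo", B = B, seed = 7)
  expect_lte(abs(p_mc - p_enum),
             3 * sqrt(p_enum * (1 - p_enum) / B) + 2 / B)
})

test_that("LD permutation test attains its minimum on duplicated loci", {
  gt <- make_genotypes(40, F = 0, seed = 52)
  g <- genotype_table(cbind(gt$a1[, 1], gt$a1[, 1]),
                      cbind(gt$a2[, 1], gt$a2[, 1]), loci = c("A", "B"))
  expect_equal(ld_test(g, "A", "B", n_perm = 199, seed = 3), 1 / 200)
})

test_that("LD test degrades gracefully on tiny samples", {
  g <- genotype_table(cbind(c(1, 2), c(3, 4)), cbind(c(1, 2), c(3, 4)),
                      loci = c("A", "B"))
  p <- ld_test(g, "A", "B", n_perm = 99, seed = 1)
  expect_gte(p, 1 / 100)
  expect_lte(p, 1)
})

test_that("Holm adjustment matches the longhand step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(holm_adjust(c(0.003, 0.013, 0.2, 0.9)),
               c(0.012, 0.039, 0.4, 0.9))
  set.seed(53)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, holm_longhand(p))
    expect_true(all(adj >= p))
    expect_equal(holm_adjust(adj) >= adj, rep(TRUE, length(adj)))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("inbreeding indices follow their definitions and invariances", {
  # heterozygous at 3 of 7 loci
  a1 <- matrix(c(1, 1, 1, 2, 2, 2, 2), 1)
  a2 <- matrix(c(2, 3, 4, 2, 2, 2, 2), 1)
  ii <- inbreeding_indices(gt_from(a1, a2))
  expect_equal(ii$mlh, 3 / 7)
  # fully homozygous individual
  ii0 <- inbreeding_indices(gt_from(matrix(rep(4, 6), 1), matrix(rep(4, 6), 1)))
  expect_equal(ii0$mlh, 0)
  expect_equal(ii0$d2, 0)
  # one locus with alleles 12 and 18 repeats, 6 loci typed: d2 = 36/6
  a1 <- matrix(c(12, rep(5, 5)), 1)
  a2 <- matrix(c(18, rep(5, 5)), 1)
  expect_equal(inbreeding_indices(gt_from(a1, a2))$d2, 6)
  # invariance to locus order and additive allele shifts
  gt <- make_genotypes(30, F = 0.2, seed = 54)
  ii1 <- inbreeding_indices(gt)
  perm <- sample(seq_along(gt$loci))
  gtp <- genotype_table(gt$a1[, perm], gt$a2[, perm], ids = gt$ids)
  iip <- inbreeding_indices(gtp)
  expect_equal(iip$mlh, ii1$mlh)
  expect_equal(iip$d2, ii1$d2)
  gts <- genotype_table(gt$a1 + 7, gt$a2 + 7, ids = gt$ids)
  expect_equal(inbreeding_indices(gts)$d2, ii1$d2)
})

test_that("individuals with no typed loci are omitted with a warning", {
  a1 <- rbind(c(1, 2), c(NA, NA))
  a2 <- rbind(c(2, 2), c(NA, NA))
  gt <- genotype_table(a1, a2, ids = c("x", "y"))
  expect_warning(ii <- inbreeding_indices(gt), "y")
  expect_equal(ii$individual, "x")
})

test_that("group comparisons pick the test by normality and Holm-correct batches", {
  set.seed(55)
  # complete separation: Mann-Whitney at its extreme (skewed groups)
  x <- rexp(20); y <- rexp(20) + 100
  res <- compare_groups(list(a = x, b = y))
  expect_equal(res$test, "mann-whitney")
  expect_true(res$statistic %in% c(0, 400))
  # two normal samples take the t-test path
  res2 <- compare_groups(list(a = rnorm(30), b = rnorm(30)))
  expect_equal(res2$test, "t")
  # batch Holm arithmetic via a batch of shifted comparisons
  batch <- list(c1 = list(rnorm(20), rnorm(20) + 10),
                c2 = list(rnorm(20), rnorm(20)),
                c3 = list(rnorm(20), rnorm(20) + 0.2))
  resb <- compare_groups(batch)
  expect_equal(resb$p_holm, holm_longhand(resb$p))
  expect_error(compare_groups(list(a = rnorm(2), b = rnorm(10))), "n >= 3")
})

test_that("Genepop files parse 2- and 3-digit encodings with missing data", {
  f <- withr::local_tempfile()
  writeLines(c("Synthetic alpine study",
               "locA", "locB, locC",
               "Pop",
               "z01 , 0102 011011 0909",
               "z02 , 0101 000000 0910",
               "Pop",
               "s01 , 0202 010010 0000"), f)
  gt <- read_genepop(f)
  expect_equal(gt$loci, c("locA", "locB", "locC"))
  expect_equal(unname(gt$a1[1, ]), c(1, 11, 9))
  expect_equal(unname(gt$a2[1, ]), c(2, 11, 9))
  expect_true(is.na(gt$a1[2, "locB"]))
  expect_true(is.na(gt$a1[3, "locC"]))
  expect_equal(gt$groups$location, c("pop1", "pop1", "pop2"))
})

test_that("genotype CSV IO round-trips and converts motifs on load", {
  gt <- make_genotypes(12, F = 0.3, seed = 56,
                       groups = data.frame(location = rep(c("a", "b"), 6)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_genotypes_csv(gt, f)
  gt2 <- read_genotypes_csv(f)
  expect_equal(gt2$a1, gt$a1)
  expect_equal(gt2$a2, gt$a2)
  expect_equal(gt2$groups$location, gt$groups$location)
  # motif division: allele sizes in bp over motif length
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual,L1", "i1,120/126", "i2,120/120"), f2)
  gt3 <- read_genotypes_csv(f2, motifs = c(L1 = 6))
  expect_equal(unname(gt3$a1[, 1]), c(20, 20))
  expect_equal(unname(gt3$a2[, 1]), c(21, 20))
})

test_that("locus screening applies Holm within each test family", {
  gt <- make_genotypes(25, F = 0.1, seed = 57)
  st <- locus_stats(gt, B = 300, n_perm = 99, seed = 5)
  expect_equal(nrow(st$loci), 7)
  expect_equal(nrow(st$pairs), choose(7, 2))
  expect_true(all(st$loci$hwe_p_holm >= st$loci$hwe_p))
  expect_true(all(st$pairs$ld_p_holm >= st$pairs$ld_p))
  expect_true(all(st$loci$Ho >= 0 & st$loci$Ho <= 1))
  expect_true(all(st$loci$He >= 0 & st$loci$He <= 1))
})
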