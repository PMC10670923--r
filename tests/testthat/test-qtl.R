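test_that("minor allele frequency follows allele counting", {
  g <- tibble::tibble(clone = sprintf("c%02d", 1:24),
                      S1 = rep("A/A", 24),
                      S2 = c(rep("T/T", 12), rep("T/C", 12)),
                      S3 = c(rep("A/G", 2), rep("A/A", 22)))
  m <- snp_maf(g)
  expect_equal(m$maf[m$snp == "S1"], 0)       # monomorphic
  expect_equal(m$maf[m$snp == "S2"], 12 / 48) # 0.25 by hand
  expect_equal(m$maf[m$snp == "S3"], 2 / 48, tolerance = 1e-12)
})

test_that("maf handles missing calls and heterozygote orientation", {
  g <- tibble::tibble(clone = c("c1", "c2", "c3", "c4"),
                      S1 = c("A/G", "G/A", "./.", "A/A"))
  m <- snp_maf(g)
  expect_equal(m$n_called[1], 3)
  expect_equal(m$maf[1], 2 / 6)
  expect_error(snp_maf(tibble::tibble(clone = "c1", S1 = "./.")), "no non-missing")
})

test_that("genotype classes partition clones and apply the size threshold", {
  g <- tibble::tibble(clone = sprintf("c%02d", 1:24),
                      S1 = c(rep("A/A", 10), rep("A/G", 10), rep("G/G", 4)))
  cl <- genotype_classes(g, "S1")
  expect_equal(sort(cl$classes$label), c("A/A", "A/G", "G/G"))
  expect_true(cl$testable)
  expect_equal(sum(cl$members$usable), 24)

  # monomorphic SNP is untestable
  g2 <- tibble::tibble(clone = sprintf("c%02d", 1:24), S1 = rep("A/A", 24))
  expect_false(genotype_classes(g2, "S1")$testable)

  # a 2-member class falls under min_class_size 3 and the SNP dies
  g3 <- tibble::tibble(clone = sprintf("c%02d", 1:24),
                       S1 = c(rep("A/A", 22), rep("A/G", 2)))
  expect_message(cl3 <- genotype_classes(g3, "S1"), "min_class_size")
  expect_false(cl3$testable)
})

test_that("classes with identical trajectories merge; threshold 0 never merges", {
  geno <- split_genotypes(12, 12)
  ph <- two_class_pheno(geno, effect = 0, noise = 0.005, seed = 2)
  cl <- genotype_classes(geno, "SNP1")
  merged <- merge_similar_classes(cl, ph, "height_m", threshold = 0.002, seed = 1)
  expect_equal(nrow(merged$classes), 1)
  expect_equal(merged$merged_from$from1, "A/A")
  no_merge <- merge_similar_classes(cl, ph, "height_m", threshold = 0, seed = 1)
  expect_equal(nrow(no_merge$classes), 2)
  expect_null(no_merge$merged_from)
})

test_that("only the truly identical pair merges in a three-class design", {
  geno <- tibble::tibble(
    clone = sprintf("c%02d", 1:24),
    SNP1 = c(rep("A/A", 8), rep("A/G", 8), rep("G/G", 8))
  )
  base <- c(a = 28, b = 0.18, c = 1.6)
  ph <- withr::with_seed(9, purrr::map_dfr(seq_len(24), function(i) {
    p <- base
    if (geno$SNP1[i] == "G/G") p["a"] <- p["a"] * 1.2 # one shifted class
    tibble::tibble(clone = geno$clone[i], trait = "height_m", age = study_ages,
                   value = growth_value("richard", p, study_ages) +
                     rnorm(9, 0, 0.005 * 28))
  }))
  cl <- genotype_classes(geno, "SNP1")
  merged <- merge_similar_classes(cl, ph, "height_m", threshold = 0.002, seed = 1)
  expect_equal(nrow(merged$classes), 2)
  expect_setequal(c(merged$merged_from$from1, merged$merged_from$from2),
                  c("A/A", "A/G"))
})

test_that("the LR statistic is nonnegative and vanishes on noiseless null data", {
  # with zero noise the pooled and class-wise fits coincide exactly, so the
  # nested models have identical (variance-floored) likelihoods
  geno <- split_genotypes(12, 12)
  ph <- two_class_pheno(geno, effect = 0, noise = 0, seed = 4)
  cl <- genotype_classes(geno, "SNP1")
  lt <- lr_trajectory_test(ph, cl, "height_m", seed = 1)
  expect_gte(lt$lr, -1e-6)
  expect_lt(abs(lt$lr), 1e-6)
  expect_equal(lt$p, 1)
  expect_equal(lt$df, 3L)
  expect_equal(lt$lr, -2 * (lt$logL0 - lt$logL1), tolerance = 1e-12)
})

test_that("a 20% asymptote effect is decisively detected", {
  geno <- split_genotypes(12, 12)
  ph <- two_class_pheno(geno, effect = 0.2, noise = 0.02, seed = 5)
  cl <- genotype_classes(geno, "SNP1")
  lt <- lr_trajectory_test(ph, cl, "height_m", seed = 1)
  expect_lt(lt$p, 0.001)
  g <- glance(lt)
  expect_equal(g$lr, lt$lr)
  td <- tidy(lt)
  expect_equal(nrow(td), 2)
  # fitted asymptotes straddle the true 28 vs 33.6
  expect_lt(abs(td$a[td$class == "A/A"] - 28), 1.5)
  expect_lt(abs(td$a[td$class == "G/G"] - 33.6), 1.5)
})

test_that("per-class sigma with counted df is the calibrated alternative", {
  geno <- split_genotypes(12, 12)
  ph <- two_class_pheno(geno, effect = 0, noise = 0.02, seed = 6)
  cl <- genotype_classes(geno, "SNP1")
  a <- lr_trajectory_test(ph, cl, "height_m", sigma = "per-class",
                          count_sigma_df = TRUE, seed = 1)
  b <- lr_trajectory_test(ph, cl, "height_m", sigma = "per-class",
                          count_sigma_df = FALSE, seed = 1)
  expect_equal(a$df, 4L); expect_equal(b$df, 3L)
  expect_equal(a$lr, b$lr) # df rule does not change the statistic
  expect_gte(a$lr, -1e-6)
})

test_that("untestable SNPs are refused by the LR test", {
  geno <- tibble::tibble(clone = sprintf("c%02d", 1:24), SNP1 = rep("A/A", 24))
  ph <- two_class_pheno(split_genotypes(12, 12), seed = 7)
  expect_error(lr_trajectory_test(ph, genotype_classes(geno, "SNP1"), "height_m"),
               "untestable")
})

test_that("per-year GLM reproduces the hand-computed two-group ANOVA", {
  # classes {10, 12} vs {20, 22}: SSB = 100, SSW = 2, F = 50
  geno <- tibble::tibble(clone = c("c1", "c2", "c3", "c4"),
                         SNP1 = c("A/A", "A/A", "G/G", "G/G"))
  ph <- tibble::tibble(clone = c("c1", "c2", "c3", "c4"), trait = "height_m",
                       age = 5, value = c(10, 12, 20, 22))
  res <- per_year_glm(ph, genotype_classes(geno, "SNP1", min_class_size = 2), "height_m")
  expect_equal(res$statistic, 50, tolerance = 1e-10)
  expect_equal(res$p, pf(50, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(res$p, 0.0194, tolerance = 1e-3)
})

test_that("per-year GLM equals the textbook ANOVA and F = t^2 on two groups", {
  set.seed(31)
  for (rep in 1:20) {
    sizes <- sample(2:6, sample(2:3, 1), replace = TRUE)
    labels <- rep(c("A/A", "A/G", "G/G")[seq_along(sizes)], sizes)
    n <- length(labels)
    geno <- tibble::tibble(clone = sprintf("c%02d", 1:n), SNP1 = labels)
    vals <- rnorm(n, mean = rep(runif(length(sizes), 0, 5), sizes))
    ph <- tibble::tibble(clone = geno$clone, trait = "height_m", age = 3, value = vals)
    res <- per_year_glm(ph, genotype_classes(geno, "SNP1", min_class_size = 2),
                        "height_m")
    oracle <- hand_anova(vals, labels)
    expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
    expect_equal(res$p, oracle$p, tolerance = 1e-10)
    if (length(sizes) == 2 && sizes[1] == sizes[2]) {
      tt <- t.test(vals[labels == labels[1]], vals[labels != labels[1]],
                   var.equal = TRUE)
      expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    }
  }
})

test_that("identical parameter vectors across classes give Wilks lambda 1", {
  geno <- split_genotypes(12, 12)
  # the same 12 parameter vectors appear in both classes (clone permutation),
  # so class means coincide exactly while the within-class scatter is full rank
  block <- withr::with_seed(19, tibble::tibble(
    a = rnorm(12, 28, 1), b = rnorm(12, 0.18, 0.02), c = rnorm(12, 1.6, 0.1)
  ))
  pars <- dplyr::bind_cols(tibble::tibble(clone = geno$clone),
                           dplyr::bind_rows(block, block))
  res <- param_association(pars, genotype_classes(geno, "SNP1"))
  expect_equal(res$lambda, 1, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-6)
})

test_that("one-dimensional parameter MANOVA collapses to the per-year ANOVA", {
  set.seed(13)
  geno <- split_genotypes(10, 8)
  vals <- rnorm(18, mean = c(rep(0, 10), rep(1, 8)))
  pars <- tibble::tibble(clone = geno$clone, a = vals)
  cl <- genotype_classes(geno, "SNP1")
  res <- param_association(pars, cl)
  oracle <- hand_anova(vals, geno$SNP1)
  expect_equal(res$statistic, oracle$f, tolerance = 1e-10)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
})

test_that("parameter MANOVA matches stats::manova and detects a shifted mean", {
  set.seed(17)
  geno <- split_genotypes(12, 12)
  pars <- tibble::tibble(
    clone = geno$clone,
    a = rnorm(24, mean = c(rep(28, 12), rep(28 + 5 * 1, 12)), sd = 1),
    b = rnorm(24, 0.18, 0.01), c = rnorm(24, 1.6, 0.05)
  )
  cl <- genotype_classes(geno, "SNP1")
  res <- param_association(pars, cl)
  expect_lt(res$p, 0.01)
  mv <- summary(stats::manova(cbind(a, b, c) ~ SNP1,
                              data = dplyr::left_join(pars, geno, by = "clone")),
                test = "Wilks")
  expect_equal(res$lambda, mv$stats[1, "Wilks"], tolerance = 1e-8)
  expect_equal(res$statistic, mv$stats[1, "approx F"], tolerance = 1e-8)
})

test_that("singular within-class covariance is refused with advice", {
  geno <- split_genotypes(10, 8)
  pars <- tibble::tibble(clone = geno$clone, a = 1:18, b = 2 * (1:18), c = rnorm(18))
  expect_error(param_association(pars, genotype_classes(geno, "SNP1")),
               "singular|standardiz")
})

test_that("genotype counts are tested against Mendelian ratios", {
  mk <- function(counts, labels = c("A/A", "A/G", "G/G")) {
    g <- tibble::tibble(
      clone = sprintf("c%02d", seq_len(sum(counts))),
      SNP1 = rep(labels[seq_along(counts)], counts)
    )
    genotype_classes(g, "SNP1", min_class_size = 1)
  }
  perfect <- genotype_count_test(mk(c(6, 12, 6)))
  expect_equal(perfect$statistic, 0, tolerance = 1e-12)
  expect_equal(perfect$p, 1, tolerance = 1e-12)

  skewed <- genotype_count_test(mk(c(10, 10, 4)))
  expect_equal(skewed$statistic, (10 - 6)^2 / 6 + (10 - 12)^2 / 12 + (4 - 6)^2 / 6,
               tolerance = 1e-12)
  expect_equal(skewed$statistic, 3.667, tolerance = 1e-3)
  expect_equal(skewed$p, pchisq(11 / 3, 2, lower.tail = FALSE), tolerance = 1e-12)

  twoclass <- genotype_count_test(mk(c(24, 1), labels = c("A/A", "G/G")))
  # observed (24, 1) vs 1:1 -> chi-square by hand
  expect_equal(twoclass$statistic, (24 - 12.5)^2 / 12.5 * 2, tolerance = 1e-12)
  expect_error(genotype_count_test(mk(c(10, 10)), ratio = c(1, 0)), "zero")
})
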