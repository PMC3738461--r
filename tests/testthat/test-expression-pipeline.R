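test_that("median-of-ratios size factors normalize library depth", {
  m <- rbind(g1 = c(10, 20), g2 = c(100, 200))
  colnames(m) <- c("L1", "L2")
  sf <- size_factors(m)
  expect_equal(unname(sf["L2"] / sf["L1"]), 2)
  norm <- normalize_counts(m, sf)
  expect_equal(norm[, 1], norm[, 2])
  # identical libraries -> unit factors
  m2 <- cbind(L1 = c(5, 50, 500), L2 = c(5, 50, 500))
  expect_equal(unname(size_factors(m2)), c(1, 1))
  # exact 3x library
  m3 <- cbind(L1 = c(10, 100), L2 = c(30, 300))
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3["L2"] / sf3["L1"]), 3)
  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "non-zero")
})

test_that("size factors agree with the reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(70)
  m <- matrix(rnbinom(500 * 6, mu = rep(exp(runif(500, 2, 8)), 6),
                      size = 10), ncol = 6)
  m <- sweep(m, 2, c(1, 1.5, 2, 0.5, 1, 3), "*")
  storage.mode(m) <- "integer"
  rownames(m) <- paste0("g", 1:500); colnames(m) <- paste0("L", 1:6)
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-6)
})

test_that("the morph-effect test is null-calibrated and powerful", {
  set.seed(71)
  G <- 2000
  mu <- exp(runif(G, log(20), log(5000)))
  m <- nb_counts(mu)
  design <- std_design()
  res <- morph_effect_test(m, design)
  expect_gt(suppressWarnings(ks.test(res$p_value, "punif"))$p.value, 0.01)
  # planted 10-fold male-biased genes at mean 500 among a null majority:
  # near-certain detection
  m2 <- nb_counts(c(rep(500, 300), exp(runif(2700, log(20), log(5000)))),
                  factors_M = c(rep(10, 300), rep(1, 2700)))
  p2 <- morph_effect_test(m2, design)$p_value[1:300]
  expect_gte(mean(p2 < 1e-3), 0.95)
  # a gene identical in every library carries no morph signal
  m3 <- matrix(7, nrow = 60, ncol = 8,
               dimnames = list(paste0("g", 1:60), design$library))
  expect_true(all(morph_effect_test(m3, design)$p_value == 1))
  # all-zero gene
  m4 <- nb_counts(rep(100, 60)); m4[1, ] <- 0
  expect_equal(morph_effect_test(m4, design)$p_value[1], 1)
  # design validation
  bad <- std_design(); bad$morph[4] <- "Q"
  expect_error(morph_effect_test(m4, bad), "unknown morph \"Q\"")
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  set.seed(72)
  p <- runif(200)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-12))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bias categories follow the fold-threshold definitions", {
  expect_equal(classify_bias(100, 10, 10, 2, TRUE), "M+F-A-")
  expect_equal(classify_bias(10, 50, 60, 2, TRUE), "M-F+A+")
  # the under-in-one branch fails (15/10 < 2) but asexual over-in-one holds
  expect_equal(classify_bias(10, 15, 60, 2, TRUE), "M-F-A+")
  expect_equal(classify_bias(100, 10, 10, 2, FALSE), "unbiased")
  expect_equal(classify_bias(0, 0, 0, 2, TRUE), "unbiased")
  # similarity clause is strict: high morphs exactly 2-fold apart fail
  # (at n = 5 the asexual over-in-one branch cannot absorb the case)
  expect_equal(classify_bias(10, 60, 120, 5, TRUE), "unbiased")
  expect_equal(classify_bias(10, 60, 119, 5, TRUE), "M-F+A+")
  # at n = 2 a 2-fold gap between the high morphs is over-in-one instead
  expect_equal(classify_bias(10, 40, 80, 2, TRUE), "M-F-A+")
  # n-fold threshold itself is inclusive
  expect_equal(classify_bias(20, 10, 10, 2, TRUE), "M+F-A-")
  # zero denominators count as exceeded only by positive numerators
  expect_equal(classify_bias(5, 0, 0, 10, TRUE), "M+F-A-")
})

test_that("categories nest across thresholds and are mutually exclusive", {
  set.seed(73)
  n <- 1e4
  means <- matrix(rlnorm(3 * n, 2, 2), ncol = 3)
  means[sample(length(means), 500)] <- 0
  c2 <- classify_bias(means[, 1], means[, 2], means[, 3], 2, TRUE)
  c5 <- classify_bias(means[, 1], means[, 2], means[, 3], 5, TRUE)
  c10 <- classify_bias(means[, 1], means[, 2], means[, 3], 10, TRUE)
  biased10 <- c10 != "unbiased"
  expect_true(all(c5[biased10] == c10[biased10]))
  biased5 <- c5 != "unbiased"
  expect_true(all(c2[biased5] == c5[biased5]))
  expect_true(all(c2 %in% c(bias_categories(), "unbiased")))
})

test_that("low-support flags apply a strict 5-read rule", {
  m <- rbind(g1 = c(4.9, 0, 0, 0, 0, 0, 0, 0),
             g2 = c(5.0, 0, 0, 0, 0, 0, 0, 0),
             g3 = rep(0, 8))
  flags <- low_support_flag(m)
  expect_identical(unname(flags), c(TRUE, FALSE, TRUE))
})

test_that("the full classification pipeline ties the steps together", {
  set.seed(74)
  ds <- synth_dataset(small_synth_config(), seed = 75)
  calls <- classify_expression(ds$counts, ds$design)
  expect_s3_class(calls, "bias_calls")
  expect_true(all(c("category_2", "category_5", "category_10") %in%
                    names(calls)))
  # only significant genes get a category
  expect_true(all(calls$category_2[calls$padj >= 0.05] == "unbiased"))
  # planted strongly-biased, well-expressed genes are mostly recovered
  truth2 <- classify_bias(ds$truth$factor_M, ds$truth$factor_F,
                          ds$truth$factor_A, 2, TRUE)
  strong <- truth2 != "unbiased" & ds$truth$fold >= 4 &
    ds$truth$abundance > 5e-5
  expect_gt(sum(strong), 30)
  expect_gte(mean(calls$category_2[strong] == truth2[strong]), 0.9)
  # externally supplied p-values short-circuit the built-in test
  p_ext <- setNames(rep(1, nrow(calls)), calls$gene)
  calls2 <- classify_expression(ds$counts, ds$design, p_values = p_ext)
  expect_true(all(calls2$category_2 == "unbiased"))
})
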