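test_that("tpm computes length-normalized rates summing to one million", {
  cnt <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  x <- tpm(cnt, c(a = 1000, b = 2000))
  expect_equal(x[, 1], c(a = 2e6 / 3, b = 1e6 / 3))

  set.seed(2)
  cnt <- matrix(rpois(60, 50), 10, 6,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  len <- setNames(sample(500:5000, 10), paste0("g", 1:10))
  x <- tpm(cnt, len)
  expect_equal(unname(colSums(x)), rep(1e6, 6))
  # library-depth invariance
  cnt2 <- cnt; cnt2[, 3] <- cnt2[, 3] * 2L
  expect_equal(tpm(cnt2, len)[, 3], x[, 3])
  # monotone within sample after log
  expect_identical(order(log_transform(x[, 1])), order(x[, 1]))
})

test_that("tpm validates lengths and all-zero samples", {
  cnt <- matrix(c(0L, 0L, 5L, 5L), 2, 2,
                dimnames = list(c("a", "b"), c("empty", "ok")))
  expect_error(tpm(cnt, c(a = 100, b = 200)),
               class = "stepsig_input_error", regexp = "empty")
  expect_error(tpm(cnt[, 2, drop = FALSE], c(a = 100)),
               class = "stepsig_input_error", regexp = "b")
  expect_error(tpm(cnt[, 2, drop = FALSE], c(a = 100, b = 0)),
               class = "stepsig_input_error")
})

test_that("log_transform is log2(x+1) and rejects negatives", {
  expect_equal(log_transform(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log_transform(-1), class = "stepsig_input_error")
})

test_that("differential_expression: null on shared data, symmetric under arm swap", {
  set.seed(21)
  half <- matrix(rnorm(50 * 4, 5), 50, 4)
  mat <- cbind(half, half) # identical arms
  rownames(mat) <- paste0("g", 1:50)
  colnames(mat) <- paste0("s", 1:8)
  groups <- rep(c("a", "b"), each = 4)
  deg <- differential_expression(mat, groups)
  expect_false(any(deg$passes))
  expect_equal(deg$fold_change, rep(1, 50))

  set.seed(22)
  mat2 <- matrix(rnorm(50 * 8, 5), 50, 8,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  d_ab <- differential_expression(mat2, groups, test = "b", control = "a")
  d_ba <- differential_expression(mat2, groups, test = "a", control = "b")
  expect_equal(d_ab$p, d_ba$p)
  expect_equal(d_ab$t, -d_ba$t)
  # fold inversion holds up to the shared pseudocount
  expect_equal((d_ab$mean_test + 1) / (d_ab$mean_control + 1),
               1 / ((d_ba$mean_test + 1) / (d_ba$mean_control + 1)))
})

test_that("per-gene Welch matches stats::t.test and the pass rule is as stated", {
  set.seed(23)
  mat <- matrix(rnorm(20 * 9, 4), 20, 9,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:9)))
  groups <- c(rep("ctl", 4), rep("trt", 5))
  deg <- differential_expression(mat, groups, test = "trt", control = "ctl")
  for (g in c(1, 7, 20)) {
    tt <- t.test(mat[g, groups == "trt"], mat[g, groups == "ctl"],
                 var.equal = FALSE)
    expect_equal(deg$t[g], unname(tt$statistic))
    expect_equal(deg$p[g], tt$p.value)
  }
  expect_equal(deg$passes,
               deg$p <= 0.05 & (deg$fold_change >= 2 | deg$fold_change <= 0.5))
  expect_true(all(deg$p_adj >= deg$p))
  expect_error(differential_expression(mat, c(rep("ctl", 1), rep("trt", 8))),
               class = "stepsig_input_error")
})

test_that("signature_genes extracts by direction", {
  mat <- rbind(up = c(1, 1, 1, 6, 6, 6), down = c(6, 6, 6, 1, 1, 1),
               flat = c(3, 3.1, 3, 3, 3.1, 3))
  colnames(mat) <- paste0("s", 1:6)
  deg <- differential_expression(mat, rep(c("a", "b"), each = 3),
                                 test = "b", control = "a")
  expect_identical(signature_genes(deg, "up"), "up")
  expect_identical(signature_genes(deg, "down"), "down")
  expect_setequal(signature_genes(deg, "both"), c("up", "down"))
})

test_that("bh_adjust matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.33), 0.33)
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "stepsig_input_error")
  expect_error(bh_adjust(c(0.5, -0.1)), class = "stepsig_input_error")
})

test_that("gene_set_enrichment matches the closed-form hypergeometric tail", {
  universe <- paste0("g", 1:100)
  sets <- list(target = paste0("g", 1:10), other = paste0("g", 51:70))
  hits <- paste0("g", 1:5)
  res <- gene_set_enrichment(hits, universe, sets)
  row <- res[res$set == "target", ]
  expect_equal(row$overlap, 5)
  expect_equal(row$fold_enrichment, (5 / 5) / (10 / 100))
  # closed form: all 5 hits inside the 10-gene set
  expect_equal(row$p, choose(10, 5) / choose(100, 5))

  # set == universe -> fold 1, p 1; empty overlap -> fold 0, p 1
  res2 <- gene_set_enrichment(hits, universe,
                              list(all = universe, none = paste0("g", 90:99)))
  expect_equal(res2[res2$set == "all", ]$fold_enrichment, 1)
  expect_equal(res2[res2$set == "all", ]$p, 1)
  expect_equal(res2[res2$set == "none", ]$fold_enrichment, 0)
  expect_equal(res2[res2$set == "none", ]$p, 1)

  expect_error(gene_set_enrichment(c("g1", "zzz"), universe, sets),
               class = "stepsig_input_error", regexp = "zzz")
  expect_error(gene_set_enrichment(hits, universe, list()),
               class = "stepsig_input_error")
})
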