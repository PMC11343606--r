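test_that("multivariate_ols recovers an exact linear response", {
  set.seed(41)
  tab <- data.frame(y = 0, age = rnorm(20, 60, 8), stage = sample(1:4, 20, TRUE))
  tab$y <- tab$age # response equals one covariate exactly
  res <- suppressWarnings(multivariate_ols(tab, "y")) # lm warns on perfect fit
  est <- setNames(res$estimate, res$term)
  expect_equal(unname(est["age"]), 1)
  expect_equal(unname(est["(Intercept)"]), 0, tolerance = 1e-10)
  expect_equal(unname(est["stage"]), 0, tolerance = 1e-10)
})

test_that("multivariate_ols equals the normal-equations oracle, with sane CIs", {
  set.seed(42)
  n <- 40
  tab <- data.frame(age = rnorm(n, 60, 8),
                    stage = sample(1:4, n, TRUE),
                    location = sample(c("left", "right"), n, TRUE))
  tab$y <- 0.5 * tab$age - 2 * tab$stage +
    3 * (tab$location == "right") + rnorm(n)
  res <- multivariate_ols(tab, "y")
  X <- model.matrix(y ~ age + stage + location,
                    transform(tab, location = factor(location)))
  beta <- oracle_ols_coef(X, tab$y)
  expect_equal(setNames(res$estimate, res$term), beta, tolerance = 1e-8)
  # CI geometry: center +/- t * SE
  tcrit <- qt(0.975, n - ncol(X))
  expect_equal(res$conf_low, res$estimate - tcrit * res$std_error)
  expect_equal(res$conf_high, res$estimate + tcrit * res$std_error)
  # categorical coded against alphabetically first level
  expect_true("locationright" %in% res$term)
})

test_that("multivariate_ols rejects bad designs", {
  tab <- data.frame(y = rnorm(10), a = 1:10)
  tab$b <- 2 * tab$a # collinear
  expect_error(multivariate_ols(tab, "y"), class = "stepsig_input_error",
               regexp = "b")
  expect_error(multivariate_ols(data.frame(y = c(1, NA), a = 1:2), "y"),
               class = "stepsig_input_error")
  expect_error(multivariate_ols(data.frame(y = rnorm(3),
                                           a = rnorm(3), b = rnorm(3),
                                           c = rnorm(3)), "y"),
               class = "stepsig_input_error")
  expect_error(multivariate_ols(data.frame(y = 1:5), "z"),
               class = "stepsig_input_error")
})

test_that("km_logrank matches survdiff-free enumeration on a worked example", {
  # 6 samples, hand-enumerable event table
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 0)
  stratum <- c("low", "high", "low", "high", "low", "high")
  res <- km_logrank(time, event, stratum)
  expect_equal(res$chisq, oracle_logrank(time, event, stratum))
  expect_equal(res$p, pchisq(res$chisq, 1, lower.tail = FALSE))

  # symmetric under stratum relabeling
  flipped <- km_logrank(time, event, ifelse(stratum == "low", "high", "low"))
  expect_equal(flipped$chisq, res$chisq)
  expect_equal(flipped$p, res$p)
})

test_that("km_logrank: identical strata give statistic 0 and p 1", {
  time <- rep(c(1, 3, 5, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  stratum <- rep(c("a", "b"), each = 4)
  res <- km_logrank(time, event, stratum)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)
})

test_that("km curves are valid product-limit estimates", {
  set.seed(43)
  time <- rexp(40, 0.1)
  event <- rbinom(40, 1, 0.7)
  stratum <- rep(c("high", "low"), 20)
  res <- km_logrank(time, event, stratum)
  for (s in c("high", "low")) {
    cv <- res$curves[res$curves$stratum == s, ]
    expect_true(all(diff(cv$survival) <= 1e-12)) # non-increasing
    expect_true(all(cv$survival >= 0 & cv$survival <= 1))
    # survival only drops at event times
    drops <- which(diff(c(1, cv$survival)) < 0)
    expect_true(all(cv$n_event[drops] > 0))
  }
})

test_that("km_logrank survives an all-censored stratum and flags zero events", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 0, 0, 0) # stratum b fully censored
  stratum <- rep(c("a", "b"), each = 3)
  res <- km_logrank(time, event, stratum)
  expect_true(is.finite(res$chisq))

  expect_warning(res0 <- km_logrank(time, rep(0, 6), stratum), "no events")
  expect_true(is.na(res0$chisq))
  expect_s3_class(res0$curves, "data.frame")

  expect_error(km_logrank(c(-1, 2), c(1, 1), c("a", "b")),
               class = "stepsig_input_error")
  expect_error(km_logrank(time, event, rep("a", 6)),
               class = "stepsig_input_error")
})

test_that("stratify_by_metagene cuts at the median with ties going low", {
  mat <- rbind(g1 = c(1, 3, 5, 7), g2 = c(1, 3, 5, 7))
  colnames(mat) <- paste0("s", 1:4)
  st <- stratify_by_metagene(mat, c("g1", "g2"))
  expect_identical(as.vector(st), c("low", "low", "high", "high"))
  expect_equal(attr(st, "metagene"), colMeans(mat))

  two <- stratify_by_metagene(rbind(g = c(a = 1, b = 3)), "g")
  expect_identical(as.vector(two), c("low", "high"))

  flat <- stratify_by_metagene(rbind(g = c(2, 2, 2)), "g")
  expect_true(all(flat == "low"))

  # invariant to gene order; missing genes warned then excluded
  set.seed(44)
  mat2 <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_identical(stratify_by_metagene(mat2, paste0("g", 1:5)),
                   stratify_by_metagene(mat2, paste0("g", 5:1)))
  expect_warning(st2 <- stratify_by_metagene(mat2, c("g1", "g2", "zz")), "zz")
  expect_identical(st2, stratify_by_metagene(mat2, c("g1", "g2")))
  expect_error(suppressWarnings(stratify_by_metagene(mat2, "zz")),
               class = "stepsig_input_error")
})

test_that("synthetic survival + metagene stratification point the stated direction", {
  # protective link: high-score stratum should show longer median survival
  longer <- vapply(1:10, function(s) {
    cfg <- synthetic_config(n_genes = 120, n_signature_genes = 20,
                            samples_per_group = 25, survival_link = -1.5,
                            censor_rate = 0.1, seed = s)
    co <- generate_counts(cfg)
    expr <- cohort_expression(co)
    st <- stratify_by_metagene(expr, co$truth$signature)
    md <- co$metadata
    median(md$time[st == "high"]) > median(md$time[st == "low"])
  }, logical(1))
  expect_gte(mean(longer), 0.9)
})
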