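# Independent oracles, written as plainly as possible and kept separate
# from the implementation paths they check.

# Brute-force one-step fit: sort, loop every split, recompute everything
# from scratch via the fitted vector.
oracle_fit_step <- function(values) {
  x <- sort(values)
  n <- length(x)
  best <- NULL
  for (k in 1:(n - 1)) {
    mu1 <- mean(x[1:k])
    mu2 <- mean(x[(k + 1):n])
    fitted <- c(rep(mu1, k), rep(mu2, n - k))
    sse <- sum((x - fitted)^2)
    if (is.null(best) || sse < best$sse_step) {
      best <- list(k = k, mu_low = mu1, mu_high = mu2, sse_step = sse,
                   threshold = (mu1 + mu2) / 2)
    }
  }
  best$sse_null <- sum((x - mean(x))^2)
  best
}

# AUC by explicit enumeration of every positive-negative pair.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Step-up BH from the definition: adj_(i) = min over j >= i of
# min(1, n * p_(j) / j), mapped back to input order.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) min(1, n * p[ord[j]] / j), numeric(1))
    adj_sorted[i] <- min(vals)
  }
  adj <- numeric(n)
  adj[ord] <- adj_sorted
  adj
}

# OLS coefficients straight from the normal equations.
oracle_ols_coef <- function(X, y) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Two-group log-rank by observed-minus-expected enumeration at each
# distinct event time; returns the 1-df chi-square.
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == tt)
    d1 <- sum(event == 1 & time == tt & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# Small, fast synthetic world shared by recovery-style tests.
small_config <- function(seed, fold = 4, n_genes = 300,
                         samples_per_group = 10) {
  synthetic_config(n_genes = n_genes, n_signature_genes = 29,
                   samples_per_group = samples_per_group,
                   signature_fold = fold, seed = seed)
}

cohort_expression <- function(cohort) {
  log_transform(tpm(cohort$counts, cohort$gene_lengths))
}
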