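# Differential CS-usage statistics: chi-square, BH-FDR, PUI, direction
# classification and the global trend test, checked against independent
# arithmetic oracles and calibration simulations.

make_table <- function(counts, conditions, gene_id = "utr1", strand = "+") {
  colnames(counts) <- names(conditions)
  list(gene_id = gene_id, positions = seq_len(nrow(counts)) * 100L,
       strand = strand, counts = counts, conditions = conditions)
}
cond2 <- c(s_ctl = "control", s_trt = "treated")

# Independent Pearson chi-square oracle: sum((O-E)^2/E) from margins.
oracle_chisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# Independent textbook BH step-up oracle.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m); out[o] <- pmin(q, 1)
  out
}

test_that("chi-square matches the direct formula oracle on worked tables", {
  flat <- make_table(matrix(c(50, 50, 50, 50), 2), cond2)
  r <- chisq_apa_test(flat, "control", "treated")
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)

  m <- matrix(c(90, 10, 10, 90), 2)
  r2 <- chisq_apa_test(make_table(m, cond2), "control", "treated")
  expect_equal(r2$chi2, oracle_chisq(m))
  expect_equal(r2$chi2, 128)
  expect_lt(r2$p, 1e-20)
  expect_equal(r2$df, 1L)

  m3 <- matrix(c(20, 30, 50, 40, 60, 100), 3)   # identical proportions
  r3 <- chisq_apa_test(make_table(m3, cond2), "control", "treated")
  expect_equal(r3$p, 1)
  expect_equal(r3$df, 2L)
})

test_that("chi-square flags low expected counts and rejects empty conditions", {
  low <- make_table(matrix(c(3, 2, 4, 1), 2), cond2)
  expect_true(chisq_apa_test(low, "control", "treated")$low_expected)
  zero <- make_table(matrix(c(0, 0, 10, 20), 2), cond2)
  expect_error(chisq_apa_test(zero, "control", "treated"), "zero total")
})

test_that("BH adjustment reproduces the textbook step-up arithmetic", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_equal(bh_fdr(p), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NaN)), "NaN")
  set.seed(1)
  for (i in 1:20) {
    pr <- runif(sample(2:50, 1))
    q <- bh_fdr(pr)
    expect_equal(q, oracle_bh(pr))
    expect_true(all(q >= pr))                       # q >= p elementwise
    expect_equal(order(q[order(pr)]), seq_along(q)) # monotone in p
  }
})

test_that("PUI is the proximal fraction of the UTR's reads", {
  tb <- make_table(matrix(c(30, 70, 30, 70), 2), cond2)
  expect_equal(compute_pui(tb, sample = "s_ctl"), 0.3)
  tb2 <- make_table(matrix(c(100, 0, 1, 0), 2), cond2)
  expect_equal(compute_pui(tb2, condition = "control"), 1)
  tb3 <- make_table(matrix(c(20, 30, 50, 0, 0, 0), 3), cond2)
  expect_equal(compute_pui(tb3, sample = "s_ctl"), 0.2)
  expect_true(is.na(compute_pui(tb3, sample = "s_trt")))
})

test_that("shift classification follows the sign of delta PUI", {
  up <- make_table(matrix(c(30, 70, 50, 50), 2), cond2)
  r <- classify_shift(up, "control", "treated")
  expect_equal(r$direction, "proximal_enhanced")
  expect_equal(r$delta_pui, 0.2)
  down <- make_table(matrix(c(50, 50, 30, 70), 2), cond2)
  expect_equal(classify_shift(down, "control", "treated")$direction,
               "proximal_reduced")
  same <- make_table(matrix(c(50, 50, 50, 50), 2), cond2)
  expect_equal(classify_shift(same, "control", "treated")$direction, "none")
})

test_that("direction agrees with an independent raw-count computation", {
  set.seed(8)
  sim <- simulate_usage_tables(n_utrs = 100, frac_shifted = 0.3, seed = 8)
  for (tb in sim$tables) {
    sh <- classify_shift(tb, "control", "treated")
    raw_a <- unname(tb$counts[1, 1] / sum(tb$counts[, 1]))
    raw_b <- unname(tb$counts[1, 2] / sum(tb$counts[, 2]))
    expect_equal(sign(sh$delta_pui), sign(raw_b - raw_a))
  }
})

test_that("UTR tables keep only multi-CS 3'UTRs, ordered proximal first", {
  sites <- data.frame(
    gene_id = c("gp", "gp", "gm", "gm", "solo", "cds1", "cds1"),
    pos = c(100L, 300L, 300L, 500L, 150L, 10L, 80L),
    strand = c("+", "+", "-", "-", "+", "+", "+"),
    category = c("3UTR", "3UTR", "3UTR", "3UTR", "3UTR", "CDS", "CDS"),
    stringsAsFactors = FALSE)
  counts <- matrix(5L, nrow = 7, ncol = 2,
                   dimnames = list(NULL, names(cond2)))
  tables <- build_utr_tables(sites, counts, cond2)
  expect_equal(sort(names(tables)), c("gm", "gp"))
  expect_equal(tables$gp$positions, c(100L, 300L))   # plus: proximal = left
  expect_equal(tables$gm$positions, c(500L, 300L))   # minus: proximal = right
  expect_error(build_utr_tables(sites, counts, c(s_ctl = "control")),
               "without condition")
})

test_that("the 20-vs-0 direction split matches the exact binomial oracle", {
  res <- data.frame(
    gene_id = sprintf("u%02d", 1:25),
    q = c(rep(0.01, 20), rep(0.8, 5)),
    direction = c(rep("proximal_enhanced", 20), rep("proximal_reduced", 5)),
    pui_a = runif(25), pui_b = runif(25), delta_pui = rnorm(25),
    stringsAsFactors = FALSE)
  tr <- global_trend_test(res)
  expect_equal(tr$n_enhanced, 20L)
  expect_equal(tr$n_reduced, 0L)
  expect_equal(tr$binomial_p_vs_half, 2 * 0.5^20)
  res2 <- res
  res2$direction <- rep(c("proximal_enhanced", "proximal_reduced"), c(10, 15))
  res2$q <- c(rep(0.01, 20), rep(0.8, 5))
  tr2 <- global_trend_test(res2)
  expect_equal(tr2$fraction_proximal_enhanced, 0.5)
  expect_equal(tr2$binomial_p_vs_half, 1)
})

test_that("null usage tables give calibrated p-values and no FDR calls", {
  # Quick calibration check (5 seeds); the full 20-seed version runs in the
  # acceptance suite.
  frac_sig <- numeric(5); n_fdr <- integer(5)
  for (s in 1:5) {
    sim <- simulate_usage_tables(n_utrs = 200, frac_shifted = 0, seed = 100 + s)
    res <- apa_test(sim$tables, "control", "treated")
    frac_sig[s] <- mean(res$p < 0.05)
    n_fdr[s] <- sum(res$q < 0.05)
  }
  expect_lt(mean(frac_sig), 0.09)
  expect_gt(mean(frac_sig), 0.015)
  expect_true(mean(n_fdr == 0) >= 0.8)
})

test_that("planted usage shifts are recovered with high recall", {
  sim <- simulate_usage_tables(n_utrs = 200, frac_shifted = 0.25,
                               delta_pui = 0.3, seed = 77)
  res <- apa_test(sim$tables, "control", "treated")
  called <- res$gene_id[res$q < 0.05]
  recall <- mean(sim$shifted %in% called)
  fdp <- if (length(called)) mean(!called %in% sim$shifted) else 0
  expect_gt(recall, 0.85)
  expect_lt(fdp, 0.15)
})
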