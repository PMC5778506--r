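# RNA-seq fold-change utilities and the IP-MS interactor filter.

test_that("RPKM matches the closed form and scales with library size", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  r <- rpkm(m, gene_lengths = c(1000, 2000), library_sizes = 1e6)
  expect_equal(unname(r[, 1]), c(10, 0))
  r2 <- rpkm(m, gene_lengths = c(1000, 2000), library_sizes = 2e6)
  expect_equal(unname(r2[, 1]), c(5, 0))
  set.seed(3)
  cm <- matrix(rpois(40, 50), 10, 4)
  lens <- sample(200:2000, 10)
  expect_equal(rpkm(cm, lens, rep(2e6, 4)), rpkm(cm, lens, rep(1e6, 4)) / 2)
  expect_error(rpkm(cm, lens, c(0, 1, 1, 1)), "library sizes")
  expect_error(rpkm(cm, rep(0, 10)), "lengths")
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(6, 4, 5))
  qn <- quantile_normalize(m)
  expect_equal(sort(qn[, "a"]), sort(qn[, "b"]), ignore_attr = TRUE)
  expect_equal(unname(sort(qn[, "a"])), c(2.5, 3.5, 4.5))
  # Rank order within columns is preserved.
  expect_equal(order(qn[, "b"]), order(m[, "b"]))
})

test_that("quantile normalization is idempotent and fixes identical columns", {
  set.seed(5)
  m <- matrix(rlnorm(200), 50, 4)
  qn <- quantile_normalize(m)
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]))
  same <- matrix(rep(m[, 1], 3), ncol = 3)
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)
  expect_equal(quantile_normalize(m[, 1, drop = FALSE]), m[, 1, drop = FALSE])
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("fold-change floors lowly expressed genes before the ratio", {
  expect_equal(log2_fold_change(0.5, 4), 2)      # floor control to 1.0
  expect_equal(log2_fold_change(0.2, 0.2), 0)    # both floored
  expect_equal(log2_fold_change(2, 8), 2)
  set.seed(6)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
  expect_error(log2_fold_change(1:3, 1:4), "match")
})

test_that("interactor selection respects >2-fold in at least 2 of 3 replicates", {
  mk <- function(diffs) {
    ctl <- matrix(20, nrow = nrow(diffs), ncol = ncol(diffs),
                  dimnames = list(rownames(diffs), NULL))
    list(ref = ctl + diffs, ctl = ctl)
  }
  diffs <- rbind(pA = c(1.5, 1.2, 0.3),   # 2 passes -> selected
                 pB = c(1.5, 0.8, 0.9),   # 1 pass  -> not
                 pC = c(1.0, 1.0, 1.0),   # strict >: not selected
                 pD = c(2.0, 2.0, 2.0))
  x <- mk(diffs)
  res <- call_interactors(x$ref, x$ctl)
  expect_equal(res$selected[match(c("pA", "pB", "pC", "pD"), res$protein_id)],
               c(TRUE, FALSE, FALSE, TRUE))
  # Missing intensity counts as a failing replicate.
  ref_na <- x$ref; ref_na["pD", 2:3] <- NA
  res_na <- call_interactors(ref_na, x$ctl)
  expect_false(res_na$selected[res_na$protein_id == "pD"])
})

test_that("planted interactors are recovered exactly on synthetic matrices", {
  aux <- simulate_aux_matrices(n_proteins = 150, interactor_shift = 2,
                               noise_sd = 0.15, seed = 12)
  res <- call_interactors(aux$ipms$log2_ref, aux$ipms$log2_ctl)
  expect_equal(sort(res$protein_id[res$selected]), aux$ipms$interactors)
})

test_that("edge classification separates phospho-only from shared interactors", {
  phospho <- data.frame(protein_id = c("P1", "P2", "P3"),
                        selected = c(TRUE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  total <- data.frame(protein_id = c("P1", "P2", "P3"),
                      selected = c(FALSE, TRUE, TRUE),
                      stringsAsFactors = FALSE)
  ed <- interactor_edges(phospho, total)
  expect_equal(ed$target, c("P1", "P2"))
  expect_equal(ed$class, c("phospho_only", "phospho_and_total"))
  expect_equal(unique(ed$source), "pPABPN1")
})
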