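test_that("RPKM follows the direct formula and its scale invariances", {
  expect_equal(compute_rpkm(100, 1e7, 1000), 10)
  expect_equal(compute_rpkm(0, 1e7, 500), 0)
  # doubling count and library together leaves RPKM unchanged
  expect_equal(compute_rpkm(2 * 137, 2 * 3.1e6, 842),
               compute_rpkm(137, 3.1e6, 842))
  expect_error(compute_rpkm(5, 0, 100), "library total")
  expect_error(compute_rpkm(5, 1e6, 0), "length_bp")
  expect_error(compute_rpkm(10, 5, 100), "k <= n")
})

test_that("presence classes follow the detection threshold", {
  expect_equal(classify_presence(0, 25, 1), "ct_only")
  expect_equal(classify_presence(10, 10, 1), "both")
  expect_equal(classify_presence(0, 0, 1), "absent")
  expect_equal(classify_presence(c(3, 0, 5, 0), c(0, 4, 6, 0), 1),
               c("ck_only", "ct_only", "both", "absent"))
  # raising the threshold demotes low-count genes
  expect_equal(classify_presence(3, 12, min_count = 5), "ct_only")
  expect_error(classify_presence(-1, 3), "nonnegative")
})

test_that("MA-plot random-sampling test: null, signal and swap symmetry", {
  # equal proportions across unequal libraries sit on the null
  r <- mars_test(50, 1e6, 100, 2e6)
  expect_lt(abs(r$z), 1e-8)
  expect_gt(r$p, 0.9)
  # a 4-fold difference at these depths is overwhelming
  r2 <- mars_test(200, 1e6, 50, 1e6)
  expect_gt(r2$z, 0)
  expect_lt(r2$p, 1e-6)
  # swapping the libraries negates M and preserves p
  r3 <- mars_test(50, 1e6, 200, 1e6)
  expect_equal(r3$M, -r2$M)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)
  expect_error(mars_test(0, 1e6, 5, 1e6), "exact_cond_test")
})

test_that("exact conditional test matches enumeration and binom.test", {
  # T = 3, symmetric libraries: only the two extreme outcomes qualify
  expect_equal(exact_cond_test(3, 1e5, 0, 1e5), 2 * 0.5^3)
  expect_equal(exact_cond_test(10, 1e5, 0, 1e5), 2 * 0.5^10)
  expect_equal(exact_cond_test(7, 1e5, 7, 1e5), 1)  # modal outcome
  expect_equal(exact_cond_test(0, 1e5, 0, 1e5), 1)  # T = 0 convention
  # minimum-likelihood two-sided p equals stats::binom.test
  cases <- expand.grid(k1 = c(0, 2, 5, 11), k2 = c(0, 3, 9),
                       n1 = 1e5, n2 = c(1e5, 3e5))
  cases <- cases[cases$k1 + cases$k2 > 0, ]
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      exact_cond_test(k1, n1, k2, n2),
      stats::binom.test(k1, k1 + k2, n1 / (n1 + n2))$p.value,
      tolerance = 1e-10))
  }
})

test_that("MARS agrees with the exact conditional oracle", {
  grid <- expand.grid(k1 = 1:50, k2 = 1:50)
  pm <- mars_test(grid$k1, 1e5, grid$k2, 1e5)$p
  pe <- exact_cond_test(grid$k1, 1e5, grid$k2, 1e5)
  expect_gte(cor(pm, pe, method = "spearman"), 0.99)
  # at counts >= 100 the approximation tracks the exact log p closely
  big <- expand.grid(k1 = seq(100, 2000, 100), k2 = seq(100, 2000, 100))
  pmb <- mars_test(big$k1, 1e5, big$k2, 1e5)$p
  peb <- exact_cond_test(big$k1, 1e5, big$k2, 1e5)
  keep <- peb < 0.5 & peb > 0 & pmb > 0    # away from p = 1 and underflow
  expect_gt(sum(keep), 100)
  rel <- abs(log(pmb[keep]) - log(peb[keep])) / abs(log(peb[keep]))
  expect_lte(max(rel), 0.1)
})

test_that("BH adjustment equals an independent brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (rep in 1:4) {
    p <- runif(4)
    perms <- matrix(unlist(lapply(combinat_perms(4), function(o) p[o])),
                    ncol = 4, byrow = TRUE)
    for (i in seq_len(nrow(perms)))
      expect_equal(bh_adjust(perms[i, ]), bh_brute(perms[i, ]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG status needs both the fold-change and the FDR criterion", {
  rec <- data.frame(log2fc = c(1.2, 0.9, -3.0, -1.5, 0),
                    q = c(1e-4, 1e-9, 0.01, 1e-5, 1e-9))
  out <- call_degs(rec)
  expect_equal(out$status,
               c("up", "no_change", "no_change", "down", "no_change"))
})

test_that("deg_table routes zero-count genes to the exact path", {
  ct <- count_table(data.frame(
    gene_id = c("a", "b", "c", "d"), length_bp = 1000,
    count_ck = c(400, 0, 80, 0), count_ct = c(100, 60, 80, 0)),
    n_ck = 1e6, n_ct = 1e6)
  d <- deg_table(ct)
  expect_equal(d$presence, c("both", "ct_only", "both", "absent"))
  expect_true(is.na(d$z[2]) && is.na(d$z[4]))
  expect_equal(d$p[2], exact_cond_test(60, 1e6, 0, 1e6))
  expect_equal(d$p[4], 1)
  expect_equal(d$status[4], "no_change")
  # gene a: 4-fold down in CT, tiny p -> down
  expect_equal(d$status[1], "down")
  expect_lt(d$log2fc[1], -1)
  # ct_only gene with 60 reads: infinite fold change, significant -> up
  expect_equal(d$status[2], "up")
})
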