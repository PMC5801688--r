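test_that("mutation-dependent threshold is the midpoint of group medians", {
  t1 <- compute_threshold(c(-2, -2, 0, 0), c(1, 1, 0, 0))
  expect_equal(t1$med_mt, -2)
  expect_equal(t1$med_wt, 0)
  expect_equal(t1$thres, -1)
  expect_identical(t1$direction, "sensitivity")
  expect_false(t1$degenerate)

  # even-count groups use the midpoint of the two central order statistics
  t2 <- compute_threshold(c(1, 3, 0, 0), c(1, 1, 0, 0))
  expect_equal(t2$med_mt, 2)
  expect_equal(t2$thres, 1)
  expect_identical(t2$direction, "resistance")

  # exact tie of medians falls to the resistance branch, flagged degenerate
  t3 <- compute_threshold(c(0, 0, 0, 0), c(1, 0, 1, 0))
  expect_equal(t3$thres, 0)
  expect_identical(t3$direction, "resistance")
  expect_true(t3$degenerate)

  expect_error(compute_threshold(c(1, 2), c(1, 1)), "wild-type")
  expect_error(compute_threshold(c(1, NA), c(1, 0)), "finite")
  expect_error(compute_threshold(1, 1), "at least two")
})

test_that("contingency table counts mutation status against threshold side", {
  y <- c(-2, -2, 0, 0); fl <- c(1, 1, 0, 0)
  tab <- build_contingency(y, fl, compute_threshold(y, fl))
  expect_equal(with(tab, c(tp, fn, fp, tn)), c(2, 0, 0, 2))

  # degenerate tie: all cells sit at the threshold, >= puts all on the
  # positive (resistant) side
  y2 <- c(0, 0, 0, 0); fl2 <- c(1, 0, 1, 0)
  tab2 <- build_contingency(y2, fl2, compute_threshold(y2, fl2))
  expect_equal(with(tab2, c(tp, fn, fp, tn)), c(2, 2, 0, 0))

  # counts always partition the cells
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:80, 1)
    y <- rnorm(n)
    fl <- c(1, 0, rbinom(n - 2, 1, 0.4))
    tab <- build_contingency(y, fl, compute_threshold(y, fl))
    expect_equal(tab$n, n)
    expect_equal(tab$tp + tab$fp, sum(fl))   # predicted positives = mutants
  }
})

test_that("phi follows the MCC formula and its symmetries", {
  expect_equal(phi_coefficient(contingency2x2(10, 0, 0, 10)), 1.0)
  expect_equal(phi_coefficient(contingency2x2(5, 5, 5, 5)), 0.0)
  expect_equal(phi_coefficient(contingency2x2(8, 2, 2, 8)), 0.6)
  expect_error(phi_coefficient(contingency2x2(5, 0, 5, 0)), "marginal")

  # swapping (TP<->FN, FP<->TN) negates phi
  set.seed(2)
  for (i in 1:200) {
    tab <- random_table()
    swapped <- contingency2x2(tab$fn, tab$tp, tab$tn, tab$fp)
    if (with(swapped, any(c(tp + fn, fn + tn, tn + fp, fp + tp) == 0))) next
    expect_equal(phi_coefficient(swapped), -phi_coefficient(tab))
  }

  # tables from the mutation-dependent threshold with distinct medians
  # never give negative phi
  set.seed(3)
  for (i in 1:200) {
    n <- sample(6:100, 1)
    y <- rnorm(n) + sample(c(-1, 0, 1), 1)
    fl <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.1, 0.6)))
    thr <- compute_threshold(y, fl)
    if (thr$degenerate) next
    expect_gte(phi_coefficient(build_contingency(y, fl, thr)), 0)
  }
})

test_that("chi-squared from the O/E sum equals n * phi^2", {
  expect_equal(chi2_statistic(contingency2x2(5, 5, 5, 5)), 0.0)
  expect_equal(chi2_statistic(contingency2x2(8, 2, 2, 8)), 7.2)
  expect_error(chi2_statistic(contingency2x2(0, 0, 3, 5)), "expected count")

  set.seed(4)
  for (i in 1:1000) {
    tab <- random_table()
    chi2 <- chi2_statistic(tab)
    ident <- tab$n * phi_coefficient(tab)^2
    expect_lt(abs(chi2 - ident), 1e-10 * max(ident, 1e-300))
  }
})

test_that("p-values are stable upper-tail df=1 probabilities", {
  expect_equal(chi2_pvalue(0), 1.0)
  expect_equal(chi2_pvalue(3.841), 0.05, tolerance = 1e-3)
  # extreme statistics stay representable instead of underflowing to 0
  expect_gt(chi2_pvalue(1300), 0)
  expect_lt(chi2_pvalue(1300), 1e-280)
  # strictly decreasing in chi2
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(chi2_pvalue(x)) < 0))
  expect_error(chi2_pvalue(-1), "non-negative")
})

test_that("BH step-up matches its oracles and reports the critical value", {
  r <- bh_fdr(c(0.001, 0.01, 0.02, 0.5), q = 0.2)
  expect_equal(r$n_significant, 3L)
  expect_equal(r$critical, 0.02)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, FALSE))

  expect_equal(bh_fdr(rep(1, 5), q = 0.2)$n_significant, 0L)
  expect_true(is.na(bh_fdr(rep(1, 5), q = 0.2)$critical))
  r1 <- bh_fdr(0.04, q = 0.2)
  expect_true(r1$significant)
  expect_equal(r1$critical, 0.04)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(0.5, q = 1), "\\(0, 1\\)")

  # random vectors: mask must agree with p.adjust, critical with the
  # explicit step-up definition
  set.seed(5)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 3, 17), 1))  # induce ties sometimes
    q <- runif(1, 0.01, 0.5)
    r <- bh_fdr(p, q)
    expect_identical(r$significant, p.adjust(p, "BH") <= q)
    if (r$n_significant > 0)
      expect_equal(r$critical, max(p[r$significant]))
  }
})

test_that("phi significance cutoff inverts chi2 = n phi^2 and scales as 1/sqrt(n)", {
  crit <- 0.00940155
  expect_equal(round(phi_significance_cutoff(300, crit), 2), 0.15)
  expect_equal(round(phi_significance_cutoff(450, crit), 2), 0.12)
  n0 <- 173
  expect_equal(phi_significance_cutoff(4 * n0, crit),
               phi_significance_cutoff(n0, crit) / 2)
  # any table at this n with phi >= cutoff is significant at critical_p
  set.seed(6)
  for (i in 1:100) {
    tab <- random_table()
    cutoff <- phi_significance_cutoff(tab$n, crit)
    if (abs(phi_coefficient(tab)) >= cutoff)
      expect_lte(chi2_pvalue(chi2_statistic(tab)), crit + 1e-12)
  }
  expect_error(phi_significance_cutoff(1, 0.05), ">= 2")
  expect_error(phi_significance_cutoff(10, 0), "\\(0, 1\\)")
})

test_that("shifting all responses by a constant moves only the threshold", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    y <- rnorm(n)
    fl <- c(1, 0, rbinom(n - 2, 1, 0.3))
    cst <- runif(1, -5, 5)
    a <- association_test(y, fl)
    b <- association_test(y + cst, fl)
    expect_equal(b$threshold$thres, a$threshold$thres + cst)
    expect_equal(b$threshold$med_mt, a$threshold$med_mt + cst)
    expect_identical(with(b$table, c(tp, fn, fp, tn)),
                     with(a$table, c(tp, fn, fp, tn)))
    expect_equal(b$phi, a$phi)
    expect_equal(b$chi2, a$chi2)
    expect_equal(b$p, a$p)
  }
})

test_that("for a common n, phi and -log p are perfectly rank-correlated", {
  set.seed(8)
  n <- 200
  phis <- numeric(0); ps <- numeric(0)
  for (i in 1:60) {
    y <- rnorm(n) - 0.8 * runif(1) * rbinom(1, 1, 0.5)
    fl <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.1, 0.5)))
    y <- y + runif(1, 0, 1.2) * fl * sample(c(-1, 1), 1)
    a <- association_test(y, fl)
    phis <- c(phis, a$phi); ps <- c(ps, a$p)
  }
  keep <- !duplicated(phis)
  expect_equal(suppressWarnings(
    cor(phis[keep], -log(ps[keep]), method = "spearman")), 1)
})
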