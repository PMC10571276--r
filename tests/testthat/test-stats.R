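# CLES, Kruskal-Wallis/Conover, Mann-Whitney screen and contingency post hoc.

brute_cles <- function(x, y) {
  (sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))) /
    (length(x) * length(y))
}

test_that("CLES matches pair enumeration, including ties", {
  expect_equal(cles(c(1, 2, 3), c(4, 5, 6)), 0.0)
  expect_equal(cles(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(cles(c(1, 3), c(2, 4)), 0.25)
  expect_error(cles(numeric(0), 1), "empty")
  set.seed(99)
  for (i in 1:50) {
    x <- sample(0:5, sample(1:20, 1), replace = TRUE)
    y <- sample(0:5, sample(1:20, 1), replace = TRUE)
    expect_identical(cles(x, y), brute_cles(x, y))
    expect_equal(cles(x, y) + cles(y, x), 1)
  }
})

test_that("Kruskal-Conover detects the displaced group, hand case", {
  g <- list(a = c(1, 1, 1), b = c(9, 9, 9), c = c(9, 9, 9.1))
  res <- kruskal_conover(g)
  # chi-square-approximate omnibus on n = 9 with heavy ties: p ~= 0.030
  expect_lt(res$omnibus_p, 0.05)
  expect_equal(res$omnibus_p,
               stats::kruskal.test(unlist(g),
                                   factor(rep(names(g), lengths(g))))$p.value)
  expect_lt(res$pairwise_p["a", "b"], 0.05)
  expect_lt(res$pairwise_p["a", "c"], 0.05)
  expect_gt(res$pairwise_p["b", "c"], 0.2)
  # direction via CLES
  expect_equal(res$cles["a", "b"], 0)
  expect_equal(res$cles["b", "a"], 1)
  expect_error(kruskal_conover(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Kruskal-Conover results permute consistently with group order", {
  set.seed(5)
  g <- list(x = rnorm(12), y = rnorm(12, 1), z = rnorm(12, 2))
  r1 <- kruskal_conover(g)
  r2 <- kruskal_conover(g[c(3, 1, 2)])
  expect_equal(r1$omnibus_p, r2$omnibus_p)
  for (a in names(g)) for (b in names(g)) {
    expect_equal(r1$pairwise_p[a, b], r2$pairwise_p[a, b])
    expect_equal(r1$cles[a, b], r2$cles[a, b])
  }
})

test_that("Kruskal-Wallis omnibus holds its type-I error under the null", {
  set.seed(314)
  reps <- 400
  rej <- 0
  for (i in seq_len(reps)) {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    if (kruskal_conover(g)$omnibus_p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
})

test_that("Mann-Whitney screen applies BH jointly and flags directions", {
  set.seed(21)
  n <- 30
  rec <- data.frame(
    chem_class = rep(c("Benzenoids", "Other"), each = n),
    permanence_label = rep(c("Lingerer", "Traverser"), times = n),
    p1 = rnorm(2 * n), p2 = rnorm(2 * n), stringsAsFactors = FALSE)
  # identical distributions -> nothing significant
  res <- mannwhitney_bh(rec, c("p1", "p2"))
  expect_true(all(res$direction %in% c("ns", "not_tested")))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))  # BH monotonicity
  # one cell with disjoint supports becomes significant after BH
  rec2 <- rec
  shift <- rec2$chem_class == "Benzenoids" & rec2$permanence_label == "Lingerer"
  rec2$p1[shift] <- rec2$p1[shift] + 100
  res2 <- mannwhitney_bh(rec2, c("p1", "p2"))
  sig <- res2[res2$direction %in% c("higher", "lower"), ]
  expect_equal(nrow(sig), 1L)
  expect_equal(sig$class, "Benzenoids")
  expect_equal(sig$property, "p1")
  expect_equal(sig$direction, "higher")
  # a class absent from one group is not tested
  rec3 <- rbind(rec, data.frame(chem_class = "Hydrocarbons",
                                permanence_label = "Lingerer",
                                p1 = 1, p2 = 1))
  res3 <- mannwhitney_bh(rec3, c("p1", "p2"))
  expect_true(all(res3$direction[res3$class == "Hydrocarbons"] == "not_tested"))
})

test_that("BH and Bonferroni agree with naive reference implementations", {
  naive_bonf <- function(p) pmin(1, p * length(p))
  naive_bh <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(stats::p.adjust(p, "bonferroni"), naive_bonf(p))
    expect_equal(stats::p.adjust(p, "BH"), naive_bh(p))
  }
})

test_that("contingency post hoc: residual identity, exact p, margins", {
  # all-equal table: zero residuals, nothing significant
  o <- matrix(5L, 2, 2)
  r <- contingency_posthoc(o)
  expect_true(all(abs(r$adjusted_residuals) < 1e-12))
  expect_false(any(r$significant))
  # 2x2 identity: every squared adjusted residual equals Pearson chi-square
  set.seed(1234)
  for (i in 1:30) {
    o <- matrix(rpois(4, 12) + 1L, 2, 2)
    r <- contingency_posthoc(o)
    chi2 <- suppressWarnings(stats::chisq.test(o, correct = FALSE)$statistic)
    expect_equal(unname(as.vector(r$adjusted_residuals^2)),
                 rep(unname(chi2), 4), tolerance = 1e-9)
  }
  # hypergeometric enumeration oracle for the diagonal table
  o <- matrix(c(10L, 0L, 0L, 10L), 2, 2)
  r <- contingency_posthoc(o)
  p_exact <- sum(stats::dhyper(0:10, 10, 10, 10)[
    stats::dhyper(0:10, 10, 10, 10) <= stats::dhyper(10, 10, 10, 10) + 1e-12])
  expect_equal(r$cell_pvalues[1, 1], p_exact, tolerance = 1e-10)
  expect_equal(r$cell_pvalues[1, 1], 1.083e-5, tolerance = 1e-3)
  # all four collapses coincide for a 2x2
  expect_true(all(abs(r$cell_pvalues - r$cell_pvalues[1, 1]) < 1e-12))
  expect_equal(r$direction[1, 1], "over")
  expect_equal(r$direction[1, 2], "under")
  # margin conservation on random tables
  set.seed(77)
  for (i in 1:100) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    o <- matrix(rpois(nr * nc, 8), nr, nc)
    if (sum(o) == 0) next
    r <- contingency_posthoc(o)
    diff <- r$observed - r$expected
    expect_true(all(abs(rowSums(diff)) < 1e-9))
    expect_true(all(abs(colSums(diff)) < 1e-9))
    expect_true(all(r$direction[r$significant] != "none"))
  }
  # zero margin -> untestable cells flagged, no crash
  o <- matrix(c(0L, 0L, 5L, 7L, 3L, 4L), 2, 3)
  r0 <- contingency_posthoc(o)
  expect_true(anyNA(r0$cell_pvalues))
  expect_error(contingency_posthoc(matrix(1L, 1, 3)), "2x2")
})

test_that("tidy_contingency emits one labelled row per cell", {
  o <- matrix(c(10L, 2L, 3L, 9L), 2, 2,
              dimnames = list(c("Gut", "DrugBank"), c("acid", "neutral")))
  td <- tidy_contingency(contingency_posthoc(o))
  expect_equal(nrow(td), 4L)
  expect_setequal(td$row, c("Gut", "DrugBank"))
  expect_equal(sum(td$observed), sum(o))
})
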