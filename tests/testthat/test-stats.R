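test_that("one-way ANOVA matches hand and brute-force sums of squares", {
  r <- oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(r$f_stat, 3)           # SSB = 6 / dfB 2, SSW = 6 / dfW 6
  expect_equal(r$df_between, 2L)
  expect_equal(r$df_within, 6L)

  same <- oneWayAnova(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_equal(same$f_stat, 0)

  # two groups: F equals the square of the pooled t statistic
  x <- c(1.2, 0.8, 1.7, 0.4); y <- c(2.2, 2.9, 1.4)
  f2 <- oneWayAnova(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(f2$f_stat, unname(tt$statistic)^2)

  set.seed(8)
  for (k in 1:20) {
    g <- lapply(seq_len(sample(2:5, 1)),
                function(i) rnorm(sample(3:8, 1)))
    names(g) <- paste0("g", seq_along(g))
    expect_equal(oneWayAnova(g)$f_stat, anovaOracle(g),
                 tolerance = 1e-10)
  }

  expect_error(oneWayAnova(list(a = 1, b = c(1, 2))), ">= 2 observations")
  expect_error(oneWayAnova(list(a = c(1, 1), b = c(1, 1))), "degenerate")
})

test_that("Tukey HSD emits all pairs with label-permutation symmetry", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  tk <- tukeyHsd(g)
  expect_equal(nrow(tk), 3L)  # k(k-1)/2
  expect_equal(tk$diff, rep(0, 3))
  expect_equal(tk$p_adj, rep(1, 3))

  set.seed(9)
  g2 <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2), d = rnorm(6))
  tk2 <- tukeyHsd(g2)
  expect_equal(nrow(tk2), 6L)
  # swapping two group labels permutes rows but leaves statistics unchanged
  g3 <- g2[c(2, 1, 3, 4)]
  tk3 <- tukeyHsd(g3)
  key2 <- paste(pmin(tk2$group_a, tk2$group_b),
                pmax(tk2$group_a, tk2$group_b))
  key3 <- paste(pmin(tk3$group_a, tk3$group_b),
                pmax(tk3$group_a, tk3$group_b))
  expect_equal(sort(key2), sort(key3))
  expect_equal(abs(tk2$diff[order(key2)]), abs(tk3$diff[order(key3)]))
  expect_equal(tk2$p_adj[order(key2)], tk3$p_adj[order(key3)])
})

test_that("pairwise t defaults to Welch and handles degenerate variance", {
  pt <- pairwiseT(list(x = c(1, 2, 3), y = c(2, 3, 4)))
  expect_equal(pt$statistic, -sqrt(1.5), tolerance = 1e-6)  # |t| = 1.2247
  expect_equal(pt$diff, -1)

  same <- pairwiseT(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(pairwiseT(list(x = c(0, 0, 0), y = c(1, 1, 1))),
               "degenerate variance")

  # Holm correction is exposed and never smaller than raw p
  set.seed(10)
  g <- list(a = rnorm(5), b = rnorm(5, 2), c = rnorm(5))
  ph <- pairwiseT(g, correction = "holm")
  expect_true(all(ph$p_adj >= ph$p_value - 1e-15))
})

test_that("Pearson chi-squared reproduces the published quadrant statistic", {
  tab <- as.matrix(retinaReferenceCounts("quadrants"))
  r <- chiSquaredTest(tab)
  expect_equal(r$chi2, 61.066, tolerance = 5e-4)
  expect_identical(r$dof, 15L)
  expect_lt(r$p_value, 0.0001)
  # expected counts conserve the observed margins
  expect_equal(rowSums(r$expected), rowSums(tab))
  expect_equal(colSums(r$expected), colSums(tab))
})

test_that("chi-squared matches the brute-force oracle and its invariances", {
  expect_equal(chiSquaredTest(rbind(c(10, 0), c(0, 10)))$chi2, 20)
  expect_equal(chiSquaredTest(rbind(c(3, 7), c(3, 7)))$chi2, 0)

  set.seed(12)
  for (k in 1:15) {
    tab <- matrix(rpois(sample(c(4, 6, 8), 1), 20) + 1,
                  nrow = 2)
    r <- chiSquaredTest(tab)
    expect_equal(r$chi2, chi2Oracle(tab), tolerance = 1e-10)
    expect_identical(r$dof, as.integer((nrow(tab) - 1) * (ncol(tab) - 1)))
    # permutation invariance
    perm <- tab[sample(nrow(tab)), sample(ncol(tab)), drop = FALSE]
    expect_equal(chiSquaredTest(perm)$chi2, r$chi2)
    # homogeneity: scaling counts by k scales chi2 by k
    expect_equal(chiSquaredTest(3 * tab)$chi2, 3 * r$chi2)
  }

  expect_error(chiSquaredTest(rbind(c(0, 0), c(1, 2))), "positive sum")
  expect_error(chiSquaredTest(rbind(c(-1, 2), c(1, 2))), "non-negative")
})
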