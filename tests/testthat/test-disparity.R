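# Sum of variances, bootstrap, Mann-Whitney, Bonferroni, group tests.

test_that("sum_of_variances matches hand computations", {
  sc <- rbind(a = c(0, 0), b = c(2, 0))
  expect_equal(sum_of_variances(sc), 2.0)
  sc3 <- rbind(a = c(0, 0), b = c(1, 1), c = c(2, 0))
  expect_equal(sum_of_variances(sc3), 1 + 1 / 3)
  expect_warning(v1 <- sum_of_variances(sc, "a"), "fewer than 2")
  expect_equal(v1, 0)
  expect_equal(sum_of_variances(rbind(a = c(1, 1), b = c(1, 1))), 0)
  expect_error(sum_of_variances(sc, c("a", "zz")), "zz")
})

test_that("sum_of_variances is rotation-invariant and trace-conserving", {
  set.seed(13)
  sc <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("s", 1:10), NULL))
  sov <- sum_of_variances(sc)
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))
  expect_equal(sum_of_variances(sc %*% q), sov, tolerance = 1e-9)
  ord <- pca(sc)
  expect_equal(sum(ord$eigenvalues), sov, tolerance = 1e-9)
  expect_equal(sum_of_variances(ord$scores), sov, tolerance = 1e-9)
})

test_that("bootstrap_disparity is reproducible, sized, and mean-biased as (n-1)/n", {
  sc <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
  b1 <- bootstrap_disparity(sc, n_boot = 100, seed = 7)
  b2 <- bootstrap_disparity(sc, n_boot = 100, seed = 7)
  expect_length(b1, 100)
  expect_identical(b1, b2)
  expect_false(identical(b1, bootstrap_disparity(sc, n_boot = 100, seed = 8)))
  # identical rows: all replicates zero
  flat <- matrix(1, 5, 3, dimnames = list(letters[1:5], NULL))
  expect_equal(unique(bootstrap_disparity(flat, n_boot = 50, seed = 1)), 0)
  expect_error(bootstrap_disparity(sc, n_boot = 0), "n_boot")
  # plug-in bias of the variance under resampling: E[replicate] ~ (n-1)/n * point
  n <- nrow(sc)
  point <- sum_of_variances(sc)
  big <- bootstrap_disparity(sc, n_boot = 10000, seed = 99)
  mc_se <- sd(big) / sqrt(length(big))
  expect_lt(abs(mean(big) - (n - 1) / n * point), 3 * mc_se)
})

test_that("mann_whitney_u exact p-values come from full enumeration", {
  r1 <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r1$W, 0)
  expect_equal(r1$p, 1 / 3)  # 2 / C(4,2) labelings as or more extreme
  expect_equal(r1$method, "exact")
  r2 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$W, 0)
  expect_equal(r2$p, 0.1)    # 2 / C(6,3)
  # identical samples (ties): approximate path, symmetric null
  r3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$method, "normal")
  expect_gt(r3$p, 0.95)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("mann_whitney_u agrees with wilcox.test on both code paths", {
  set.seed(17)
  for (rep in 1:20) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, 0.8)
    mine <- mann_whitney_u(x, y)
    ref <- wilcox_oracle(x, y)
    expect_equal(mine$W, ref$W)
    expect_equal(mine$p, ref$p, tolerance = 1e-12)
  }
  # large / tied samples: normal approximation with tie + continuity correction
  set.seed(18)
  for (rep in 1:10) {
    x <- round(rnorm(25), 1)
    y <- round(rnorm(30, 0.3), 1)
    mine <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("exact and normal Mann-Whitney p-values agree within 0.02 for samples of 6-12", {
  set.seed(19)
  for (rep in 1:30) {
    nx <- sample(6:9, 1)
    ny <- sample(6:9, 1)
    x <- rnorm(nx)
    y <- rnorm(ny, 0.5)
    exact <- mann_whitney_u(x, y, exact_max = 18L)$p
    approx <- mann_whitney_u(x, y, exact_max = 0L)$p
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("bonferroni_adjust multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 4), 1.0)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_equal(bonferroni_adjust(c(0.01, 0.04)), c(0.02, 0.08))
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), ">=")
})

test_that("compare_disparities detects a constructed dispersion difference", {
  set.seed(21)
  scores <- rbind(
    matrix(rnorm(30 * 2, sd = 1), 30, 2),
    matrix(rnorm(30 * 2, sd = 2), 30, 2)
  )
  rownames(scores) <- paste0("s", 1:60)
  groups <- setNames(rep(c("narrow", "wide"), each = 30), rownames(scores))
  res <- compare_disparities(scores, groups, n_boot = 100, seed = 42)
  est <- setNames(res$groups$sum_of_variances, res$groups$group)
  expect_gt(est["wide"], est["narrow"])
  expect_lt(res$tests$p_adj[1], 0.001)
  expect_equal(lengths(res$boot), c(narrow = 100L, wide = 100L))
  # reproducibility for a fixed seed
  res2 <- compare_disparities(scores, groups, n_boot = 100, seed = 42)
  expect_identical(res$boot, res2$boot)
})

test_that("compare_disparities handles self-comparison, degeneracy and small groups", {
  set.seed(22)
  sc <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  # a group compared against itself (duplicated membership): identical
  # bootstrap replicates, so the test is an exact tie with p = 1
  ids <- rownames(sc)[1:10]
  res <- compare_disparities(sc, list(a = ids, b = ids), n_boot = 50,
                             seed = 5)
  expect_identical(res$boot$a, res$boot$b)
  expect_equal(res$tests$p_adj[1], 1)
  # identical points in both groups: zero disparity, test flagged degenerate
  flat <- matrix(1, 10, 2, dimnames = list(paste0("f", 1:10), NULL))
  fg <- setNames(rep(c("a", "b"), each = 5), rownames(flat))
  resf <- compare_disparities(flat, fg, n_boot = 20, seed = 1)
  expect_equal(resf$groups$sum_of_variances, c(0, 0))
  expect_true(all(resf$tests$degenerate))
  # small group warned and excluded from testing
  g3 <- setNames(c(rep("a", 9), rep("b", 9), "c", "c"), rownames(sc))
  expect_warning(res3 <- compare_disparities(sc, g3, n_boot = 20, seed = 2),
                 "minimum size")
  expect_false(res3$groups$tested[res3$groups$group == "c"])
  expect_equal(nrow(res3$tests), 1L)
  expect_error(compare_disparities(sc, setNames(rep("a", 20), rownames(sc)),
                                   n_boot = 10),
               ">= 2 groups")
})

test_that("pairwise_group_means matches the pooled-SD hand computation and pairwise.t.test", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("g1", "g2"), each = 3)
  res <- pairwise_group_means(vals, grp)
  expect_equal(res$t, -3 / (1 * sqrt(2 / 3)), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(res$t), 4), tolerance = 1e-12)
  # identical groups: t = 0, adjusted p = 1
  res0 <- pairwise_group_means(c(1, 2, 3, 1, 2, 3), grp)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_adj, 1)
  # three groups: Bonferroni multiplier 3, matches stats::pairwise.t.test
  set.seed(25)
  vals3 <- rnorm(18)
  grp3 <- rep(c("a", "b", "c"), each = 6)
  res3 <- pairwise_group_means(vals3, grp3)
  expect_equal(res3$p_adj, pmin(1, res3$p * 3))
  ref <- pairwise.t.test(vals3, grp3, p.adjust.method = "bonferroni",
                         pool.sd = TRUE)
  expect_equal(res3$p_adj[res3$group1 == "a" & res3$group2 == "b"],
               ref$p.value["b", "a"], tolerance = 1e-12)
  expect_equal(res3$p_adj[res3$group1 == "b" & res3$group2 == "c"],
               ref$p.value["c", "b"], tolerance = 1e-12)
  # welch variant agrees with t.test
  resw <- pairwise_group_means(vals, grp, method = "welch")
  reft <- t.test(vals[1:3], vals[4:6])
  expect_equal(resw$t, unname(reft$statistic), tolerance = 1e-12)
  expect_equal(resw$df, unname(reft$parameter), tolerance = 1e-12)
  expect_warning(pairwise_group_means(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "c")),
                 "excluded")
})

test_that("pearson_correlation matches the covariance-formula oracle and cor.test", {
  r <- pearson_correlation(1:4, 2 * (1:4) + 1)
  expect_equal(r$R, 1)
  expect_equal(r$p, 0)
  x <- c(1, 2, 3, 4)
  y <- c(1, -1, 1, -1)
  r2 <- pearson_correlation(x, y)
  expect_equal(r2$R, -1 / sqrt(5), tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(r2$R, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_correlation(1:2, 2:3), "n >= 3")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "constant")
})
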