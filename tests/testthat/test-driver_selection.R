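test_that("pearsonR matches hand-worked values and flags importance", {
  expect_equal(pearsonR(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearsonR(c(1, 2, 3), c(3, 2, 1))$r, -1.0)
  p <- pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(p$r, 0.8)
  expect_true(p$important)
  expect_false(pearsonR(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5.2))$r > 1)
  expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearsonR(1:3, 1:4), "equal length")
})

test_that("pearsonR is symmetric and shift/scale invariant with |r| <= 1", {
  set.seed(5)
  for (k in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    a <- pearsonR(x, y)$r
    expect_equal(pearsonR(y, x)$r, a)
    expect_equal(pearsonR(3 * x + 7, y)$r, a)
    expect_true(abs(a) <= 1)
  }
})

test_that("chiSquare reproduces worked tables", {
  z0 <- chiSquare(matrix(5, 2, 2))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$df, 1L)
  z <- chiSquare(matrix(c(10, 20, 20, 10), 2))
  expect_equal(z$statistic, 20 / 3, tolerance = 1e-3)
  z2 <- chiSquare(matrix(c(30, 0, 0, 30), 2))
  expect_equal(z2$statistic, 60)
  expect_lt(z2$p_value, 1e-10)
  expect_error(chiSquare(matrix(c(0, 0, 3, 4), 2)), "marginal")
})

test_that("chiSquare agrees with a brute-force loop and chisq.test", {
  bruteChi <- function(tab) {
    tot <- sum(tab); s <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / tot
      s <- s + (tab[i, j] - e)^2 / e
    }
    s
  }
  set.seed(17)
  for (k in 1:200) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 8) + 1, nr, nc)
    z <- chiSquare(tab)
    expect_equal(z$statistic, bruteChi(tab), tolerance = 1e-9)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(z$statistic, unname(ref$statistic))
    expect_equal(z$p_value, ref$p.value)
    expect_equal(z$df, (nr - 1L) * (nc - 1L))
    # expected marginals reproduce observed marginals
    expect_equal(rowSums(z$expected), rowSums(tab))
    expect_equal(colSums(z$expected), colSums(tab))
    # invariance under row/column permutation
    zp <- chiSquare(tab[sample(nr), sample(nc), drop = FALSE])
    expect_equal(zp$statistic, z$statistic)
  }
})

test_that("pcaSelect retains 9 PCs for 10 exactly uncorrelated drivers", {
  X <- orthogonalDrivers(10)
  rep <- pcaSelect(X)
  expect_equal(rep$eigenvalues, rep(1, 10))
  expect_equal(rep$proportion, rep(0.1, 10))
  # cumulative hits 0.80 exactly at k = 8; strict > needs k = 9
  expect_equal(rep$retainedPcCount, 9L)
  expect_true(all(diff(rep$cumulative) >= 0))
  expect_equal(rep$cumulative[10], 1, tolerance = 1e-9)
})

test_that("pcaSelect resolves duplicated driver pairs to 2 components", {
  O <- orthogonalDrivers(9)        # 10 samples, exactly orthogonal columns
  X <- cbind(v1 = O[, 1], v2 = O[, 1], v3 = O[, 2], v4 = O[, 2])
  rep <- pcaSelect(X)
  expect_equal(sort(rep$eigenvalues, decreasing = TRUE), c(2, 2, 0, 0),
               tolerance = 1e-9)
  expect_equal(rep$retainedPcCount, 2L)
  # every variable loads on the retained pair; the l2 norm of its
  # loadings over PC1-PC2 is 1/sqrt(2) regardless of the rotation
  # within the degenerate eigenspace
  L <- rep$loadings[, 1:2]
  expect_equal(unname(sqrt(rowSums(L^2))), rep(1 / sqrt(2), 4),
               tolerance = 1e-9)
  expect_setequal(rep$retainedDrivers, c("v1", "v2", "v3", "v4"))
  expect_error(pcaSelect(cbind(a = rep(1, 5), b = rnorm(5))), "constant")
})

test_that("eigenvalues of the correlation matrix sum to the driver count", {
  set.seed(23)
  X <- matrix(rnorm(200), 40, 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  rep <- pcaSelect(X)
  expect_equal(sum(rep$eigenvalues), 5, tolerance = 1e-9)
  expect_true(all(diff(rep$cumulative) >= -1e-12))
})

test_that("driver clustering merges duplicates at height 0, independents near 1", {
  O <- orthogonalDrivers(2)
  X <- cbind(v1 = O[, 1], v2 = O[, 1], v3 = O[, 2])
  cl <- clusterDrivers(X, h = 0.5)
  hts <- cl$hclust$height
  expect_true(all(diff(hts) >= -1e-12))   # monotone merge heights
  expect_equal(hts[1], 0, tolerance = 1e-12)
  expect_equal(hts[2], 1, tolerance = 1e-9)  # exactly uncorrelated join
  expect_equal(cl$clusters[["v1"]], cl$clusters[["v2"]])
  expect_false(cl$clusters[["v3"]] == cl$clusters[["v1"]])
  # anticorrelation is distance 0 too
  Y <- cbind(a = O[, 1], b = -O[, 1])
  expect_equal(clusterDrivers(Y)$hclust$height[1], 0, tolerance = 1e-12)
})

test_that("independent drivers show distance near 1 at large n", {
  set.seed(31)
  X <- cbind(a = rnorm(2000), b = rnorm(2000))
  d <- 1 - abs(cor(X))[1, 2]
  expect_gt(d, 0.9)
})

test_that("selectDrivers keeps one representative per cluster and flags categoricals", {
  set.seed(41)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  strong <- y + rnorm(n, sd = 0.3)          # predictive driver
  dup <- strong                              # exact duplicate
  indep <- rnorm(n)                          # unrelated driver
  X <- cbind(strong = strong, dup = dup, indep = indep)
  catDrv <- factor(ifelse(y == 1, "irrigated", "rainfed"))
  rep <- selectDrivers(X, y, categorical = list(lulc = catDrv))
  # exactly one of the duplicated pair survives the cluster reduction
  expect_equal(sum(c("strong", "dup") %in% rep$finalDrivers), 1L)
  # the perfectly associated categorical driver is significant
  expect_true("lulc" %in% rep$finalDrivers)
  expect_lt(rep$chiSquare$lulc$p_value, 1e-6)
  prov <- rep$provenance
  expect_false(prov$selected[prov$driver == "indep"])
})

test_that("a single perfectly predictive driver is retained as important", {
  set.seed(43)
  y <- rep(c(0, 1), 30)
  X <- cbind(perfect = y, noise = rnorm(60))
  rep <- selectDrivers(X, y)
  expect_true("perfect" %in% rep$finalDrivers)
  expect_true(rep$provenance$important[rep$provenance$driver == "perfect"])
})
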