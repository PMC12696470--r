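test_that("standardization maps columns by direction onto [0, 1]", {
  m <- cbind(pos = c(2, 4, 10), neg = c(2, 4, 10))
  rownames(m) <- c("a", "b", "c")
  x <- new("ChangeRateMatrix", rates = m,
           directions = c(pos = "positive", neg = "negative"))
  v <- standardizedValues(standardizeRates(x))
  expect_equal(unname(v[, "pos"]), c(0, 0.25, 1))
  expect_equal(unname(v[, "neg"]), c(1, 0.75, 0))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("constant columns standardize to neutral 0.5 with a warning", {
  m <- cbind(a = c(1, 2, 3), b = rep(7, 3))
  rownames(m) <- c("x", "y", "z")
  x <- new("ChangeRateMatrix", rates = m,
           directions = c(a = "positive", b = "positive"))
  expect_warning(s <- standardizeRates(x), "constant")
  expect_equal(unname(s@values[, "b"]), rep(0.5, 3))
  expect_equal(s@constantColumns, "b")
  one <- new("ChangeRateMatrix", rates = m[1, , drop = FALSE],
             directions = c(a = "positive", b = "positive"))
  expect_error(standardizeRates(one), ">= 2")
})

test_that("direction coherence: negating sign and direction is a no-op", {
  set.seed(2)
  m <- matrix(rnorm(28), 7, dimnames = list(paste0("cv", 1:7),
                                            paste0("i", 1:4)))
  d1 <- setNames(rep("positive", 4), colnames(m))
  d2 <- d1; d2["i2"] <- "negative"
  m2 <- m; m2[, "i2"] <- -m2[, "i2"]
  s1 <- standardizeRates(new("ChangeRateMatrix", rates = m, directions = d1))
  s2 <- standardizeRates(new("ChangeRateMatrix", rates = m2, directions = d2))
  expect_equal(s1@values, s2@values)
})

test_that("membership scores are the weighted mean of standardized values", {
  v <- rbind(best = rep(1, 4), worst = rep(0, 4), mid = c(1, 0, 0.5, 0.5))
  X <- stdMatrix(v)
  res <- membershipScores(X)
  expect_equal(unname(scores(res)[c("best", "worst", "mid")]), c(1, 0, 0.5))
  expect_equal(tolranking(res)[1], "best")
  # degenerate weight vector picks out one column
  res1 <- membershipScores(X, weights = c(1, 0, 0, 0))
  expect_equal(unname(scores(res1)), unname(v[, 1]))
  expect_error(membershipScores(X, weights = c(0.5, 0.5)), "expected 4")
  expect_error(membershipScores(X, weights = c(0.6, 0.2, 0.1, 0.2)),
               "sum to 1")
  # matches the loop oracle on random matrices
  for (s in 1:5) {
    set.seed(s)
    v <- matrix(runif(24), 6)
    w <- runif(4); w <- w / sum(w)
    expect_equal(unname(scores(membershipScores(stdMatrix(v), w))),
                 bruteMembership(v, w), tolerance = 1e-12)
  }
})

test_that("entropy weights reward informative columns and sum to 1", {
  # identity-like matrix: symmetric by row permutation -> equal weights
  X <- stdMatrix(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(entropyWeights(X)), c(0.5, 0.5))
  # duplicated column -> equal split
  v <- cbind(c(0.1, 0.5, 1), c(0.1, 0.5, 1))
  expect_equal(unname(entropyWeights(stdMatrix(v))), c(0.5, 0.5))
  # constant column carries no information
  v2 <- cbind(c(0.2, 0.2, 0.2), c(0, 0.5, 1))
  expect_warning(w <- entropyWeights(stdMatrix(v2)), "zero-information")
  expect_equal(unname(w), c(0, 1))
  expect_error(suppressWarnings(
    entropyWeights(stdMatrix(matrix(0.3, 3, 2)))), "zero-information")
  set.seed(3)
  w3 <- entropyWeights(stdMatrix(matrix(runif(35), 7)))
  expect_equal(sum(w3), 1)
  expect_true(all(w3 >= 0))
})

test_that("TOPSIS closeness matches its defining formulas", {
  X <- stdMatrix(rbind(a = c(1, 1), b = c(0, 0)))
  expect_equal(unname(closeness(topsis(X))), c(1, 0))
  X2 <- stdMatrix(rbind(a = c(1, 0), b = c(0, 1), c = c(0.5, 0.5)))
  r2 <- topsis(X2)
  expect_equal(unname(r2@dPlus["c"]), sqrt(0.5))
  expect_equal(unname(r2@dMinus["c"]), sqrt(0.5))
  expect_equal(unname(closeness(r2)["c"]), 0.5)
  # the alternative equal to the positive ideal everywhere has C = 1
  set.seed(4)
  v <- matrix(runif(20), 5)
  v[3, ] <- apply(v, 2, max)
  expect_equal(unname(closeness(topsis(stdMatrix(v)))[3]), 1)
  expect_error(topsis(stdMatrix(matrix(0.5, 3, 2))), "constant")
})

test_that("TOPSIS matches the brute-force oracle on grid matrices", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  # exhaustive over all 2x2 grid matrices with at least one varying column
  combos <- expand.grid(grid, grid, grid, grid)
  for (i in seq_len(nrow(combos))) {
    v <- matrix(as.numeric(combos[i, ]), 2)
    if (all(v[1, ] == v[2, ])) next
    got <- topsis(stdMatrix(v))
    want <- bruteTopsis(v)
    expect_equal(unname(closeness(got)), want$c, tolerance = 1e-12)
  }
  # random matrices up to 5x4 on the grid
  set.seed(5)
  for (rep in 1:100) {
    n <- sample(2:5, 1); m <- sample(2:4, 1)
    v <- matrix(sample(grid, n * m, replace = TRUE), n)
    if (any(apply(v, 2, function(z) min(z) == max(z)))) next
    got <- topsis(stdMatrix(v))
    want <- bruteTopsis(v)
    expect_equal(unname(got@dPlus), want$dPlus, tolerance = 1e-12)
    expect_equal(unname(got@dMinus), want$dMinus, tolerance = 1e-12)
    expect_equal(unname(closeness(got)), want$c, tolerance = 1e-12)
  }
})

test_that("dominated alternatives rank below dominating ones", {
  set.seed(6)
  for (rep in 1:20) {
    v <- matrix(runif(24), 6,
                dimnames = list(paste0("cv", 1:6), paste0("i", 1:4)))
    v[2, ] <- pmin(v[1, ] - 0.05, v[2, ])  # cv2 strictly below cv1
    v <- pmax(v, 0)
    if (any(v[2, ] >= v[1, ])) next
    X <- stdMatrix(v)
    expect_gt(scores(membershipScores(X))["cv1"],
              scores(membershipScores(X))["cv2"])
    expect_gt(closeness(topsis(X))["cv1"], closeness(topsis(X))["cv2"])
  }
})

test_that("PCA diagnostics report explained variance without touching ranks", {
  v <- cbind(c(0, 0.5, 1), rep(0.5, 3))
  res <- pcaSummary(stdMatrix(v))
  expect_equal(res$explainedVariance[1], 1)
  a <- c(0, 0.5, 1)
  res2 <- pcaSummary(stdMatrix(cbind(a, 0.2 + 0.8 * a)))
  expect_equal(res2$explainedVariance[2], 0)
  set.seed(7)
  res3 <- pcaSummary(stdMatrix(matrix(runif(28), 7)))
  expect_equal(sum(res3$explainedVariance), 1)
})

test_that("ranking concordance reproduces the reference two-reversal case", {
  idc <- compareRankings(orderMembership, orderMembership)
  expect_equal(idc@spearmanRho, 1)
  expect_equal(idc@kendallTau, 1)
  expect_equal(idc@nReversals, 0L)
  cc <- compareRankings(orderMembership, orderTopsis)
  expect_equal(cc@nReversals, 2L)
  expect_equal(cc@spearmanRho, 1 - 6 * 2 / (9 * 80))
  expect_error(compareRankings(c("a", "b"), c("a", "c")), "difference")
})

test_that("a zero-noise panel is ranked identically by both methods", {
  p <- simulatePhysioPanel(noiseSd = 0, seed = 8)
  res <- rankCultivars(p)
  ord <- groundTruth(p)$order
  expect_equal(tolranking(res$membership), ord)
  expect_equal(tolranking(res$topsis), ord)
  expect_equal(res$concordance@nReversals, 0L)
  expect_equal(res$concordance@spearmanRho, 1)
})

test_that("rankings are invariant to affine rescaling of a raw indicator", {
  p <- simulatePhysioPanel(seed = 10)
  r1 <- rankCultivars(p)
  df <- panelData(p)
  df$value[df$indicator == "SOD"] <- df$value[df$indicator == "SOD"] * 3.2
  r2 <- rankCultivars(PhysioPanel(df, directions(p)))
  expect_equal(tolranking(r1$membership), tolranking(r2$membership))
  expect_equal(tolranking(r1$topsis), tolranking(r2$topsis))
})

test_that("a cultivar dominating every indicator ranks first", {
  rates <- rbind(top = c(0.9, 0.8, -0.1), mid = c(0.5, 0.4, 0.2),
                 low = c(0.1, 0.05, 0.6))
  colnames(rates) <- c("SOD", "CAT", "MDA")
  p <- panelFromRates(rates, c(SOD = "positive", CAT = "positive",
                               MDA = "negative"))
  res <- rankCultivars(p)
  expect_equal(tolranking(res$membership)[1], "top")
  expect_equal(tolranking(res$topsis)[1], "top")
})
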