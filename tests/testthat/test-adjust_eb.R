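# direct (no empirical-Bayes) location/scale oracle used by several tests
direct_adjust <- function(X, groups) {
  groups <- factor(groups)
  ng <- table(groups)
  gm <- rowsum(X, groups) / as.vector(ng)
  alpha <- colSums(gm * as.vector(ng)) / nrow(X)
  sigma2 <- colSums((X - gm[groups, , drop = FALSE])^2) /
    (nrow(X) - nlevels(groups))
  Z <- sweep(sweep(X, 2, alpha), 2, sqrt(sigma2), "/")
  gh <- rowsum(Z, groups) / as.vector(ng)
  dh <- rowsum((Z - gh[groups, , drop = FALSE])^2, groups) /
    (as.vector(ng) - 1)
  Zadj <- (Z - gh[groups, , drop = FALSE]) / sqrt(dh)[groups, , drop = FALSE]
  sweep(sweep(Zadj, 2, sqrt(sigma2), "*"), 2, alpha, "+")
}

test_that("a pure group shift is removed completely", {
  X <- rand_dosage(60, 30, seed = 1) + 0.0
  X[31:60, ] <- X[31:60, ] + 0.8
  g <- rep(c("g1", "g2"), each = 30)
  # exact removal in the direct location/scale limit
  adj0 <- combat_adjust(X, g, shrink = FALSE)$adjusted
  dmean0 <- colMeans(adj0[1:30, ]) - colMeans(adj0[31:60, ])
  expect_lt(max(abs(dmean0) / apply(X, 2, sd)), 1e-6)
  # the EB posteriors leave only a small shrinkage residual
  adj <- combat_adjust(X, g)$adjusted
  dmean <- colMeans(adj[1:30, ]) - colMeans(adj[31:60, ])
  expect_lt(max(abs(dmean)), 0.5 * 0.8)
})

test_that("identically distributed groups are nearly unchanged", {
  set.seed(4)
  X <- matrix(rnorm(372 * 50), 372, 50)
  g <- rep(c("g1", "g2"), length.out = 372)
  adj <- combat_adjust(X, g)$adjusted
  expect_lt(mean(abs(adj - X)), 0.05 * mean(apply(X, 2, sd)))
})

test_that("without shrinkage the adjustment equals direct standardization", {
  X <- rand_dosage(50, 25, seed = 2) + 0.0
  g <- rep(c("g1", "g2"), each = 25)
  adj <- combat_adjust(X, g, shrink = FALSE)$adjusted
  expect_equal(adj, direct_adjust(X, g), tolerance = 1e-6)
})

test_that("the adjustment is nearly idempotent", {
  set.seed(5)
  X <- matrix(rnorm(120 * 40), 120, 40)
  X[61:120, ] <- X[61:120, ] + 0.5
  g <- rep(c("g1", "g2"), each = 60)
  # the location/scale path is exactly idempotent
  a1 <- combat_adjust(X, g, shrink = FALSE)$adjusted
  a2 <- combat_adjust(a1, g, shrink = FALSE)$adjusted
  expect_lt(max(abs(a2 - a1)), 1e-3 * mean(apply(X, 2, sd)))
  # the EB path re-shrinks only the residual group differences
  b1 <- combat_adjust(X, g)$adjusted
  b2 <- combat_adjust(b1, g)$adjusted
  expect_lt(max(abs(b2 - b1)), 0.1 * mean(apply(X, 2, sd)))
})

test_that("group F statistics are deflated to the null after adjustment", {
  set.seed(6)
  X <- matrix(rnorm(150 * 60), 150, 60)
  X[1:50, ] <- X[1:50, ] + 1
  g <- rep(c("g1", "g2", "g3"), each = 50)
  adj <- combat_adjust(X, g)$adjusted
  f_of <- function(M) apply(M, 2, function(x)
    summary(aov(x ~ factor(g)))[[1]]$`F value`[1])
  null_median <- qf(0.5, 2, 147)
  expect_lt(median(f_of(adj)), 2 * null_median)
  expect_gt(median(f_of(X)), 10 * null_median)
})

test_that("degenerate inputs are handled", {
  X <- rand_dosage(20, 10, seed = 3) + 0.0
  X[, 3] <- 1   # zero variance
  g <- rep(c("g1", "g2"), each = 10)
  res <- combat_adjust(X, g)
  expect_equal(res$skipped, "m003")
  expect_equal(res$adjusted[, 3], X[, 3])
  expect_error(combat_adjust(X, c("g1", rep("g2", 19))), "singleton")
})

test_that("the EB adjustment matches the reference batch-effect routine", {
  set.seed(7)
  X <- matrix(rnorm(80 * 40), 80, 40)
  X[41:80, ] <- X[41:80, ] + 0.6
  g <- rep(c("g1", "g2"), each = 40)
  ours <- combat_adjust(X, g)$adjusted
  ref <- t(suppressMessages(sva::ComBat(dat = t(X), batch = g)))
  # conventions differ only in the pooled-variance denominator (n-G vs n)
  expect_gt(cor(as.vector(ours), as.vector(ref)), 0.999)
  expect_lt(mean(abs(ours - ref)), 0.02)
})

test_that("phenotype residualization removes group means", {
  y <- c(rnorm(20), rnorm(20) + 3)
  g <- rep(c("g1", "g2"), each = 20)
  yr <- residualize_phenotype(y, g)
  expect_equal(mean(yr[1:20]), mean(yr[21:40]), tolerance = 1e-12)
  expect_equal(mean(yr), mean(y), tolerance = 1e-12)
})
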