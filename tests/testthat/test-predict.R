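# shared small regression problem
make_xy <- function(n, p, seed = 1, n_sig = min(p, 5), sd_e = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  b <- c(rnorm(n_sig), rep(0, p - n_sig))
  y <- drop(X %*% b) + rnorm(n, sd = sd_e)
  list(X = X, y = y, b = b)
}

test_that("LASSO reaches the OLS solution when the penalty vanishes", {
  d <- make_xy(20, 3, seed = 1)
  fit <- gp_fit(d$X, d$y, method = "lasso", lasso_lambda = 1e-10,
                lasso_thresh = 1e-14)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
})

test_that("LASSO soft-thresholds OLS coefficients on orthonormal designs", {
  set.seed(2)
  n <- 40; p <- 6
  # orthonormal columns with zero mean (so centering leaves them intact)
  M <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)
  Q <- qr.Q(qr(M))
  colnames(Q) <- paste0("m", 1:p)
  b <- rnorm(p, sd = 2)
  y <- drop(Q %*% b) + rnorm(n, sd = 0.3)
  lam <- 0.02
  fit <- gp_fit(Q, y, method = "lasso", lasso_lambda = lam,
                lasso_thresh = 1e-14)
  # objective (1/2n)||yc - Q beta||^2 + lam ||beta||_1 on the orthonormal
  # design: coordinates soft-threshold at n * lam
  yc <- y - mean(y)
  z <- drop(crossprod(Q, yc))
  expected <- sign(z) * pmax(abs(z) - n * lam, 0)
  expect_equal(unname(fit$beta), unname(expected), tolerance = 1e-6)
})

test_that("constant phenotypes give null effect vectors", {
  X <- rand_dosage(15, 6, seed = 3)
  for (m in c("lasso", "pls", "gblup")) {
    fit <- gp_fit(X, rep(2, 15), method = m)
    expect_equal(unname(fit$beta), rep(0, 6))
    expect_equal(unname(predict(fit, X)), rep(2, 15))
  }
})

test_that("single-predictor PLS equals simple least squares", {
  d <- make_xy(25, 1, seed = 4)
  fit <- gp_fit(d$X, d$y, method = "pls", n_components = 1)
  sl <- lm(d$y ~ d$X[, 1])
  expect_equal(unname(fit$beta[1]), unname(coef(sl)[2]), tolerance = 1e-8)
  expect_equal(unname(fit$mu), unname(mean(d$y)))
})

test_that("PLS score vectors are mutually orthogonal", {
  d <- make_xy(40, 15, seed = 5)
  fit <- gp_fit(d$X, d$y, method = "pls", n_components = 6)
  Tm <- fit$details$scores
  g <- crossprod(Tm)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
})

test_that("full-component PLS on a full-rank design equals OLS", {
  d <- make_xy(30, 5, seed = 6)
  fit <- gp_fit(d$X, d$y, method = "pls", n_components = 5)
  ols <- lm(d$y ~ d$X)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
})

test_that("sparse PLS with all variables kept is ordinary PLS", {
  d <- make_xy(40, 12, seed = 7)
  pls <- gp_fit(d$X, d$y, method = "pls", n_components = 3)
  spls <- gp_fit(d$X, d$y, method = "spls", n_components = 3,
                 vars_per_component = 12)
  expect_equal(spls$beta, pls$beta, tolerance = 1e-8)
})

test_that("sparse PLS keeps exactly the requested number of loadings", {
  set.seed(8)
  X <- matrix(rbinom(372 * 331, 2, 0.4) + 0.0, 372, 331,
              dimnames = list(NULL, paste0("m", 1:331)))
  y <- drop(X[, 1:30] %*% rnorm(30)) + rnorm(372)
  fit <- gp_fit(X, y, method = "spls", n_components = 2,
                vars_per_component = 50)
  nz <- colSums(abs(fit$details$W) > 0)
  expect_equal(unname(nz), c(50, 50))
  expect_lte(length(fit$details$selected), 100)
})

test_that("sparse PLS agrees with the reference implementation", {
  d <- make_xy(50, 30, seed = 9)
  fit <- gp_fit(d$X, d$y, method = "spls", n_components = 2,
                vars_per_component = 10)
  ref <- mixOmics::spls(d$X, d$y, ncomp = 2, keepX = c(10, 10),
                        mode = "regression", scale = FALSE)
  sel_ref <- lapply(1:2, function(h) unname(which(ref$loadings$X[, h] != 0)))
  sel_our <- lapply(1:2, function(h) unname(which(fit$details$W[, h] != 0)))
  expect_identical(sel_our, sel_ref)
})

test_that("GBLUP solves the mixed-model equations", {
  d <- make_xy(5, 3, seed = 10, sd_e = 0.2)
  X <- round(abs(d$X) %% 3)      # integer dosages
  colnames(X) <- paste0("m", 1:3)
  y <- d$y
  fit <- gp_fit(X, y, method = "gblup")
  sg2 <- fit$details$sigma_g2; se2 <- fit$details$sigma_e2
  G <- fit$details$G
  # dense GLS/BLUP solve at the estimated variance components
  V <- sg2 * G + se2 * diag(5)
  Vi <- solve(V)
  one <- rep(1, 5)
  mu <- drop(solve(t(one) %*% Vi %*% one, t(one) %*% Vi %*% y))
  g <- drop(sg2 * G %*% Vi %*% (y - mu))
  expect_equal(unname(fit$mu), mu, tolerance = 1e-8)
  expect_equal(unname(fit$details$gebv), g, tolerance = 1e-8)
  expect_equal(unname(fit$fitted), mu + g, tolerance = 1e-8)
})

test_that("GBLUP equals ridge regression on the centered dosages", {
  set.seed(11)
  X <- matrix(rbinom(50 * 80, 2, 0.4) + 0.0, 50, 80,
              dimnames = list(NULL, paste0("m", 1:80)))
  y <- drop(X[, 1:10] %*% rnorm(10)) + rnorm(50)
  fit <- gp_fit(X, y, method = "gblup")
  W <- sweep(X, 2, colMeans(X))
  lam <- fit$details$denom * fit$details$sigma_e2 / fit$details$sigma_g2
  bridge <- solve(crossprod(W) + lam * diag(80), crossprod(W, y - fit$mu))
  expect_equal(unname(fit$beta), unname(drop(bridge)), tolerance = 1e-6)
})

test_that("Bayesian chains are reproducible and the null prior nullifies", {
  d <- make_xy(40, 15, seed = 12)
  cfg <- bayes_config(n_iter = 1500, burn_in = 500)
  f1 <- gp_fit(d$X, d$y, method = "bayesA", bayes = cfg, seed = 3)
  f2 <- gp_fit(d$X, d$y, method = "bayesA", bayes = cfg, seed = 3)
  expect_identical(f1$beta, f2$beta)
  cfg1 <- bayes_config(pi = 1, n_iter = 1500, burn_in = 500)
  fb <- gp_fit(d$X, d$y, method = "bayesB", bayes = cfg1, seed = 4)
  expect_lt(max(abs(fb$beta)), 1e-3 * sd(d$y))
  expect_error(bayes_config(n_iter = 100, burn_in = 100))
})

test_that("deterministic methods are invariant to marker column order", {
  d <- make_xy(40, 12, seed = 13)
  set.seed(99)
  perm <- sample(12)
  tol <- c(lasso = 1e-6, pls = 1e-8, spls = 1e-8, gblup = 1e-8)
  for (m in names(tol)) {
    f1 <- gp_fit(d$X, d$y, method = m, seed = 2, n_components = 3,
                 lasso_thresh = 1e-13)
    f2 <- gp_fit(d$X[, perm], d$y, method = m, seed = 2, n_components = 3,
                 lasso_thresh = 1e-13)
    expect_equal(f2$beta[names(f1$beta)], f1$beta, tolerance = tol[[m]])
  }
})

test_that("prediction applies training centering and checks columns", {
  d <- make_xy(30, 8, seed = 14)
  fit <- gp_fit(d$X, d$y, method = "pls", n_components = 3)
  expect_equal(unname(predict(fit, d$X)), unname(fit$fitted))
  expect_equal(predict(fit, d$X[c(1, 1), ])[1],
               predict(fit, d$X[c(1, 1), ])[2])
  bad <- d$X[, 1:7]
  expect_error(predict(fit, bad), "m8")
})
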