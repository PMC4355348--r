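#' Fit a whole-genome regression model
#'
#' Single entry point to the six genomic-prediction methods compared in
#' the package: LASSO, partial least squares (PLS), sparse PLS, GBLUP,
#' Bayes A and Bayes B. All methods centre the marker columns and the
#' phenotype on the training data (the intercept is the training
#' phenotype mean) and expose an equivalent per-marker effect vector, so
#' predictions are always `mu + X_new_centered %*% beta`.
#'
#' Tuning follows the repeated-evaluation protocol the package implements:
#' the LASSO constraint bound and the PLS/SPLS component count are chosen
#' by `cv_folds`-fold cross-validation on the training data, minimising
#' the mean squared error of prediction.
#'
#' @param X complete numeric dosage matrix (accessions x markers)
#' @param y numeric phenotype vector, length nrow(X)
#' @param method one of `"lasso"`, `"pls"`, `"spls"`, `"gblup"`,
#'   `"bayesA"`, `"bayesB"`
#' @param standardize also scale marker columns to unit variance before
#'   fitting (default `FALSE`: centre only); reported effects are always
#'   on the original dosage scale
#' @param cv_folds folds for internal tuning (default 10)
#' @param max_components maximum PLS/SPLS components tried by CV
#'   (default 10)
#' @param n_components fixed component count for PLS/SPLS (overrides CV)
#' @param vars_per_component number of markers with nonzero loading per
#'   sparse-PLS component (default 50)
#' @param bayes a [bayes_config()] for the Bayesian methods
#' @param lasso_thresh glmnet coordinate-descent convergence threshold
#'   (default 1e-9)
#' @param lasso_lambda optional fixed penalty for the LASSO (skips the CV
#'   choice of the constraint bound; mainly for calibration studies)
#' @param seed integer seed for CV folds / Gibbs chains
#' @return an object of class `gp_model` (and `gp_<method>`): list with
#'   `method`, `mu`, `beta` (named, original dosage scale), `center`
#'   (training column means), `fitted`, `y`, and method-specific
#'   `details`.
#' @seealso [predict.gp_model()], [coef.gp_model()]
#' @export
gp_fit <- function(X, y,
                   method = c("lasso", "pls", "spls", "gblup", "bayesA", "bayesB"),
                   standardize = FALSE, cv_folds = 10,
                   max_components = 10, n_components = NULL,
                   vars_per_component = 50, bayes = bayes_config(),
                   lasso_thresh = 1e-9, lasso_lambda = NULL,
                   seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(p))

  center <- colMeans(X)
  scale_ <- if (standardize) {
    s <- apply(X, 2, sd); s[s == 0] <- 1; s
  } else rep(1, p)
  Xc <- sweep(sweep(X, 2, center), 2, scale_, "/")
  mu <- mean(y)
  yc <- y - mu

  details <- list()
  if (var(y) == 0) {
    beta_s <- rep(0, p)
  } else {
    eng <- switch(method,
      lasso = engine_lasso(Xc, yc, cv_folds, seed, lasso_thresh,
                           lasso_lambda),
      pls = engine_pls_cv(Xc, yc, max_components, n_components, cv_folds,
                          seed, keep = NULL),
      spls = engine_pls_cv(Xc, yc, max_components, n_components, cv_folds,
                           seed, keep = vars_per_component),
      gblup = engine_gblup(X, y),
      bayesA = engine_bayes(Xc, yc, bayes, variant = 0L, seed = seed),
      bayesB = engine_bayes(Xc, yc, bayes, variant = 1L, seed = seed))
    beta_s <- eng$beta
    details <- eng$details
    if (method == "gblup") { mu <- eng$mu; beta_s <- beta_s * scale_ }
  }
  beta <- setNames(beta_s / scale_, colnames(X))
  fitted <- drop(mu + sweep(X, 2, center) %*% beta)
  structure(list(method = method, mu = mu, beta = beta, center = center,
                 scale = scale_, standardize = standardize,
                 fitted = fitted, y = y, details = details, n = n, p = p),
            class = c(paste0("gp_", method), "gp_model"))
}

# ---- LASSO via the glmnet regularization path --------------------------

engine_lasso <- function(Xc, yc, cv_folds, seed, thresh = 1e-9,
                         lambda = NULL) {
  if (!is.null(lambda)) {
    # fixed penalty: descend the path to the requested lambda
    lmax <- max(abs(crossprod(Xc, yc))) / length(yc)
    path <- exp(seq(log(lmax), log(max(lambda, 1e-12)), length.out = 100))
    path <- sort(unique(c(path, lambda)), decreasing = TRUE)
    fit <- glmnet::glmnet(Xc, yc, intercept = FALSE, standardize = FALSE,
                          lambda = path, thresh = thresh)
    beta <- suppressWarnings(as.numeric(coef(fit, s = lambda,
                                             exact = FALSE))[-1])
    return(list(beta = beta,
                details = list(lambda = lambda, t = sum(abs(beta)),
                               cvm = NULL, lambda_path = path)))
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(cv_folds), length(yc)))
  cv <- glmnet::cv.glmnet(Xc, yc, intercept = FALSE, standardize = FALSE,
                          foldid = foldid, type.measure = "mse",
                          thresh = thresh)
  beta <- as.numeric(coef(cv, s = "lambda.min"))[-1]
  list(beta = beta,
       details = list(lambda = cv$lambda.min, t = sum(abs(beta)),
                      cvm = cv$cvm, lambda_path = cv$lambda))
}

# ---- univariate NIPALS PLS / sparse PLS --------------------------------

# One PLS1 fit with ncomp components.  keep = NULL -> ordinary PLS;
# keep = k -> per component only the k loadings with largest |X'y| stay
# nonzero (soft-thresholded at the largest excluded |X'y|; ties broken by
# lower column index).
pls_engine <- function(Xc, yc, ncomp, keep = NULL) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  h_done <- 0
  for (h in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    if (!is.null(keep) && keep < p) {
      o <- order(-abs(w), seq_along(w))
      thr <- abs(w[o[min(keep + 1, p)]])
      w_new <- numeric(p)
      sel <- o[seq_len(keep)]
      w_new[sel] <- sign(w[sel]) * pmax(abs(w[sel]) - thr, 0)
      w <- w_new
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- drop(crossprod(Xd, t_h)) / tt
    q_h <- sum(yd * t_h) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    yd <- yd - t_h * q_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
    h_done <- h
  }
  if (h_done == 0)
    return(list(beta = numeric(p), ncomp = 0, W = W[, 0], P = P[, 0],
                scores = Tm[, 0], q = numeric(0)))
  W <- W[, seq_len(h_done), drop = FALSE]
  P <- P[, seq_len(h_done), drop = FALSE]
  Tm <- Tm[, seq_len(h_done), drop = FALSE]
  q <- q[seq_len(h_done)]
  beta <- drop(W %*% solve(crossprod(P, W), q))
  list(beta = beta, ncomp = h_done, W = W, P = P, scores = Tm, q = q)
}

engine_pls_cv <- function(Xc, yc, max_components, n_components, cv_folds,
                          seed, keep = NULL) {
  p <- ncol(Xc); n <- nrow(Xc)
  if (!is.null(keep)) keep <- min(keep, p)
  cap <- min(max_components, p, n - 2)
  if (is.null(n_components)) {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    press <- matrix(NA_real_, cv_folds, cap)
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      ctr <- colMeans(Xc[tr, , drop = FALSE]); mtr <- mean(yc[tr])
      fit <- pls_engine(sweep(Xc[tr, , drop = FALSE], 2, ctr),
                        yc[tr] - mtr, cap, keep)
      if (fit$ncomp == 0) next
      Xte <- sweep(Xc[!tr, , drop = FALSE], 2, ctr)
      for (h in seq_len(fit$ncomp)) {
        bh <- drop(fit$W[, 1:h, drop = FALSE] %*%
                     solve(crossprod(fit$P[, 1:h, drop = FALSE],
                                     fit$W[, 1:h, drop = FALSE]),
                           fit$q[1:h]))
        press[f, h] <- mean((yc[!tr] - mtr - Xte %*% bh)^2)
      }
    }
    msep <- colMeans(press, na.rm = TRUE)
    n_components <- which.min(msep)
  }
  fit <- pls_engine(Xc, yc, min(n_components, cap), keep)
  sel <- which(abs(fit$W) > 0, arr.ind = TRUE)
  list(beta = fit$beta,
       details = list(ncomp = fit$ncomp, W = fit$W, P = fit$P,
                      scores = fit$scores, q = fit$q,
                      keep = keep,
                      selected = if (!is.null(keep))
                        colnames(Xc)[sort(unique(sel[, 1]))] else NULL))
}

# ---- GBLUP with REML via the spectral decomposition of G ---------------

engine_gblup <- function(X, y) {
  n <- nrow(X)
  if (n < 3) stop("GBLUP needs at least 3 accessions")
  pfreq <- colMeans(X) / 2
  W <- sweep(X, 2, 2 * pfreq)
  cc <- 2 * sum(pfreq * (1 - pfreq))
  if (!is.finite(cc) || cc <= 1e-12)
    cc <- sum(W^2) / n   # trace scaling for non-dosage (real-valued) inputs
  if (cc <= 0) stop("no polymorphic marker for the relationship matrix")
  G <- tcrossprod(W) / cc + diag(1e-8, n)   # tiny jitter for stability
  eg <- eigen(G, symmetric = TRUE)
  if (min(eg$values) < -1e-6) stop("G is not positive semidefinite")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  os <- drop(crossprod(U, rep(1, n)))
  # profile REML over the variance ratio r = sigma_g^2 / sigma_e^2
  reml <- function(logr) {
    r <- exp(logr)
    v <- r * d + 1
    wi <- 1 / v
    mu <- sum(wi * os * ys) / sum(wi * os^2)
    rss <- sum(wi * (ys - os * mu)^2)
    se2 <- rss / (n - 1)
    0.5 * ((n - 1) * log(se2) + sum(log(v)) + log(sum(wi * os^2)) + (n - 1))
  }
  opt <- optimize(reml, c(-15, 15))
  r <- exp(opt$minimum)
  v <- r * d + 1
  wi <- 1 / v
  mu <- sum(wi * os * ys) / sum(wi * os^2)
  se2 <- sum(wi * (ys - os * mu)^2) / (n - 1)
  sg2 <- r * se2
  resid_rot <- ys - os * mu
  gebv <- drop(U %*% (r * d * wi * resid_rot))
  # equivalent per-marker effects (ridge back-solve through W)
  u <- drop(crossprod(W, U %*% ((r / cc) * wi * resid_rot)))
  list(beta = u, mu = mu,
       details = list(sigma_g2 = sg2, sigma_e2 = se2, lambda = 1 / r,
                      gebv = setNames(gebv, rownames(X)), G = G,
                      p_freq = pfreq, denom = cc))
}

# ---- Bayes A / Bayes B (Gibbs sampler in C++) --------------------------

#' Hyperparameters for the Bayesian whole-genome regressions
#'
#' @param nu degrees of freedom of the scaled-inverse-chi-square prior on
#'   per-marker effect variances (default 4)
#' @param S scale of that prior; `NULL` (default) sets it at fit time so
#'   the prior mode of the effect variance equals
#'   `var(y) * r_prior / sum(2 p_j (1 - p_j))` with `r_prior = 0.5`
#' @param r_prior fraction of phenotypic variance attributed to markers by
#'   the default scale heuristic (default 0.5)
#' @param pi prior probability of a null effect in the mixture variant
#'   (default 0.95)
#' @param n_iter,burn_in,thin Gibbs chain length, burn-in, thinning
#'   (defaults 12000 / 2000 / 5)
#' @return list of class `bayes_config`
#' @export
bayes_config <- function(nu = 4, S = NULL, r_prior = 0.5, pi = 0.95,
                         n_iter = 12000, burn_in = 2000, thin = 5) {
  stopifnot(pi >= 0, pi <= 1, burn_in < n_iter, thin >= 1, nu > 0)
  structure(list(nu = nu, S = S, r_prior = r_prior, pi = pi,
                 n_iter = n_iter, burn_in = burn_in, thin = thin),
            class = "bayes_config")
}

engine_bayes <- function(Xc, yc, config, variant, seed) {
  stopifnot(inherits(config, "bayes_config"))
  S <- config$S
  if (is.null(S)) {
    # column means of Xc are 0; recover 2p(1-p) from the dosage variance
    # proxy sum of column variances, falling back to a small floor
    vsum <- sum(apply(Xc, 2, var))
    mode_target <- var(yc) * config$r_prior / max(vsum, 1e-8)
    S <- mode_target * (config$nu + 2) / config$nu
  }
  set.seed(seed)
  res <- .gibbs_bayes(Xc, yc, config$nu, S, config$pi,
                      as.integer(config$n_iter), as.integer(config$burn_in),
                      as.integer(config$thin), as.integer(variant),
                      4, var(yc) / 2)
  list(beta = res$u_mean,
       details = list(S = S, nu = config$nu, pi = config$pi,
                      mu_offset = res$mu_mean,
                      sigma_e2 = res$sigma_e2_mean,
                      incl_prob = res$incl_prob, n_kept = res$n_kept))
}

# ---- methods ------------------------------------------------------------

#' Predict phenotypes from a fitted model
#'
#' @param object a `gp_model`
#' @param newdata numeric matrix with the training marker columns (matched
#'   by name when available)
#' @param ... ignored
#' @return numeric vector of predictions
#' @export
predict.gp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing_mk <- setdiff(names(object$beta), colnames(X))
    if (length(missing_mk))
      stop("newdata lacks marker(s): ", paste(head(missing_mk, 5), collapse = ", "))
    X <- X[, names(object$beta), drop = FALSE]
  } else if (ncol(X) != length(object$beta)) {
    stop("newdata has ", ncol(X), " columns; model has ", length(object$beta),
         " markers")
  }
  drop(object$mu + sweep(X, 2, object$center) %*% object$beta)
}

#' @export
coef.gp_model <- function(object, ...) {
  c("(Intercept)" = object$mu, object$beta)
}

#' @export
fitted.gp_model <- function(object, ...) object$fitted

#' @export
residuals.gp_model <- function(object, ...) object$y - object$fitted

#' @method print gp_model
#' @export
print.gp_model <- function(x, ...) {
  cat("gp_model (", x$method, "): ", x$n, " accessions, ", x$p, " markers\n",
      sep = "")
  cat("  intercept:", signif(x$mu, 5), "| nonzero effects:",
      sum(x$beta != 0), "\n")
  invisible(x)
}

#' @method summary gp_model
#' @export
summary.gp_model <- function(object, ...) {
  r2 <- 1 - sum((object$y - object$fitted)^2) /
    sum((object$y - mean(object$y))^2)
  out <- list(method = object$method, n = object$n, p = object$p,
              mu = object$mu, n_nonzero = sum(object$beta != 0),
              train_r2 = r2, details = object$details)
  class(out) <- "summary.gp_model"
  out
}

#' @method print summary.gp_model
#' @export
print.summary.gp_model <- function(x, ...) {
  cat("Whole-genome regression:", x$method, "\n")
  cat("  n =", x$n, ", p =", x$p, "\n")
  cat("  intercept:", signif(x$mu, 5), "\n")
  cat("  nonzero marker effects:", x$n_nonzero, "\n")
  cat("  training R2:", round(x$train_r2, 4), "\n")
  if (!is.null(x$details$ncomp)) cat("  components:", x$details$ncomp, "\n")
  if (!is.null(x$details$sigma_g2))
    cat("  sigma_g2:", signif(x$details$sigma_g2, 4),
        " sigma_e2:", signif(x$details$sigma_e2, 4), "\n")
  invisible(x)
}

#' @export
plot.gp_model <- function(x, ...) {
  plot(x$fitted, x$y, xlab = "fitted", ylab = "observed",
       main = paste("gp_model:", x$method), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Serialize a fitted model to JSON
#' @param model a `gp_model`
#' @param path output path
#' @export
write_gp_model <- function(model, path) {
  jsonlite::write_json(list(method = model$method, mu = model$mu,
                            beta = as.list(model$beta),
                            center = as.list(model$center)),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
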