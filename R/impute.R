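#' Probabilistic-PCA imputation of missing dosages
#'
#' Fits the probabilistic PCA latent-variable model x = W z + mu + eps,
#' z ~ N(0, I), eps ~ N(0, sigma2 I), by EM with the missing entries
#' treated as latent, and returns the matrix with missing entries replaced
#' by their posterior-mean reconstruction. Observed entries are returned
#' unchanged. Convergence is declared when the relative change in the
#' expected complete-data log-likelihood falls below `tol`.
#'
#' @param X numeric matrix (accessions x markers) with `NA` for missing;
#'   every row and column needs at least one observed entry
#' @param n_components latent dimension (default 5)
#' @param tol relative log-likelihood tolerance (default 1e-5)
#' @param max_iter maximum EM iterations (default 500)
#' @param seed seed for the random initialization of the loadings
#' @param clip_range optional length-2 numeric; imputed values outside the
#'   range are counted in the returned report (dosages live in [0, 2]) but
#'   not modified
#' @return list of class `ppca_impute`: `X` (completed matrix),
#'   `converged`, `n_iter`, `sigma2`, `W`, `n_imputed`, `n_outside_range`
#' @export
ppca_impute <- function(X, n_components = 5, tol = 1e-5, max_iter = 500,
                        seed = 1L, clip_range = c(0, 2)) {
  X <- as.matrix(X)
  obs <- !is.na(X)
  if (any(rowSums(obs) == 0)) stop("row(s) with no observed entry")
  if (any(colSums(obs) == 0)) stop("column(s) with no observed entry")
  n <- nrow(X); p <- ncol(X)
  q <- min(n_components, p - 1, n - 1)
  if (!anyNA(X))
    return(structure(list(X = X, converged = TRUE, n_iter = 0L,
                          sigma2 = 0, W = NULL, n_imputed = 0L,
                          n_outside_range = 0L), class = "ppca_impute"))
  set.seed(seed)
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  Xf[!obs] <- matrix(mu, n, p, byrow = TRUE)[!obs]   # mean start
  W <- matrix(rnorm(p * q, sd = 0.01), p, q)
  sigma2 <- mean((sweep(Xf, 2, mu))^2)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Xc <- sweep(Xf, 2, mu)
    M <- crossprod(W) + sigma2 * diag(q)
    Minv <- solve(M)
    Ez <- Xc %*% W %*% Minv                       # n x q posterior means
    Ezz <- n * sigma2 * Minv + crossprod(Ez)      # sum of E[zz']
    # M-step
    W_new <- crossprod(Xc, Ez) %*% solve(Ezz)
    recon <- Ez %*% t(W_new)
    sigma2_new <- (sum(Xc^2) - 2 * sum(recon * Xc) +
                     sum(diag(Ezz %*% crossprod(W_new)))) / (n * p)
    sigma2_new <- max(sigma2_new, 1e-12)
    # impute: posterior-mean reconstruction at missing positions
    fill <- sweep(Ez %*% t(W_new), 2, mu, "+")
    Xf[!obs] <- fill[!obs]
    mu <- colMeans(Xf)
    # expected complete-data log-likelihood (up to constants)
    ll <- -(n * p / 2) * log(sigma2_new) -
      (sum((sweep(Xf, 2, mu) - Ez %*% t(W_new))^2) / (2 * sigma2_new))
    W <- W_new; sigma2 <- sigma2_new
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  if (!converged) warning("ppca_impute: not converged after ", max_iter,
                          " iterations")
  out <- X
  out[!obs] <- Xf[!obs]
  n_out <- if (!is.null(clip_range))
    sum(out[!obs] < clip_range[1] | out[!obs] > clip_range[2]) else 0L
  structure(list(X = out, converged = converged, n_iter = it, sigma2 = sigma2,
                 W = W, n_imputed = sum(!obs), n_outside_range = n_out),
            class = "ppca_impute")
}

#' @method print ppca_impute
#' @export
print.ppca_impute <- function(x, ...) {
  cat("ppca_impute:", x$n_imputed, "entries imputed in", x$n_iter,
      "EM iterations (converged:", x$converged, ");",
      x$n_outside_range, "imputed values outside [0, 2]\n")
  invisible(x)
}
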