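#' Empirical-Bayes location/scale adjustment of genotypes for structure
#'
#' Removes per-group location and scale effects from the dosage matrix
#' before prediction, treating markers as "genes", accessions as
#' "samples" and inferred structure groups as "batches". Each marker is
#' standardized by its grand mean (group-size-weighted average of group
#' means) and pooled variance; per-(group, marker) location and scale
#' estimates are then shrunk towards parametric empirical-Bayes priors —
#' normal for the location, inverse-gamma for the scale — by the usual
#' iterative posterior computation, and the data are adjusted with the
#' shrunk estimates and rescaled to the original marker scale.
#'
#' @param numeric a `numeric_genotypes` object or complete numeric matrix
#'   (accessions x markers)
#' @param groups group labels (named by accession or in row order); every
#'   group needs >= 2 members
#' @param shrink if `FALSE`, skip the EB shrinkage and use the direct
#'   per-group location/scale estimates (the infinite-prior-variance
#'   limit)
#' @param tol convergence tolerance on successive location posteriors
#'   (default 1e-4)
#' @param max_iter maximum EB iterations (default 1000)
#' @return list of class `combat_adjust`: `adjusted` (matrix, same shape
#'   as input), `model` (per-group gamma_star/delta_star, per-marker grand
#'   mean and pooled variance, hyperparameters), `skipped` (zero-variance
#'   markers left unadjusted).
#' @export
combat_adjust <- function(numeric, groups, shrink = TRUE, tol = 1e-4,
                          max_iter = 1000) {
  X <- if (inherits(numeric, "numeric_genotypes")) numeric$X else as.matrix(numeric)
  if (anyNA(X)) stop("combat_adjust() needs a complete matrix; impute first")
  if (!is.null(names(groups)) && !is.null(rownames(X)))
    groups <- groups[rownames(X)]
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  ng <- table(groups)
  if (any(ng < 2))
    stop("singleton group(s): ", paste(names(ng)[ng < 2], collapse = ", "))
  n <- nrow(X); p <- ncol(X); G <- nlevels(groups)

  sd0 <- apply(X, 2, sd)
  skipped <- colnames(X)[sd0 == 0]
  use <- sd0 > 0
  Y <- X[, use, drop = FALSE]

  # group means and the size-weighted grand mean per marker
  gm <- rowsum(Y, groups) / as.vector(ng)              # G x p
  alpha <- colSums(gm * as.vector(ng)) / n             # grand mean
  resid <- Y - gm[groups, , drop = FALSE]
  sigma2 <- colSums(resid^2) / (n - G)                 # unbiased pooled variance
  Z <- sweep(sweep(Y, 2, alpha), 2, sqrt(sigma2), "/") # standardized

  gamma_hat <- rowsum(Z, groups) / as.vector(ng)       # G x p
  delta_hat <- rowsum((Z - gamma_hat[groups, , drop = FALSE])^2, groups) /
    pmax(as.vector(ng) - 1, 1)

  hyper <- list()
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  if (shrink) {
    for (g in seq_len(G)) {
      gh <- gamma_hat[g, ]; dh <- delta_hat[g, ]
      gbar <- mean(gh); tau2 <- var(gh)
      if (!is.finite(tau2)) tau2 <- 0
      m <- mean(dh); s2 <- var(dh)
      # degenerate hyperpriors (all estimates equal) collapse to no shrinkage
      shrink_scale <- is.finite(s2) && s2 > 1e-12
      lambda <- if (shrink_scale) (2 * s2 + m^2) / s2 else Inf
      theta <- if (shrink_scale) (m * s2 + m^3) / s2 else Inf
      n_g <- ng[g]
      zg <- Z[groups == levels(groups)[g], , drop = FALSE]
      g_new <- gh; d_new <- dh
      for (it in seq_len(max_iter)) {
        g_old <- g_new
        g_new <- (n_g * tau2 * gh + d_new * gbar) / (n_g * tau2 + d_new)
        ssq <- colSums((zg - matrix(g_new, n_g, ncol(zg), byrow = TRUE))^2)
        if (shrink_scale)
          d_new <- (theta + 0.5 * ssq) / (n_g / 2 + lambda - 1)
        if (max(abs(g_new - g_old)) < tol) break
      }
      gamma_star[g, ] <- g_new
      delta_star[g, ] <- d_new
      hyper[[levels(groups)[g]]] <- list(gamma_bar = gbar, tau2 = tau2,
                                         lambda = lambda, theta = theta,
                                         n_iter = it)
    }
  }

  Zadj <- (Z - gamma_star[groups, , drop = FALSE]) /
    sqrt(delta_star)[groups, , drop = FALSE]
  Yadj <- sweep(sweep(Zadj, 2, sqrt(sigma2), "*"), 2, alpha, "+")
  out <- X
  out[, use] <- Yadj
  structure(list(adjusted = out,
                 model = list(gamma_star = gamma_star, delta_star = delta_star,
                              gamma_hat = gamma_hat, delta_hat = delta_hat,
                              alpha = alpha, sigma2 = sigma2,
                              hyper = hyper, groups = groups, shrink = shrink),
                 skipped = skipped),
            class = "combat_adjust")
}

#' @method print combat_adjust
#' @export
print.combat_adjust <- function(x, ...) {
  cat("combat_adjust:", nrow(x$adjusted), "accessions x", ncol(x$adjusted),
      "markers,", nlevels(x$model$groups), "groups",
      if (x$model$shrink) "(EB-shrunk)\n" else "(no shrinkage)\n")
  invisible(x)
}

#' Serialize an adjustment model to JSON
#' @param fit a `combat_adjust` object
#' @param path output path
#' @export
write_adjustment_model <- function(fit, path) {
  m <- fit$model
  jsonlite::write_json(list(gamma_star = m$gamma_star, delta_star = m$delta_star,
                            alpha = m$alpha, sigma2 = m$sigma2,
                            hyper = m$hyper, shrink = m$shrink),
                       path, digits = NA)
  invisible(path)
}

#' Residualize a phenotype on structure-group indicators
#'
#' Alternative to adjusting the genotype matrix: removes the group means
#' from the phenotype instead.
#'
#' @param y numeric phenotype vector (named by accession or in group order)
#' @param groups group labels
#' @return residualized phenotype (grand mean re-added)
#' @export
residualize_phenotype <- function(y, groups) {
  if (!is.null(names(y)) && !is.null(names(groups))) groups <- groups[names(y)]
  groups <- factor(groups)
  gm <- tapply(y, groups, mean)
  y - gm[groups] + mean(y)
}
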