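#' Discriminant analysis of principal components (DAPC)
#'
#' Infers population structure from a complete dosage matrix: (1) columns
#' are centred/scaled and projected onto the leading principal components;
#' (2) k-means (10 starts) is run for every candidate number of clusters
#' and scored with BIC = n*ln(WSS/n) + k*ln(n); (3) the k minimising BIC
#' is retained (ties broken towards the smallest k); (4) linear
#' discriminant analysis on the PC scores with the k-means labels gives
#' min(k-1, n_da_axes) discriminant axes; (5) membership probabilities are
#' the LDA posterior probabilities (Gaussian class-conditional densities
#' with shared covariance).
#'
#' @param numeric a `numeric_genotypes` object or a complete numeric
#'   matrix (accessions x markers); missing entries are an error — impute
#'   first (see [ppca_impute()]).
#' @param k_range candidate cluster numbers (default 1:8)
#' @param n_pcs number of retained principal components (default
#'   min(n/3, 100), a common guard against over-fitting the discriminant
#'   step)
#' @param n_da_axes maximum number of discriminant axes (default 5)
#' @param seed integer seed for the k-means starts
#' @return object of class `dapc_fit`: `k` (chosen number of groups),
#'   `groups` (hard labels), `membership` (n x k posterior matrix),
#'   `axes` (discriminant-axis coordinates), `bic` (data.frame k, bic),
#'   `n_pcs`, `pc_scores`.
#' @export
dapc_fit <- function(numeric, k_range = 1:8, n_pcs = NULL, n_da_axes = 5,
                     seed = 1L) {
  X <- if (inherits(numeric, "numeric_genotypes")) numeric$X else as.matrix(numeric)
  if (anyNA(X)) stop("dapc_fit() needs a complete matrix; impute first")
  n <- nrow(X)
  if (any(k_range > n)) stop("k_range contains k > number of accessions")
  if (is.null(n_pcs)) n_pcs <- min(floor(n / 3), 100)
  n_pcs <- min(n_pcs, n - 1, ncol(X))
  keep <- apply(X, 2, sd) > 0
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  S <- pc$x[, seq_len(min(n_pcs, ncol(pc$x))), drop = FALSE]

  set.seed(seed)
  km <- lapply(k_range, function(k) {
    if (k == 1) list(cluster = rep(1L, n), tot.withinss = sum(scale(S, scale = FALSE)^2))
    else kmeans(S, centers = k, nstart = 10, iter.max = 50)
  })
  wss <- vapply(km, function(f) f$tot.withinss, numeric(1))
  bic <- n * log(wss / n) + k_range * log(n)
  best <- which(bic == min(bic))[1]        # ties -> smallest k (k_range sorted)
  k <- k_range[best]
  groups <- km[[best]]$cluster
  names(groups) <- rownames(X)

  if (k == 1) {
    membership <- matrix(1, n, 1, dimnames = list(rownames(X), "1"))
    axes <- matrix(numeric(0), n, 0, dimnames = list(rownames(X), NULL))
  } else {
    n_axes <- min(k - 1, n_da_axes)
    ld <- MASS::lda(S, grouping = factor(groups))
    pred <- predict(ld, S)
    membership <- pred$posterior
    axes <- pred$x[, seq_len(min(n_axes, ncol(pred$x))), drop = FALSE]
    rownames(membership) <- rownames(axes) <- rownames(X)
  }
  structure(list(k = k, groups = groups, membership = membership,
                 axes = axes, bic = data.frame(k = k_range, bic = bic),
                 n_pcs = n_pcs, pc_scores = S),
            class = "dapc_fit")
}

#' @method print dapc_fit
#' @export
print.dapc_fit <- function(x, ...) {
  cat("dapc_fit:", length(x$groups), "accessions,", x$n_pcs, "PCs, chosen k =",
      x$k, "\n  group sizes:", paste(table(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Build a structure assignment from an external membership table
#'
#' Wraps group/membership output of an external clustering program (e.g. a
#' Bayesian admixture model) in the same shape as [dapc_fit()], so the
#' admixture summary and downstream adjustment accept either source.
#'
#' @param membership n x K matrix of membership probabilities (rows sum
#'   to 1), rownames = accessions
#' @return a `dapc_fit`-classed object with `k`, `groups`, `membership`
#' @export
structure_assignment <- function(membership) {
  membership <- as.matrix(membership)
  if (any(abs(rowSums(membership) - 1) > 1e-6))
    stop("membership rows must sum to 1")
  groups <- max.col(membership)
  names(groups) <- rownames(membership)
  structure(list(k = ncol(membership), groups = groups,
                 membership = membership,
                 axes = matrix(numeric(0), nrow(membership), 0),
                 bic = NULL, n_pcs = NA_integer_, pc_scores = NULL),
            class = "dapc_fit")
}

#' Fraction of admixed accessions
#'
#' An accession is admixed at threshold `t` when its largest membership
#' probability is below 1 - t.
#'
#' @param assignment a `dapc_fit` (or [structure_assignment()])
#' @param threshold admixture threshold in (0, 0.5] (default 0.2)
#' @return proportion of admixed accessions
#' @export
admixed_fraction <- function(assignment, threshold = 0.2) {
  stopifnot(threshold > 0, threshold <= 0.5)
  mx <- apply(assignment$membership, 1, max)
  mean(mx < 1 - threshold)
}

#' ANOVA of passport variables on discriminant axes
#'
#' One-way ANOVA of each discriminant axis's coordinates on each
#' categorical passport variable; reports the F statistic and p-value.
#' Levels with fewer than 2 members are dropped with a warning.
#'
#' @param assignment a `dapc_fit` with discriminant axes
#' @param labels_table data.frame of categorical variables, rows matching
#'   (or named by) the accessions
#' @return data.frame: variable, axis, F, p_value
#' @export
axis_group_anova <- function(assignment, labels_table) {
  axes <- assignment$axes
  if (ncol(axes) == 0) stop("assignment has no discriminant axes")
  labels_table <- as.data.frame(labels_table)
  if (!is.null(rownames(labels_table)) &&
      all(rownames(axes) %in% rownames(labels_table)))
    labels_table <- labels_table[rownames(axes), , drop = FALSE]
  out <- list()
  for (v in names(labels_table)) {
    lab <- as.character(labels_table[[v]])
    tab <- table(lab)
    small <- names(tab)[tab < 2]
    if (length(small)) {
      warning("dropping level(s) with <2 members in ", v, ": ",
              paste(small, collapse = ", "))
      lab[lab %in% small] <- NA
    }
    if (length(unique(lab[!is.na(lab)])) < 2) {
      warning("variable ", v, " has <2 usable levels; skipped")
      next
    }
    for (ax in seq_len(ncol(axes))) {
      keep <- !is.na(lab)
      fit <- aov(axes[keep, ax] ~ factor(lab[keep]))
      an <- anova(fit)
      out[[length(out) + 1]] <- data.frame(
        variable = v, axis = ax, F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no usable passport variable")
  do.call(rbind, out)
}

#' Write a structure assignment as delimited text
#' @param assignment a `dapc_fit`
#' @param path output path
#' @export
write_assignment <- function(assignment, path) {
  df <- data.frame(accession = names(assignment$groups),
                   group = unname(assignment$groups),
                   assignment$membership, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("q", seq_len(ncol(assignment$membership)))
  if (ncol(assignment$axes) > 0) {
    ax <- as.data.frame(assignment$axes)
    names(ax) <- paste0("LD", seq_len(ncol(ax)))
    df <- cbind(df, ax)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
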