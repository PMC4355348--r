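#' Per-marker and per-system diversity statistics
#'
#' Computes, for every marker, the minor-allele (or minor allele-class)
#' frequency, the polymorphism information content PIC = 1 - sum(p_i^2)
#' over allele frequencies (heterogeneous calls excluded), missing and
#' heterogeneous call rates and a monomorphic flag; and per marker system
#' the counts, % monomorphic, % accessions with at least one heterogeneous
#' call, % markers with MAF < 0.01, and mean/min/max PIC.
#'
#' @param panel a [marker_panel()]
#' @return list of class `marker_summary` with `per_marker` and
#'   `per_system` data.frames.
#' @export
marker_stats <- function(panel) {
  calls <- panel$calls
  if (ncol(calls) == 0) stop("empty panel")
  p_mk <- ncol(calls)
  maf <- pic <- miss <- het <- numeric(p_mk)
  n_alleles <- integer(p_mk)
  for (j in seq_len(p_mk)) {
    a <- calls[, j]
    miss[j] <- mean(is.na(a))
    het[j] <- mean(a == HET_TOKEN, na.rm = TRUE)
    if (is.nan(het[j])) het[j] <- 0
    hom <- a[!is.na(a) & a != HET_TOKEN]
    codes <- panel$allele_codes[[j]]
    n_alleles[j] <- length(codes)
    if (length(hom) == 0) {
      maf[j] <- pic[j] <- NA_real_
      next
    }
    freq <- table(hom) / length(hom)
    pic[j] <- 1 - sum(freq^2)
    maf[j] <- if (length(freq) < 2) 0 else min(freq)
  }
  mono <- !is.na(pic) & n_alleles <= 1
  per_marker <- data.frame(marker = colnames(calls),
                           system = unname(panel$system),
                           n_alleles = n_alleles, maf = maf, pic = pic,
                           missing_rate = miss, het_rate = het,
                           monomorphic = mono, stringsAsFactors = FALSE)
  per_system <- do.call(rbind, lapply(c("SNP", "SSR", "RBIP"), function(sys) {
    sel <- per_marker$system == sys
    if (!any(sel)) return(NULL)
    pm <- per_marker[sel, ]
    def <- !is.na(pm$pic)
    acc_het <- mean(apply(calls[, sel, drop = FALSE] == HET_TOKEN, 1,
                          any, na.rm = TRUE))
    if (!any(def)) return(data.frame(
      system = sys, n_markers = sum(sel), n_monomorphic = 0L,
      pct_monomorphic = NA_real_, pct_het_accessions = 100 * acc_het,
      pct_maf_below_0.01 = NA_real_, mean_pic = NA_real_,
      min_pic = NA_real_, max_pic = NA_real_, stringsAsFactors = FALSE))
    data.frame(system = sys, n_markers = sum(sel),
               n_monomorphic = sum(pm$monomorphic, na.rm = TRUE),
               pct_monomorphic = 100 * mean(pm$monomorphic[def]),
               pct_het_accessions = 100 * acc_het,
               pct_maf_below_0.01 = 100 * mean(pm$maf[def] < 0.01),
               mean_pic = mean(pm$pic[def]), min_pic = min(pm$pic[def]),
               max_pic = max(pm$pic[def]), stringsAsFactors = FALSE)
  }))
  structure(list(per_marker = per_marker, per_system = per_system),
            class = "marker_summary")
}

#' @method print marker_summary
#' @export
print.marker_summary <- function(x, ...) {
  cat("marker_summary over", nrow(x$per_marker), "markers\n")
  print(x$per_system, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Rogers pairwise distances for one marker system
#'
#' For every pair of accessions, the distance is the number of co-scored
#' markers (both calls non-missing) at which the calls differ, divided by
#' the number of co-scored markers. A heterogeneous call differs from
#' every homozygous call (it signals a genuinely different seed lot);
#' two heterogeneous calls are treated as equal. Pairs with no co-scored
#' marker get `NA`.
#'
#' @param panel a [marker_panel()]
#' @param marker_system one of "SNP", "SSR", "RBIP", or "all"
#' @return list of class `distance_matrix`: `d` (symmetric n x n matrix,
#'   zero diagonal) and `n_scored` (markers co-scored per pair).
#' @export
rogers_distance <- function(panel, marker_system = "all") {
  sel <- if (identical(marker_system, "all")) rep(TRUE, ncol(panel$calls))
         else panel$system == marker_system
  if (!any(sel)) stop("no markers of system ", marker_system)
  calls <- panel$calls[, sel, drop = FALSE]
  n <- nrow(calls)
  diffs <- matrix(0, n, n)
  scored <- matrix(0, n, n)
  for (j in seq_len(ncol(calls))) {
    a <- match(calls[, j], unique(calls[, j]))  # integer codes, NA kept
    ok <- !is.na(calls[, j])
    if (!any(ok)) next
    obs <- outer(ok, ok, "&")
    ne <- outer(a, a, "!=")
    ne[!obs] <- FALSE
    diffs <- diffs + ne
    scored <- scored + obs
  }
  d <- diffs / scored
  d[scored == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(calls), rownames(calls))
  dimnames(scored) <- dimnames(d)
  structure(list(d = d, n_scored = scored, system = marker_system),
            class = "distance_matrix")
}

#' @method print distance_matrix
#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix (", x$system, "): ", nrow(x$d), " accessions, mean RD = ",
      round(mean(x$d[upper.tri(x$d)], na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Write a distance matrix as square delimited text
#' @param d a `distance_matrix`
#' @param path output path
#' @export
write_distance_matrix <- function(d, path) {
  write.table(data.frame(accession = rownames(d$d), d$d, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

upper_vec <- function(m) m[upper.tri(m)]

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the upper-triangle entries.
#' Significance is one-sided: rows/columns of `d2` are permuted jointly
#' `n_perm` times and p = (1 + #{r_perm >= r_obs}) / (n_perm + 1).
#'
#' @param d1,d2 `distance_matrix` objects (or plain symmetric matrices)
#'   over the same accessions in the same order
#' @param n_perm number of permutations (>= 99; default 999)
#' @param seed integer seed
#' @return list with `r`, `p_value`, `n_perm`
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1L) {
  m1 <- if (inherits(d1, "distance_matrix")) d1$d else as.matrix(d1)
  m2 <- if (inherits(d2, "distance_matrix")) d2$d else as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices have different dimensions")
  if (n_perm < 99) stop("n_perm must be >= 99")
  set.seed(seed)
  v1 <- upper_vec(m1)
  r_obs <- cor(v1, upper_vec(m2), use = "complete.obs")
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    cor(v1, upper_vec(m2[idx, idx]), use = "complete.obs")
  }, numeric(1))
  list(r = r_obs, p_value = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
       n_perm = n_perm)
}

#' Mean within- and between-group distances
#'
#' @param d a `distance_matrix` (or plain symmetric matrix)
#' @param labels group labels named by accession, or in matrix order;
#'   `NA`-labelled accessions are skipped
#' @return G x G symmetric matrix of mean pairwise distances; diagonal =
#'   within-group means (`NA` for singleton groups).
#' @export
group_distance_table <- function(d, labels) {
  m <- if (inherits(d, "distance_matrix")) d$d else as.matrix(d)
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  keep <- !is.na(labels)
  m <- m[keep, keep, drop = FALSE]
  labels <- labels[keep]
  gs <- sort(unique(labels))
  out <- matrix(NA_real_, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) for (j in i:length(gs)) {
    a <- which(labels == gs[i]); b <- which(labels == gs[j])
    if (i == j) {
      if (length(a) < 2) next
      out[i, j] <- mean(m[a, a][upper.tri(m[a, a])], na.rm = TRUE)
    } else {
      out[i, j] <- out[j, i] <- mean(m[a, b], na.rm = TRUE)
    }
  }
  out
}

#' Complete-linkage hierarchical clustering of accessions
#'
#' Standard complete-linkage agglomeration on the Rogers distance matrix
#' (equivalently on the 1 - RD similarity).
#'
#' @param d a `distance_matrix` (or plain symmetric matrix) with no
#'   undefined entries
#' @return an [stats::hclust] object
#' @export
complete_linkage_tree <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$d else as.matrix(d)
  if (nrow(m) < 2) stop("need at least 2 accessions to cluster")
  if (anyNA(m)) stop("distance matrix has undefined entries")
  hclust(as.dist(m), method = "complete")
}

#' Serialize a dendrogram to Newick
#' @param tree an `hclust` object
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Linkage disequilibrium decay along the genetic map
#'
#' For every pair of mapped markers on the same linkage group, computes
#' the composite LD r^2 (squared Pearson correlation of dosage vectors
#' over accessions non-missing at both markers — appropriate for inbred
#' lines) against the cM distance. Pairs involving a zero-variance marker
#' are skipped.
#'
#' @param numeric a `numeric_genotypes` object from [encode_numeric()]
#' @param map genetic map data.frame (marker, lg, pos_cm)
#' @return data.frame with columns marker1, marker2, lg, dist_cm, r2
#' @export
ld_decay <- function(numeric, map) {
  X <- numeric$X
  map <- map[map$marker %in% colnames(X), , drop = FALSE]
  out <- vector("list", 0)
  for (lg in unique(map$lg)) {
    mk <- map$marker[map$lg == lg]
    if (length(mk) < 2) next
    pos <- setNames(map$pos_cm[map$lg == lg], mk)
    Xl <- X[, mk, drop = FALSE]
    r <- suppressWarnings(cor(Xl, use = "pairwise.complete.obs"))
    idx <- which(upper.tri(r), arr.ind = TRUE)
    out[[length(out) + 1]] <- data.frame(
      marker1 = mk[idx[, 1]], marker2 = mk[idx[, 2]], lg = lg,
      dist_cm = abs(pos[idx[, 2]] - pos[idx[, 1]]),
      r2 = r[idx]^2, stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(out) == 0) stop("no linkage group with >= 2 mapped markers")
  res <- do.call(rbind, out)
  res[!is.na(res$r2), , drop = FALSE]
}
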