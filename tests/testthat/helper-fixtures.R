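# Small panels and matrices built in code for the tests.

# hand-written panel: 4 accessions x 3 SNPs + 1 SSR
tiny_panel <- function() {
  calls <- matrix(c("A", "A", "G", "G",
                    "C", "HET", "T", "T",
                    "A", "A", "A", "A",
                    "a1", "a2", "a3", "a1"),
                  nrow = 4,
                  dimnames = list(paste0("acc", 1:4),
                                  c("snp1", "snp2", "snp3", "ssr1")))
  marker_panel(calls, c("SNP", "SNP", "SNP", "SSR"))
}

# iid (unstructured) random biallelic panel
random_panel <- function(n = 20, p = 30, miss = 0, het = 0, seed = 1) {
  set.seed(seed)
  freq <- runif(p, 0.1, 0.9)
  calls <- vapply(freq, function(f)
    ifelse(rbinom(n, 1, f) == 1, "A", "B"), character(n))
  if (het > 0) calls[matrix(runif(n * p) < het, n, p)] <- "HET"
  if (miss > 0) calls[matrix(runif(n * p) < miss, n, p)] <- NA
  dimnames(calls) <- list(sprintf("acc%02d", 1:n), sprintf("m%03d", 1:p))
  marker_panel(calls, "SNP")
}

# small structured simulation used by several suites
small_config <- function(seed = 7, fst = 0.4, ...) {
  panel_sim_config(n_accessions = 150, group_sizes = c(50, 50, 50),
                   fst = fst, n_snp = 120, n_ssr = 10, n_rbip = 10,
                   seed = seed, ...)
}

# three well-separated isotropic Gaussian blobs (no within-group substructure)
gaussian_blobs <- function(n_per = 40, d = 80, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per),
             matrix(rnorm(n_per * d, mean = -sep), n_per))
  dimnames(X) <- list(sprintf("a%03d", seq_len(3 * n_per)),
                      sprintf("v%02d", seq_len(d)))
  X
}

rand_dosage <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.9)[rep(1:p, each = n)]), n, p)
  dimnames(X) <- list(sprintf("a%03d", 1:n), sprintf("m%03d", 1:p))
  X
}

# independent oracle: naive complete-linkage agglomeration returning the
# cophenetic distance matrix
brute_complete_linkage_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    coph[clusters[[i]], clusters[[j]]] <- best[1]
    coph[clusters[[j]], clusters[[i]]] <- best[1]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  coph
}

# independent oracle: multi-population Fst (Weir & Cockerham theta) from
# biallelic dosages and group labels
wc_fst <- function(X, groups) {
  groups <- factor(groups)
  K <- nlevels(groups)
  a_sum <- abc_sum <- 0
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ok <- !is.na(x)
    ni <- tapply(ok, groups, sum)
    if (any(ni < 2)) next
    pi <- tapply(x[ok], groups[ok], mean) / 2
    hi <- tapply(x[ok] == 1, groups[ok], mean)
    nbar <- mean(ni)
    nc <- (K * nbar - sum(ni^2) / (K * nbar)) / (K - 1)
    pbar <- sum(ni * pi) / (K * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((K - 1) * nbar)
    hbar <- sum(ni * hi) / (K * nbar)
    if (pbar <= 0 || pbar >= 1) next
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (K - 1) / K * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (K - 1) / K * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + cc
  }
  a_sum / abc_sum
}
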