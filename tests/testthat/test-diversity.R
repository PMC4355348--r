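test_that("PIC follows the gene-diversity formula", {
  # biallelic p = 0.5 -> 0.5; four equifrequent alleles -> 0.75
  calls <- cbind(m1 = c("A", "A", "G", "G"),
                 m2 = c("a1", "a2", "a3", "a4"),
                 m3 = rep("A", 4))
  rownames(calls) <- paste0("a", 1:4)
  st <- marker_stats(marker_panel(calls, c("SNP", "SSR", "SNP")))
  expect_equal(st$per_marker$pic, c(0.5, 0.75, 0), tolerance = 1e-12)
  expect_true(st$per_marker$monomorphic[3])
  expect_equal(st$per_marker$maf[3], 0)
})

test_that("PIC is invariant under allele relabeling", {
  p <- random_panel(30, 10, seed = 2)
  relab <- p$calls
  relab[relab == "A"] <- "x"; relab[relab == "B"] <- "y"
  st1 <- marker_stats(p)
  st2 <- marker_stats(marker_panel(relab, "SNP"))
  expect_equal(st1$per_marker$pic, st2$per_marker$pic)
})

test_that("Rogers distance is the proportion of mismatching co-scored markers", {
  calls <- rbind(a1 = c("A", "C", "A", "T", "G"),
                 a2 = c("A", "C", "A", "T", "G"),
                 a3 = c("G", "C", "A", "A", "G"),   # differs at 2 of 5
                 a4 = c("G", "A", "G", "A", "C"))   # differs from a1 at all 5
  colnames(calls) <- paste0("m", 1:5)
  d <- rogers_distance(marker_panel(calls, "SNP"))
  expect_equal(d$d["a1", "a2"], 0)
  expect_equal(d$d["a1", "a3"], 0.4)
  expect_equal(d$d["a1", "a4"], 1)
  # heterogeneous differs from both homozygotes
  h <- rbind(a1 = c("A", "A"), a2 = c("HET", "A"))
  colnames(h) <- c("m1", "m2")
  dh <- rogers_distance(marker_panel(h, "SNP"))
  expect_equal(dh$d["a1", "a2"], 0.5)
})

test_that("Rogers distance is a semimetric satisfying the triangle inequality", {
  for (s in 1:5) {
    p <- random_panel(10, 15, seed = 30 + s)
    d <- rogers_distance(p)$d
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:10) for (j in 1:10) for (k in 1:10)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("mean Rogers distance matches the allele-frequency expectation", {
  p <- random_panel(80, 60, seed = 8)
  d <- rogers_distance(p)$d
  num <- encode_numeric(p)
  n <- 80
  # mismatch probability per marker for two accessions drawn without
  # replacement: 2p(1-p) * n/(n-1)
  expected <- mean(2 * num$p * (1 - num$p)) * n / (n - 1)
  expect_equal(mean(d[upper.tri(d)]), expected, tolerance = 0.02)
})

test_that("the Mantel statistic is correlation-based and matches vegan", {
  p1 <- random_panel(15, 40, seed = 1)
  p2 <- random_panel(15, 40, seed = 2)
  d1 <- rogers_distance(p1)
  d2 <- rogers_distance(p2)
  expect_equal(mantel_test(d1, d1, 99, 1)$r, 1)
  d_lin <- 0.5 * d1$d + 0.1; diag(d_lin) <- 0
  expect_equal(mantel_test(d1, d_lin, 99, 1)$r, 1)
  ref <- vegan::mantel(as.dist(d1$d), as.dist(d2$d), permutations = 99)
  expect_equal(mantel_test(d1, d2, 99, 1)$r, unname(ref$statistic),
               tolerance = 1e-12)
  expect_error(mantel_test(d1, rogers_distance(random_panel(10, 5))),
               "dimensions")
})

test_that("group distance tables average within and between groups", {
  d <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(1, 1, 0, 0), c(1, 1, 0, 0))
  dimnames(d) <- list(paste0("a", 1:4), paste0("a", 1:4))
  tab <- group_distance_table(d, setNames(c("g1", "g1", "g2", "g2"),
                                          paste0("a", 1:4)))
  expect_equal(unname(tab), rbind(c(0, 1), c(1, 0)))
  tab1 <- group_distance_table(d, rep("g", 4))
  expect_equal(dim(tab1), c(1, 1))
  expect_equal(tab1[1, 1], mean(d[upper.tri(d)]))
})

test_that("complete linkage reproduces known merges and ultrametric input", {
  d <- rbind(c(0, 0.1, 0.9), c(0.1, 0, 0.9), c(0.9, 0.9, 0))
  dimnames(d) <- list(c("A", "B", "C"), c("A", "B", "C"))
  tr <- complete_linkage_tree(d)
  expect_equal(tr$height, c(0.1, 0.9))
  expect_equal(sort(tr$labels[-tr$merge[1, ]]), c("A", "B"))
  coph <- as.matrix(stats::cophenetic(tr))[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(unname(coph), unname(d))   # ultrametric is reproduced exactly
})

test_that("complete linkage agrees with a brute-force agglomeration oracle", {
  for (s in 1:20) {
    set.seed(400 + s)
    m <- matrix(runif(64), 8, 8)
    d <- (m + t(m)) / 2
    diag(d) <- 0
    tr <- complete_linkage_tree(d)
    expect_equal(unname(as.matrix(stats::cophenetic(tr))),
                 brute_complete_linkage_cophenetic(d), tolerance = 1e-12)
  }
})

test_that("dendrograms serialize to Newick", {
  p <- random_panel(8, 20, seed = 12)
  tr <- complete_linkage_tree(rogers_distance(p)$d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  ph <- ape::read.tree(f)
  expect_setequal(ph$tip.label, rownames(p$calls))
})

test_that("LD r2 is 1 for duplicated markers and ~1/n for independent loci", {
  X <- rand_dosage(372, 2, seed = 5)
  X <- cbind(X, dup = X[, 1])
  map <- data.frame(marker = colnames(X), lg = "LG1", pos_cm = c(0, 5, 0))
  ld <- ld_decay(list(X = X), map)
  r2_dup <- ld$r2[ld$marker1 == "m001" & ld$marker2 == "dup"]
  expect_equal(r2_dup, 1, tolerance = 1e-12)

  Xi <- rand_dosage(372, 40, seed = 6)   # 780 independent pairs
  mapi <- data.frame(marker = colnames(Xi), lg = "LG1",
                     pos_cm = seq(0, 39))
  ldi <- ld_decay(list(X = Xi), mapi)
  expect_lt(mean(ldi$r2), 0.01)
})
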