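test_that("marker table round-trips through write/read", {
  p <- tiny_panel()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(p, f)
  p2 <- read_marker_table(f)
  expect_identical(p2$calls, p$calls)
  expect_identical(p2$system, p$system)
  expect_identical(p2$allele_codes, p$allele_codes)
})

test_that("missing tokens and validation errors behave as specified", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,m1,m2", "#system,SNP,SNP", "a1,A,-", "a2,G,C"), f)
  p <- read_marker_table(f)
  expect_true(is.na(p$calls["a1", "m2"]))
  expect_equal(sum(is.na(p$calls)), 1)

  # duplicate accession ids are a hard error
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,m1", "#system,SNP", "a1,A", "a1,G"), f2)
  expect_error(read_marker_table(f2), "duplicate accession")

  # >2 allele codes at a SNP marker names the marker
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,bad1", "#system,SNP", "a1,A", "a2,G", "a3,T"), f3)
  expect_error(read_marker_table(f3), "bad1")
})

test_that("dosage encoding uses the minor allele with lexicographic ties", {
  calls <- matrix(c("A", "A", "G", "G"), 4, 1,
                  dimnames = list(paste0("a", 1:4), "m1"))
  num <- encode_numeric(marker_panel(calls, "SNP"))
  expect_equal(unname(num$X[, 1]), c(0, 0, 2, 2))   # tie -> ref "A"
  expect_equal(unname(num$p["m1"]), 0.5)

  mono <- matrix("A", 4, 1, dimnames = list(paste0("a", 1:4), "m1"))
  num2 <- encode_numeric(marker_panel(mono, "SNP"))
  expect_equal(unname(num2$X[, 1]), rep(0, 4))
  expect_equal(unname(num2$p["m1"]), 0)

  het <- matrix(c("A", "HET", "G"), 3, 1,
                dimnames = list(paste0("a", 1:3), "m1"))
  num3 <- encode_numeric(marker_panel(het, "SNP"))
  expect_equal(unname(num3$X[, 1]), c(0, 1, 2))

  expect_error(encode_numeric(tiny_panel()), "SSR")
})

test_that("dosage column means equal twice the minor allele frequency", {
  p <- random_panel(40, 25, seed = 3)
  num <- encode_numeric(p)
  expect_equal(unname(colMeans(num$X)), unname(2 * num$p), tolerance = 1e-12)
})

test_that("marker filtering removes MAF/missing/heterogeneous violators", {
  # 351 SNPs of which exactly 20 violate a threshold -> 331 retained
  set.seed(11)
  n <- 60
  calls <- vapply(runif(351, 0.2, 0.8), function(f)
    ifelse(rbinom(n, 1, f) == 1, "A", "B"), character(n))
  dimnames(calls) <- list(sprintf("a%02d", 1:n), sprintf("s%03d", 1:351))
  # 8 rare markers (MAF 1/60 <= 2%), 6 too-missing, 6 too-heterogeneous
  for (j in 1:8) calls[, j] <- c("B", rep("A", n - 1))
  for (j in 9:14) calls[1:30, j] <- NA
  for (j in 15:20) calls[1:30, j] <- "HET"
  panel <- marker_panel(calls, "SNP")
  res <- filter_markers(panel)
  expect_equal(ncol(res$panel$calls), 331)
  expect_equal(nrow(res$report), 20)
  expect_setequal(res$report$marker, sprintf("s%03d", 1:20))

  # boundary: MAF exactly at the threshold is excluded
  b <- matrix(c(rep("A", 49), "G"), 50, 1,
              dimnames = list(sprintf("a%02d", 1:50), "m1"))
  expect_warning(res_b <- filter_markers(marker_panel(b, "SNP"),
                                         maf_max_excl = 0.02), "all markers")
  expect_equal(ncol(res_b$panel$calls), 0)
  expect_match(res_b$report$reason, "MAF")

  # no violators -> unchanged, and filtering is idempotent
  clean <- random_panel(30, 40, seed = 5)
  res_c <- filter_markers(clean)
  expect_equal(nrow(res_c$report), 0)
  res_c2 <- filter_markers(res_c$panel)
  expect_identical(res_c2$panel$calls, res_c$panel$calls)
})

test_that("phenotype tables are typed, keyed and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- expand.grid(accession = c("a1", "a2"), trait = "TSW", year = "2007",
                    block = c("B1", "B2"), stringsAsFactors = FALSE)
  df$value <- c(10, 20, 11, 21)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- read_phenotype_table(f)
  expect_s3_class(ph, "phenotype_table")
  expect_equal(nrow(ph), 4)

  writeLines("accession\ttrait\tyear\tblock\tvalue", f)
  expect_warning(ph0 <- read_phenotype_table(f), "empty")
  expect_equal(nrow(ph0), 0)

  df2 <- rbind(df, df[1, ])
  write.table(df2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotype_table(f), "duplicate")

  df$value <- c("10", "twenty", "11", "21")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_phenotype_table(f), "row")
})

test_that("VCF genotypes map onto panel calls", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "1\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "1\t200\tsnpB\tC\tT\t.\tPASS\t.\tGT\t1|1\t./.\t0/0"), f)
  p <- read_vcf_markers(f)
  expect_equal(unname(p$calls[, "snpA"]), c("A", "G", "HET"))
  expect_equal(unname(p$calls[, "snpB"]), c("T", NA, "C"))
  expect_true(all(p$system == "SNP"))
})
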