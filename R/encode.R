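#' Encode biallelic markers as minor-allele dosages
#'
#' Produces the numeric genotype matrix used by all prediction methods.
#' The reference allele at each marker is the major allele (ties broken by
#' taking the lexicographically first code); calls are coded as dosage of
#' the minor allele: major homozygote 0, heterogeneous 1, minor homozygote
#' 2. Missing calls become `NA` for downstream imputation.
#'
#' @param panel a [marker_panel()]
#' @param biallelic_only if `TRUE` (default) only SNP/RBIP markers are
#'   encoded and the presence of SSR markers is an error; set markers to
#'   encode explicitly by subsetting the panel first.
#' @return a list of class `numeric_genotypes`: `X` (accession x marker
#'   dosage matrix), `ref_allele`, `minor_allele` and `p` (minor allele
#'   frequency over non-missing calls, heterogeneous calls contributing
#'   half a copy of each allele) per marker.
#' @export
encode_numeric <- function(panel, biallelic_only = TRUE) {
  sys <- panel$system
  if (biallelic_only) {
    if (any(sys == "SSR"))
      stop("SSR markers cannot be dosage-encoded; subset to SNP/RBIP first")
  }
  calls <- panel$calls
  p_mk <- ncol(calls)
  X <- matrix(NA_real_, nrow(calls), p_mk, dimnames = dimnames(calls))
  ref <- minor <- character(p_mk)
  p <- numeric(p_mk)
  for (j in seq_len(p_mk)) {
    a <- calls[, j]
    codes <- panel$allele_codes[[j]]
    if (length(codes) > 2)
      stop("marker ", colnames(calls)[j], " has >2 alleles")
    # allele counts: homozygote contributes 2 copies, heterogeneous 1+1
    cnt <- setNames(numeric(length(codes)), codes)
    for (cd in codes) cnt[cd] <- 2 * sum(a == cd, na.rm = TRUE)
    n_het <- sum(a == HET_TOKEN, na.rm = TRUE)
    if (length(codes) == 2) cnt <- cnt + n_het
    # major allele = reference; ties -> lexicographically first
    if (length(codes) == 0) {           # all missing/het at this marker
      ref[j] <- minor[j] <- NA_character_
      p[j] <- NA_real_
      X[a == HET_TOKEN & !is.na(a), j] <- 1
      next
    }
    ord <- order(-cnt, names(cnt))
    ref[j] <- names(cnt)[ord[1]]
    minor[j] <- if (length(codes) == 2) names(cnt)[ord[2]] else NA_character_
    tot <- sum(cnt)
    p[j] <- if (tot > 0 && length(codes) == 2) cnt[minor[j]] / tot else 0
    x <- rep(NA_real_, length(a))
    x[a == ref[j]] <- 0
    x[a == HET_TOKEN] <- 1
    if (length(codes) == 2) x[a == minor[j]] <- 2
    X[, j] <- x
  }
  structure(list(X = X, ref_allele = setNames(ref, colnames(calls)),
                 minor_allele = setNames(minor, colnames(calls)),
                 p = setNames(p, colnames(calls))),
            class = "numeric_genotypes")
}

#' @method print numeric_genotypes
#' @export
print.numeric_genotypes <- function(x, ...) {
  cat("numeric_genotypes:", nrow(x$X), "accessions x", ncol(x$X), "markers;",
      sum(is.na(x$X)), "missing entries\n")
  invisible(x)
}

#' Filter markers on MAF, missingness and heterogeneity
#'
#' Removes markers whose minor-allele frequency is less than or equal to
#' `maf_max_excl` (for biallelic markers; for SSR the minimum allele-class
#' frequency is used in the report but SSR markers are only excluded on
#' missing/heterogeneous rate), whose missing rate exceeds `max_missing`,
#' or whose heterogeneous-call rate exceeds `max_heterogeneous`.
#'
#' @param panel a [marker_panel()]
#' @param maf_max_excl exclusive-retention MAF bound (default 0.02: markers
#'   with MAF <= 2\% are dropped)
#' @param max_missing maximum tolerated missing-call rate (default 0.10)
#' @param max_heterogeneous maximum tolerated heterogeneous-call rate
#'   (default 0.10)
#' @return list with `panel` (retained markers) and `report`, a data.frame
#'   of excluded markers with their reason(s).
#' @export
filter_markers <- function(panel, maf_max_excl = 0.02, max_missing = 0.10,
                           max_heterogeneous = 0.10) {
  stopifnot(maf_max_excl >= 0, maf_max_excl <= 1,
            max_missing >= 0, max_missing <= 1,
            max_heterogeneous >= 0, max_heterogeneous <= 1)
  calls <- panel$calls
  n <- nrow(calls)
  miss_rate <- colMeans(is.na(calls))
  het_rate <- colMeans(calls == HET_TOKEN, na.rm = TRUE)
  het_rate[is.nan(het_rate)] <- 0
  maf <- marker_maf(panel)
  biallelic <- panel$system %in% c("SNP", "RBIP")
  excl_maf <- biallelic & !is.na(maf) & maf <= maf_max_excl
  excl_miss <- miss_rate > max_missing
  excl_het <- het_rate > max_heterogeneous
  drop <- excl_maf | excl_miss | excl_het
  reason <- vapply(seq_along(drop), function(j) {
    paste(c(if (excl_maf[j]) "MAF", if (excl_miss[j]) "missing",
            if (excl_het[j]) "heterogeneous"), collapse = "+")
  }, character(1))
  report <- data.frame(marker = colnames(calls)[drop],
                       system = unname(panel$system[drop]),
                       maf = unname(maf[drop]),
                       missing_rate = unname(miss_rate[drop]),
                       het_rate = unname(het_rate[drop]),
                       reason = reason[drop],
                       stringsAsFactors = FALSE)
  if (all(drop)) warning("filter_markers: all markers excluded")
  list(panel = panel[, !drop], report = report)
}

# Per-marker minor allele frequency.  Biallelic: frequency of the rarer
# allele (heterogeneous calls contribute one copy of each).  Multi-allelic
# (SSR): frequency of the rarest allele class.  All-missing markers -> NA.
marker_maf <- function(panel) {
  calls <- panel$calls
  vapply(seq_len(ncol(calls)), function(j) {
    a <- calls[, j]
    codes <- panel$allele_codes[[j]]
    if (length(codes) == 0) return(NA_real_)
    if (length(codes) == 1) return(0)
    cnt <- 2 * vapply(codes, function(cd) sum(a == cd, na.rm = TRUE), numeric(1))
    if (length(codes) == 2) cnt <- cnt + sum(a == HET_TOKEN, na.rm = TRUE)
    min(cnt) / sum(cnt)
  }, numeric(1))
}
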