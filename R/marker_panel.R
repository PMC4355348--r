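#' @useDynLib gspanel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats anova aov as.dist cor cutree dist hclust kmeans lm
#'   median optimize prcomp predict quantile rbeta rbinom rgamma rnorm runif
#'   sd setNames var complete.cases coef model.matrix pf
#' @importFrom utils head read.table write.table
#' @importFrom graphics abline plot
NULL

# Canonical internal tokens for the two special call states.
HET_TOKEN <- "HET"
MISSING_INPUT_TOKENS <- c("-", "", "NA", "N", "./.", ".")

#' Construct a marker panel
#'
#' A `marker_panel` stores categorical allele calls for a set of accessions
#' at markers of up to three systems (SNP, SSR, RBIP). Calls are opaque
#' allele-code strings; two special states exist: `NA` (missing) and
#' `"HET"` (heterogeneous, i.e. more than one allele observed for the
#' accession sample — in a selfing crop usually a mixture of homozygous
#' lines rather than a true heterozygote).
#'
#' @param calls character matrix, accessions in rows (rownames = accession
#'   ids), markers in columns (colnames = marker ids). `NA` = missing,
#'   `"HET"` = heterogeneous.
#' @param system character vector of marker systems, one of `"SNP"`,
#'   `"SSR"`, `"RBIP"` per marker (recycled if length 1).
#' @return An object of class `marker_panel` with elements `calls`,
#'   `system` (named by marker) and `allele_codes` (named list of the
#'   allele codes observed at each marker, sorted).
#' @export
marker_panel <- function(calls, system) {
  if (!is.matrix(calls) || !is.character(calls))
    stop("`calls` must be a character matrix")
  if ((is.null(rownames(calls)) && nrow(calls) > 0) ||
      (is.null(colnames(calls)) && ncol(calls) > 0))
    stop("`calls` must have accession rownames and marker colnames")
  if (anyDuplicated(rownames(calls)))
    stop("duplicate accession ids: ",
         paste(unique(rownames(calls)[duplicated(rownames(calls))]), collapse = ", "))
  if (anyDuplicated(colnames(calls)))
    stop("duplicate marker ids: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  system <- rep_len(as.character(system), ncol(calls))
  if (!all(system %in% c("SNP", "SSR", "RBIP")))
    stop("marker systems must be SNP, SSR or RBIP")
  names(system) <- colnames(calls)
  allele_codes <- lapply(seq_len(ncol(calls)), function(j) {
    a <- calls[, j]
    sort(unique(a[!is.na(a) & a != HET_TOKEN]))
  })
  names(allele_codes) <- colnames(calls)
  biallelic <- system %in% c("SNP", "RBIP")
  n_codes <- lengths(allele_codes)
  if (any(bad <- biallelic & n_codes > 2))
    stop("SNP/RBIP marker(s) with >2 allele codes: ",
         paste(colnames(calls)[bad], collapse = ", "))
  structure(list(calls = calls, system = system, allele_codes = allele_codes),
            class = "marker_panel")
}

#' @method print marker_panel
#' @export
print.marker_panel <- function(x, ...) {
  tab <- table(factor(x$system, levels = c("SNP", "SSR", "RBIP")))
  cat("marker_panel:", nrow(x$calls), "accessions x", ncol(x$calls), "markers\n")
  cat("  systems:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  missing: %.2f%%, heterogeneous: %.2f%%\n",
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == HET_TOKEN, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) dim(x$calls)

#' Subset a marker panel
#'
#' @param x a `marker_panel`
#' @param i accession index (rows)
#' @param j marker index (columns)
#' @param ... ignored
#' @export
`[.marker_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  marker_panel(x$calls[i, j, drop = FALSE], x$system[colnames(x$calls)[j]])
}

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

#' Read a genotype table
#'
#' Reads a delimited (tab or comma, auto-detected) genotype table with
#' accessions in rows: first column the accession id, one column per
#' marker. Marker systems come either from a second header-like row whose
#' first field is `#system`, or from the `system` argument. `-`, empty,
#' `NA` cells become missing; `HET` marks heterogeneous calls. Unparseable
#' (non-character-representable) cells are treated as missing and counted
#' in a message.
#'
#' @param path file path.
#' @param system optional character vector (length 1 or one per marker)
#'   overriding / replacing the `#system` row.
#' @return a [marker_panel()].
#' @export
read_marker_table <- function(path, system = NULL) {
  sep <- detect_sep(path)
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "")
  if (nrow(raw) == 0L) stop("empty genotype table: ", path)
  sys_row <- raw[[1]] == "#system"
  if (is.null(system)) {
    if (!any(sys_row))
      stop("no `#system` row and no `system` argument given")
    system <- as.character(raw[which(sys_row)[1], -1])
  }
  raw <- raw[!sys_row, , drop = FALSE]
  ids <- raw[[1]]
  calls <- as.matrix(raw[, -1, drop = FALSE])
  rownames(calls) <- ids
  miss <- calls %in% MISSING_INPUT_TOKENS
  n_bad <- sum(miss & !(calls %in% c("-", "")))
  calls[miss] <- NA_character_
  if (n_bad > 0) message("read_marker_table: ", n_bad, " unparseable cells set to missing")
  marker_panel(calls, system)
}

#' Write a genotype table
#'
#' Inverse of [read_marker_table()]: tab-delimited, `#system` row second,
#' missing written as `-`.
#'
#' @param panel a `marker_panel`
#' @param path output file path
#' @export
write_marker_table <- function(panel, path) {
  calls <- panel$calls
  calls[is.na(calls)] <- "-"
  df <- data.frame(accession = rownames(calls), calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sys <- data.frame(accession = "#system", t(unname(panel$system)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(sys) <- names(df)
  out <- rbind(sys, df)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP calls from a VCF file
#'
#' Converts diploid GT fields into panel calls: homozygous genotypes map to
#' the corresponding REF/ALT allele string, heterozygous (phased or not) to
#' the heterogeneous state, missing to missing. Requires the `vcfR`
#' package.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @return a [marker_panel()] of SNP markers (accessions = VCF samples).
#' @export
read_vcf_markers <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_markers() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  alleles <- cbind(fix[, "REF"], fix[, "ALT"])
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  calls <- matrix(NA_character_, nrow = ncol(gt), ncol = nrow(gt),
                  dimnames = list(colnames(gt), ids))
  for (m in seq_len(nrow(gt))) {
    g <- gsub("\\|", "/", gt[m, ])
    a <- c("0/0" = alleles[m, 1], "1/1" = alleles[m, 2],
           "0/1" = HET_TOKEN, "1/0" = HET_TOKEN)
    calls[, m] <- unname(a[g])
  }
  marker_panel(calls, "SNP")
}

#' Read a long-format phenotype table
#'
#' Expects delimited text (tab or comma) with columns `accession`, `trait`,
#' `year`, `block`, `value`. Keys (accession, trait, year, block) must be
#' unique; `value` must parse as numeric (empty / NA allowed, flagged
#' missing).
#'
#' @param path file path
#' @return a data.frame of class `phenotype_table`
#' @export
read_phenotype_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  need <- c("accession", "trait", "year", "block", "value")
  if (nrow(df) == 0L) {
    warning("empty phenotype table: ", path)
    df <- data.frame(accession = character(), trait = character(),
                     year = character(), block = character(), value = numeric())
    class(df) <- c("phenotype_table", "data.frame")
    return(df)
  }
  if (!all(need %in% names(df)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  suppressWarnings(v <- as.numeric(df$value))
  bad <- which(is.na(v) & !(df$value %in% c("", "NA", "-")))
  if (length(bad))
    stop("non-numeric phenotype value(s) at row(s): ", paste(head(bad, 5), collapse = ", "))
  df$value <- v
  phenotype_table(df)
}

#' Validate / class a phenotype data.frame
#' @param df data.frame with columns accession, trait, year, block, value
#' @return same data.frame, classed `phenotype_table`
#' @export
phenotype_table <- function(df) {
  key <- paste(df$accession, df$trait, df$year, df$block, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (accession, trait, year, block) keys in phenotype table")
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a genetic map
#'
#' Delimited text with columns `marker`, `lg` (linkage group), `pos_cm`
#' (position in centimorgans, >= 0).
#'
#' @param path file path
#' @return data.frame with columns marker, lg, pos_cm
#' @export
read_genetic_map <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("marker", "lg", "pos_cm")
  if (!all(need %in% names(df)))
    stop("genetic map must have columns: ", paste(need, collapse = ", "))
  df$pos_cm <- as.numeric(df$pos_cm)
  if (any(!is.finite(df$pos_cm)) || any(df$pos_cm < 0))
    stop("map positions must be finite, non-negative cM")
  if (anyDuplicated(df$marker)) stop("duplicate markers in genetic map")
  df[need]
}
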