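#' Run the full synthetic-panel study end to end
#'
#' Orchestrates simulate -> diversity -> structure -> (adjust) -> impute ->
#' predict -> evaluate on a synthetic panel and writes every artifact to
#' `out_dir`. Stages can be toggled; every output file is checksummed in
#' the returned manifest.
#'
#' @param config a [panel_sim_config()]
#' @param out_dir output directory (created if absent)
#' @param methods prediction methods for the evaluation stage
#' @param n_reps evaluation repetitions (default 50)
#' @param with_adjustment also evaluate PLS/SPLS/LASSO on the
#'   structure-adjusted matrix (default TRUE)
#' @param mantel_perm permutations for the Mantel tests (default 199)
#' @param seed integer seed for the evaluation protocol
#' @param ... passed to [repeated_cv()]
#' @return manifest list: seeds, chosen parameters, per-stage summaries,
#'   output paths and md5 checksums
#' @export
run_pipeline <- function(config = panel_sim_config(), out_dir = tempfile("gspanel_run_"),
                         methods = c("lasso", "pls", "spls", "gblup",
                                     "bayesA", "bayesB"),
                         n_reps = 50, with_adjustment = TRUE,
                         mantel_perm = 199, seed = config$seed, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    paths[[name]] <<- path
    path
  }

  # simulate
  tp <- simulate_panel(config)
  ph <- simulate_phenotypes(tp)
  emit("genotypes.tsv", function(p) write_marker_table(tp$panel, p))
  emit("map.tsv", function(p) write.table(tp$map, p, sep = "\t",
                                          quote = FALSE, row.names = FALSE))
  emit("phenotypes.tsv", function(p) write.table(ph$phenotypes, p, sep = "\t",
                                                 quote = FALSE, row.names = FALSE))
  emit("truth.json", function(p)
    jsonlite::write_json(list(groups = as.list(tp$groups),
                              qtl = ph$truth$qtl, u = ph$truth$u,
                              realized_h2 = ph$truth$realized_h2),
                         p, digits = NA, auto_unbox = TRUE))

  # marker filtering + encoding
  filt <- filter_markers(tp$panel)
  snp_panel <- filt$panel[, filt$panel$system == "SNP"]
  num <- encode_numeric(snp_panel)

  # diversity
  stats <- marker_stats(tp$panel)
  emit("marker_stats.tsv", function(p) write.table(stats$per_marker, p,
                                                   sep = "\t", quote = FALSE,
                                                   row.names = FALSE))
  dists <- lapply(setNames(nm = c("SNP", "SSR", "RBIP")),
                  function(s) rogers_distance(tp$panel, s))
  for (s in names(dists))
    emit(paste0("rd_", s, ".tsv"), function(p) write_distance_matrix(dists[[s]], p))
  mant <- list(
    SNP_SSR = mantel_test(dists$SNP, dists$SSR, mantel_perm, seed),
    SNP_RBIP = mantel_test(dists$SNP, dists$RBIP, mantel_perm, seed),
    SSR_RBIP = mantel_test(dists$SSR, dists$RBIP, mantel_perm, seed))
  tree <- complete_linkage_tree(dists$SNP)
  emit("snp_tree.nwk", function(p) write_newick(tree, p))
  ld <- ld_decay(num, tp$map)
  emit("ld_pairs.tsv", function(p) write.table(ld, p, sep = "\t",
                                               quote = FALSE, row.names = FALSE))

  # impute, structure, adjust
  imp <- ppca_impute(num$X, seed = seed)
  dapc <- dapc_fit(imp$X, seed = seed)
  emit("dapc_assignment.tsv", function(p) write_assignment(dapc, p))
  emit("dapc_bic.tsv", function(p) write.table(dapc$bic, p, sep = "\t",
                                               quote = FALSE, row.names = FALSE))
  adm <- admixed_fraction(dapc, 0.2)

  # evaluate
  y <- ph$means[rownames(imp$X)]
  cv_raw <- repeated_cv(imp$X, y, methods = methods, n_reps = n_reps,
                        seed = seed, ...)
  emit("cv_raw.tsv", function(p) write.table(cv_raw$summary, p, sep = "\t",
                                             quote = FALSE, row.names = FALSE))
  cv_adj <- NULL
  if (with_adjustment && dapc$k >= 2) {
    cv_adj <- repeated_cv(imp$X, y,
                          methods = intersect(methods, c("lasso", "pls", "spls")),
                          n_reps = n_reps, groups = dapc$groups, seed = seed, ...)
    emit("cv_adjusted.tsv", function(p) write.table(cv_adj$summary, p,
                                                    sep = "\t", quote = FALSE,
                                                    row.names = FALSE))
  }

  manifest <- list(
    seed = seed, config = unclass(config),
    n_markers_retained = ncol(filt$panel$calls),
    n_markers_excluded = nrow(filt$report),
    realized_h2 = ph$truth$realized_h2,
    mantel = lapply(mant, function(m) m[c("r", "p_value")]),
    dapc_k = dapc$k, admixed_fraction = adm,
    imputation = list(n_imputed = imp$n_imputed, converged = imp$converged),
    cv = cv_raw$summary, cv_adjusted = if (!is.null(cv_adj)) cv_adj$summary,
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, digits = NA, auto_unbox = TRUE,
                         dataframe = "rows", force = TRUE))
  manifest$out_dir <- out_dir
  invisible(manifest)
}
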