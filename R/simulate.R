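#' Configuration for the synthetic diversity panel generator
#'
#' Defaults emulate a diversity panel of a highly selfing crop genotyped
#' with three marker systems: ~372 accessions in a few differentiated
#' groups, 351 biallelic SNPs, 29 multi-allelic SSRs and 31 biallelic
#' RBIPs with a low-MAF-skewed frequency spectrum, markers mapped on 7
#' linkage groups of 100 cM, and about 1% residual heterogeneous calls.
#'
#' @param n_accessions total panel size (default 372)
#' @param group_sizes sizes of the latent subpopulations; must sum to
#'   `n_accessions` (default: 3 near-equal groups)
#' @param fst differentiation between groups under the Balding-Nichols
#'   model (default 0.15)
#' @param selfing_het_rate per-call probability of a heterogeneous call
#'   (default 0.01)
#' @param n_snp,n_ssr,n_rbip marker counts per system (defaults 351/29/31)
#' @param ssr_alleles range of allele counts per SSR (default 4:12)
#' @param map_lgs number of linkage groups (default 7)
#' @param lg_length_cm length of each linkage group in cM (default 100)
#' @param n_founder founder lines per group; 2*n_founder haplotypes are
#'   recombined along the map to induce within-group LD (default 30)
#' @param missing_rate per-call missing probability (default 0.01)
#' @param n_qtl number of trait QTL drawn among the SNP markers (default 50)
#' @param h2_target broad-sense heritability of the simulated trait on an
#'   accession-mean basis (default 0.9)
#' @param group_effect_sd SD of the per-group trait shift confounding
#'   structure with the polygenic signal, in trait units of genetic SD
#'   (default 0: no confounding)
#' @param n_blocks field blocks per trial (default 2)
#' @param seed integer seed for the generator
#' @return a list of class `panel_sim_config`
#' @export
panel_sim_config <- function(n_accessions = 372,
                             group_sizes = NULL,
                             fst = 0.15,
                             selfing_het_rate = 0.01,
                             n_snp = 351, n_ssr = 29, n_rbip = 31,
                             ssr_alleles = 4:12,
                             map_lgs = 7, lg_length_cm = 100,
                             n_founder = 30,
                             missing_rate = 0.01,
                             n_qtl = 50, h2_target = 0.9,
                             group_effect_sd = 0,
                             n_blocks = 2,
                             seed = 1L) {
  if (is.null(group_sizes)) {
    k <- 3L
    group_sizes <- rep(n_accessions %/% k, k)
    group_sizes[1] <- group_sizes[1] + n_accessions - sum(group_sizes)
  }
  if (sum(group_sizes) != n_accessions)
    stop("group_sizes must sum to n_accessions")
  if (length(group_sizes) > n_accessions)
    stop("more groups than accessions")
  stopifnot(fst > 0, fst < 1, selfing_het_rate >= 0, selfing_het_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            h2_target >= 0, h2_target <= 1, n_blocks >= 1)
  structure(as.list(environment()), class = "panel_sim_config")
}

# group-specific allele frequency under the Balding-Nichols model
bn_freq <- function(p, fst, n) {
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(n, a, b)
}

#' Simulate a structured selfing diversity panel
#'
#' Draws ancestral biallelic frequencies (Uniform(0.05, 0.95) for SNPs,
#' Beta(0.4, 1.2) for RBIPs to skew their spectrum towards low MAF),
#' differentiates them into groups with the Balding-Nichols Beta model,
#' recombines 2*n_founder founder haplotypes per group along the genetic
#' map (Haldane mapping function) to induce within-group LD, and derives
#' inbred-line genotypes with a residual heterogeneous-call rate. SSR
#' alleles are drawn from group-specific Dirichlet-perturbed frequency
#' vectors. All markers are placed uniformly at random on the map.
#'
#' @param config a [panel_sim_config()]
#' @return list of class `true_panel`: `panel` ([marker_panel()]), `map`
#'   (genetic map data.frame), `groups` (named integer vector of true
#'   group labels), `group_freq` (list of per-group biallelic allele-1
#'   frequencies), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  K <- length(config$group_sizes)
  n <- config$n_accessions
  acc_ids <- sprintf("ACC%03d", seq_len(n))
  groups <- rep(seq_len(K), config$group_sizes)
  names(groups) <- acc_ids

  n_bi <- config$n_snp + config$n_rbip
  marker_ids <- c(sprintf("SNP%03d", seq_len(config$n_snp)),
                  sprintf("SSR%02d", seq_len(config$n_ssr)),
                  sprintf("RBIP%02d", seq_len(config$n_rbip)))
  systems <- c(rep("SNP", config$n_snp), rep("SSR", config$n_ssr),
               rep("RBIP", config$n_rbip))

  # map: all markers uniform over lgs x [0, L]
  p_all <- length(marker_ids)
  map <- data.frame(marker = marker_ids,
                    lg = paste0("LG", sample.int(config$map_lgs, p_all, replace = TRUE)),
                    pos_cm = round(runif(p_all, 0, config$lg_length_cm), 2),
                    stringsAsFactors = FALSE)

  # ancestral + group frequencies for biallelic markers (allele "A" = allele 1)
  p_anc <- c(runif(config$n_snp, 0.05, 0.95),
             pmin(pmax(rbeta(config$n_rbip, 0.4, 1.2), 0.02), 0.98))
  group_freq <- lapply(seq_len(K), function(g) bn_freq(p_anc, config$fst, n_bi))

  bi_ids <- marker_ids[systems != "SSR"]
  bi_map <- map[match(bi_ids, map$marker), ]
  # order biallelic markers along the map for recombination
  ord <- order(bi_map$lg, bi_map$pos_cm)
  # Haldane recombination fraction between adjacent ordered markers
  d <- diff(bi_map$pos_cm[ord])
  new_lg <- bi_map$lg[ord][-1] != bi_map$lg[ord][-length(ord)]
  rec <- 0.5 * (1 - exp(-2 * d / 100))
  rec[new_lg] <- 0.5

  # base (ancestral) allele-frequency vectors for the SSRs
  ssr_cols <- which(systems == "SSR")
  ssr_base <- lapply(ssr_cols, function(s) {
    n_all <- if (length(config$ssr_alleles) == 1) config$ssr_alleles
             else sample(config$ssr_alleles, 1)
    w <- rgamma(n_all, 1)
    w / sum(w)
  })

  calls <- matrix(NA_character_, n, p_all, dimnames = list(acc_ids, marker_ids))
  n_hap <- 2L * config$n_founder
  for (g in seq_len(K)) {
    idx <- which(groups == g)
    pf <- group_freq[[g]][ord]   # group_freq rows follow bi_ids order
    # founder haplotypes: 1 = allele A, 0 = allele B, independent per marker
    H <- matrix(rbinom(n_hap * length(pf), 1, rep(pf, each = n_hap)),
                nrow = n_hap)
    for (i in idx) {
      pair <- sample.int(n_hap, 2)
      # gamete: recombine the two founder haplotypes along the map
      sw <- c(rbinom(1, 1, 0.5), rbinom(length(rec), 1, rec))
      cur <- cumsum(sw) %% 2
      gam <- ifelse(cur == 0, H[pair[1], ], H[pair[2], ])
      a <- ifelse(gam == 1, "A", "B")
      # undo the map ordering
      a_unord <- character(length(a)); a_unord[ord] <- a
      calls[i, match(bi_ids, marker_ids)] <- a_unord
    }
    # SSR: group-specific Dirichlet-perturbed allele frequencies
    for (k in seq_along(ssr_cols)) {
      base <- ssr_base[[k]]
      w <- rgamma(length(base), base * (1 - config$fst) / config$fst)
      w <- w / sum(w)
      calls[idx, ssr_cols[k]] <- paste0("a", sample.int(length(w), length(idx),
                                                        replace = TRUE, prob = w))
    }
  }

  # residual heterogeneity and missingness
  if (config$selfing_het_rate > 0) {
    het <- matrix(runif(n * p_all) < config$selfing_het_rate, n, p_all)
    calls[het] <- HET_TOKEN
  }
  if (config$missing_rate > 0) {
    mis <- matrix(runif(n * p_all) < config$missing_rate, n, p_all)
    calls[mis] <- NA_character_
  }

  structure(list(panel = marker_panel(calls, systems), map = map,
                 groups = groups, group_freq = group_freq, config = config),
            class = "true_panel")
}

#' @method print true_panel
#' @export
print.true_panel <- function(x, ...) {
  cat("true_panel:", x$config$n_accessions, "accessions,",
      length(x$config$group_sizes), "groups (fst =", x$config$fst, ")\n")
  print(x$panel)
  invisible(x)
}

#' Simulate an additive quantitative trait for a panel
#'
#' Draws `n_qtl` QTL among the panel's SNP markers with Normal(0, 1)
#' effects, computes genetic values from minor-allele dosages (missing
#' dosages replaced by the marker mean for the purpose of the truth), adds
#' a shared per-group shift (structure confounding) and block-replicated
#' phenotypic records. The within-block error variance is set so that the
#' accession-mean heritability Var(g) / (Var(g) + Var(e_mean)) equals
#' `h2_target`.
#'
#' @param true_panel a `true_panel` from [simulate_panel()]
#' @param trait trait name for the phenotype table (default "TSWsim")
#' @param year trial label (default "Y1")
#' @param seed optional seed; defaults to `config$seed + 1`
#' @return list: `phenotypes` (a `phenotype_table` with one row per
#'   accession x block), `truth` (qtl ids, effects `u`, genetic values `g`,
#'   group shifts, realized h2), and `means` (accession means).
#' @export
simulate_phenotypes <- function(true_panel, trait = "TSWsim", year = "Y1",
                                seed = NULL) {
  config <- true_panel$config
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  snp_idx <- which(true_panel$panel$system == "SNP")
  num <- encode_numeric(true_panel$panel[, snp_idx])
  X <- num$X
  if (config$n_qtl > ncol(X)) stop("n_qtl exceeds number of SNP markers")
  # mean-impute missing dosages for the generative truth
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (anyNA(xj)) X[is.na(xj), j] <- mean(xj, na.rm = TRUE)
  }
  qtl <- sort(sample.int(ncol(X), config$n_qtl))
  u <- rnorm(config$n_qtl)
  g <- drop(X[, qtl, drop = FALSE] %*% u)
  sd_scale <- sd(g)                      # trait unit for group/block effects
  if (config$h2_target == 0) g[] <- 0    # null trait: no genetic contribution
  var_g <- var(g)
  group_shift <- rnorm(length(unique(true_panel$groups)), 0,
                       config$group_effect_sd * sd_scale)
  shift <- setNames(group_shift[true_panel$groups], names(true_panel$groups))

  # Var of the accession-mean error fixed by the target heritability
  var_e_mean <- if (config$h2_target >= 1) 0
                else if (config$h2_target == 0) sd_scale^2
                else var_g * (1 - config$h2_target) / config$h2_target
  sd_within <- sqrt(var_e_mean * config$n_blocks)
  block_eff <- rnorm(config$n_blocks, 0, 0.25 * sd_scale)

  n <- nrow(X)
  rows <- expand.grid(accession = rownames(X), block = seq_len(config$n_blocks),
                      stringsAsFactors = FALSE)
  eps <- rnorm(nrow(rows), 0, sd_within)
  value <- g[rows$accession] + shift[rows$accession] +
    block_eff[rows$block] + eps
  ph <- phenotype_table(data.frame(accession = rows$accession, trait = trait,
                                   year = year, block = paste0("B", rows$block),
                                   value = value, stringsAsFactors = FALSE))
  mn <- tapply(value, rows$accession, mean)[rownames(X)]
  e_mean <- mn - g - shift[rownames(X)] - mean(block_eff)
  realized_h2 <- var_g / (var_g + var(e_mean))
  list(phenotypes = ph,
       truth = list(qtl = colnames(X)[qtl], u = u, g = setNames(g, rownames(X)),
                    group_shift = group_shift, realized_h2 = realized_h2),
       means = mn)
}
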