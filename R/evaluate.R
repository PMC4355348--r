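#' Random train/test split
#'
#' Draws a training set of round(`train_fraction` * n) accessions (round
#' half away from zero) without replacement; the rest form the test set.
#'
#' @param n number of accessions (>= 3)
#' @param train_fraction training fraction (default 2/3)
#' @param seed integer seed
#' @return list with integer vectors `train` and `test`
#' @export
split_train_test <- function(n, train_fraction = 2 / 3, seed = 1L) {
  stopifnot(n >= 3)
  n_train <- floor(train_fraction * n + 0.5)
  set.seed(seed)
  tr <- sort(sample.int(n, n_train))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Prediction-quality metrics
#'
#' MSEP = mean squared error on the test set; R2 = 1 - RSS/TSS on the
#' training set (TSS about the training mean); Q2 = 1 - PRESS/TSS_test on
#' the test set (TSS about the test mean) — negative when the model
#' predicts worse than the test mean.
#'
#' @param y_train,yhat_train observed and fitted training phenotypes
#' @param y_test,yhat_test observed and predicted test phenotypes
#' @return list with `msep`, `r2`, `q2` (`q2` is `NA` with a warning when
#'   the test phenotypes have zero variance)
#' @export
prediction_metrics <- function(y_train, yhat_train, y_test, yhat_test) {
  stopifnot(length(y_train) == length(yhat_train),
            length(y_test) == length(yhat_test))
  msep <- mean((y_test - yhat_test)^2)
  r2 <- 1 - sum((y_train - yhat_train)^2) /
    sum((y_train - mean(y_train))^2)
  tss_test <- sum((y_test - mean(y_test))^2)
  if (tss_test == 0) {
    warning("zero test variance: Q2 undefined")
    q2 <- NA_real_
  } else {
    q2 <- 1 - sum((y_test - yhat_test)^2) / tss_test
  }
  list(msep = msep, r2 = r2, q2 = q2)
}

#' Repeated train/test evaluation of prediction methods
#'
#' Implements the repeated hold-out protocol: in every repetition the
#' panel is split 2/3 train : 1/3 test at random without replacement;
#' every requested method is tuned and fitted on the training set (the
#' LASSO bound and PLS/SPLS component count by internal 10-fold CV on the
#' training data only) and evaluated on both sets; MSEP, R2 and Q2 are
#' averaged over repetitions, with sample SDs (n - 1 denominator).
#'
#' When `groups` are given, the genotype matrix is first adjusted for
#' structure with [combat_adjust()] (a phenotype-free operation, so it
#' leaks no trait information into the test sets), and models are trained
#' and tested on the adjusted matrix.
#'
#' @param X complete numeric dosage matrix
#' @param y phenotype vector (accession means)
#' @param methods character vector of [gp_fit()] methods
#' @param n_reps number of repetitions (default 500)
#' @param groups optional structure labels; triggers ComBat adjustment
#' @param train_fraction training fraction (default 2/3)
#' @param seed integer seed; repetition r uses seed + r
#' @param adjustment_label label stored in the result rows (default
#'   "none" or "adjusted")
#' @param ... passed to [gp_fit()] (e.g. `bayes`, `vars_per_component`)
#' @return object of class `cv_result`: `summary` (one row per method:
#'   mean and sd of MSEP/R2/Q2, reps used, failures), `per_rep` (long
#'   data.frame of per-repetition metrics)
#' @export
repeated_cv <- function(X, y, methods = c("lasso", "pls", "spls", "gblup",
                                          "bayesA", "bayesB"),
                        n_reps = 500, groups = NULL, train_fraction = 2 / 3,
                        seed = 1L, adjustment_label = NULL, ...) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (is.null(adjustment_label))
    adjustment_label <- if (is.null(groups)) "none" else "adjusted"
  if (!is.null(groups)) X <- combat_adjust(X, groups)$adjusted
  n <- nrow(X)
  rows <- vector("list", n_reps * length(methods))
  k <- 0L
  for (r in seq_len(n_reps)) {
    sp <- split_train_test(n, train_fraction, seed = seed + r)
    Xtr <- X[sp$train, , drop = FALSE]; ytr <- y[sp$train]
    Xte <- X[sp$test, , drop = FALSE]; yte <- y[sp$test]
    for (m in methods) {
      k <- k + 1L
      res <- tryCatch({
        fit <- gp_fit(Xtr, ytr, method = m, seed = seed + r, ...)
        mt <- prediction_metrics(ytr, fit$fitted, yte, predict(fit, Xte))
        data.frame(rep = r, method = m, adjustment = adjustment_label,
                   n_train = length(sp$train), n_test = length(sp$test),
                   msep = mt$msep, r2 = mt$r2, q2 = mt$q2, ok = TRUE,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(rep = r, method = m, adjustment = adjustment_label,
                   n_train = length(sp$train), n_test = length(sp$test),
                   msep = NA_real_, r2 = NA_real_, q2 = NA_real_, ok = FALSE,
                   stringsAsFactors = FALSE)
      })
      rows[[k]] <- res
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(unique(per_rep$method), function(m) {
    d <- per_rep[per_rep$method == m & per_rep$ok, ]
    data.frame(method = m, adjustment = adjustment_label,
               n_reps_used = nrow(d),
               n_failed = sum(per_rep$method == m & !per_rep$ok),
               msep_mean = mean(d$msep), msep_sd = sd(d$msep),
               r2_mean = mean(d$r2), r2_sd = sd(d$r2),
               q2_mean = mean(d$q2), q2_sd = sd(d$q2),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ, per_rep = per_rep), class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, digits = 2, ...) {
  s <- x$summary
  fmt <- function(m, sdv, d) sprintf("%.*f (%.*f)", d, m, d, sdv)
  cat("repeated_cv over", max(x$per_rep$rep), "repetitions (",
      unique(s$adjustment), ")\n")
  out <- data.frame(method = s$method,
                    MSEP = fmt(s$msep_mean, s$msep_sd, digits),
                    R2 = fmt(s$r2_mean, s$r2_sd, 2),
                    Q2 = fmt(s$q2_mean, s$q2_sd, 2),
                    reps = s$n_reps_used)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Broad-sense heritability from the genotype ANOVA F
#' @param F_genotype F statistic of the genotype effect
#' @return h2 = 1 - 1/F
#' @export
h2_from_f <- function(F_genotype) 1 - 1 / F_genotype

#' Two-way ANOVA of a trait and broad-sense heritability
#'
#' Fixed-effects two-way ANOVA (genotype + block, no interaction) of one
#' trait in one trial; broad-sense heritability on an accession-mean basis
#' is 1 - 1/F with F the genotype F statistic.
#'
#' @param phenotypes a `phenotype_table`
#' @param trait trait name
#' @param year trial/year label
#' @return list: `F_genotype`, `F_block`, `p_genotype`, `p_block`, `h2`,
#'   `means` (per-accession means, for downstream prediction)
#' @export
heritability_from_anova <- function(phenotypes, trait, year) {
  d <- phenotypes[phenotypes$trait == trait & phenotypes$year == year &
                    !is.na(phenotypes$value), , drop = FALSE]
  if (length(unique(d$accession)) < 2 || length(unique(d$block)) < 2)
    stop("need >= 2 genotypes and >= 2 blocks with data")
  tab <- table(d$accession, d$block)
  if (any(rowSums(tab > 0) == 0))
    stop("accessions with no data in any block")
  fit <- lm(value ~ factor(accession) + factor(block), data = d)
  an <- anova(fit)
  Fg <- an$`F value`[1]; Fb <- an$`F value`[2]
  list(F_genotype = Fg, F_block = Fb,
       p_genotype = an$`Pr(>F)`[1], p_block = an$`Pr(>F)`[2],
       h2 = h2_from_f(Fg),
       means = tapply(d$value, d$accession, mean))
}

#' Stability of marker-effect vectors between two fitted models
#'
#' Squared Pearson correlation of the per-marker effect vectors of two
#' models fitted on the same marker set (e.g. the same trait in two
#' years), plus the top-ranked markers shared by both.
#'
#' @param model_a,model_b `gp_model` objects over the same markers
#' @param top_k how many top markers (by |effect|) to intersect
#'   (default 20)
#' @return list: `r2`, `top_shared` (marker ids in both models' top_k)
#' @export
coefficient_stability <- function(model_a, model_b, top_k = 20) {
  if (!identical(names(model_a$beta), names(model_b$beta)))
    stop("models were fitted on different marker sets")
  ba <- model_a$beta; bb <- model_b$beta
  if (sd(ba) == 0 || sd(bb) == 0) {
    warning("zero-variance effect vector: stability undefined")
    return(list(r2 = NA_real_, top_shared = character()))
  }
  ta <- names(sort(abs(ba), decreasing = TRUE))[seq_len(min(top_k, length(ba)))]
  tb <- names(sort(abs(bb), decreasing = TRUE))[seq_len(min(top_k, length(bb)))]
  list(r2 = cor(ba, bb)^2, top_shared = intersect(ta, tb))
}
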