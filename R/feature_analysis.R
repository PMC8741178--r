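# Feature-level analysis: univariate ANOVA F ranking, staged
# feature-addition curves, impurity importances, and class-conditional
# kernel density estimates.

#' Rank features by one-way ANOVA F statistic
#'
#' For each feature, computes the two-group one-way ANOVA F statistic
#' (between-group mean square over within-group mean square; for two
#' groups this equals the squared pooled-variance two-sample t statistic)
#' and ranks features by descending F. A feature with zero between- and
#' within-group variance gets F = 0; ties are broken lexicographically by
#' feature name. The statistic is computed from its definition so that
#' the ranking is an explicit, inspectable part of the pipeline.
#'
#' @param features feature table (ideally min-max scaled; F is invariant
#'   to positive affine rescaling in any case).
#' @param labels logical vector, `TRUE` = in-corona; each class needs at
#'   least 2 members.
#' @return A `data.frame` with columns `rank`, `feature`, `F`.
#' @export
anova_rank <- function(features, labels) {
  x <- feature_matrix(features)
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("each class needs at least 2 members")
  n <- length(labels)
  f_stat <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    grand <- mean(v)
    m1 <- mean(v[labels])
    m0 <- mean(v[!labels])
    ssb <- sum(labels) * (m1 - grand)^2 + sum(!labels) * (m0 - grand)^2
    ssw <- sum((v[labels] - m1)^2) + sum((v[!labels] - m0)^2)
    msb <- ssb / 1
    msw <- ssw / (n - 2)
    if (msw == 0) {
      if (msb == 0) {
        message("feature '", colnames(x)[j],
                "' is constant within and between classes; F set to 0")
        return(0)
      }
      return(Inf)
    }
    msb / msw
  }, numeric(1))
  ord <- order(-f_stat, colnames(x))
  data.frame(rank = seq_len(ncol(x)), feature = colnames(x)[ord],
             F = f_stat[ord], stringsAsFactors = FALSE)
}

#' Staged feature-addition performance curve
#'
#' Unmasks features one by one from highest to lowest ANOVA rank and
#' revalidates the classifier on each prefix, producing the performance
#' versus feature-count curve. With a shared seed, the row at `n = m`
#' (all features) reproduces a plain [validate] run exactly.
#'
#' @inheritParams validate
#' @param ranking a [anova_rank] table covering all feature columns.
#' @param n_values which prefix sizes to evaluate; default `1:m`.
#' @return A `data.frame` with one row per prefix size: `n_features` plus
#'   mean and 95% CI columns for each metric. The underlying
#'   `validation_result`s are attached as attribute `"results"`.
#' @export
staged_feature_curve <- function(features, labels, ranking,
                                 n_values = NULL, n_splits = 100,
                                 test_fraction = 0.1,
                                 cfg = classifier_config(),
                                 smote_cfg = smote_config(),
                                 seed = NULL) {
  x <- feature_matrix(features)
  if (!setequal(ranking$feature, colnames(x)))
    stop("ranking must cover exactly the feature columns")
  m <- ncol(x)
  if (is.null(n_values)) n_values <- seq_len(m)
  results <- vector("list", length(n_values))
  rows <- vector("list", length(n_values))
  for (i in seq_along(n_values)) {
    n <- n_values[[i]]
    keep <- ranking$feature[seq_len(n)]
    v <- validate(x[, keep, drop = FALSE], labels, n_splits = n_splits,
                  test_fraction = test_fraction, cfg = cfg,
                  smote_cfg = smote_cfg, seed = seed)
    results[[i]] <- v
    s <- v$summary
    row <- c(n_features = n)
    for (j in seq_len(nrow(s))) {
      row[paste0(s$metric[j], "_mean")] <- s$mean[j]
      row[paste0(s$metric[j], "_ci_lower")] <- s$ci_lower[j]
      row[paste0(s$metric[j], "_ci_upper")] <- s$ci_upper[j]
    }
    rows[[i]] <- row
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "results") <- results
  out
}

#' Impurity-based feature importances
#'
#' Mean-impurity-decrease importance of each feature in a trained model,
#' normalized to sum to 1. Features never selected by any tree score 0.
#'
#' @param model a [train]ed `corona_model`.
#' @return A `data.frame` with columns `feature` and `importance`,
#'   sorted by decreasing importance.
#' @export
impurity_importances <- function(model) {
  if (!inherits(model, "corona_model"))
    stop("model must be a trained corona_model")
  imp <- model$forest$variable.importance
  total <- sum(imp)
  if (total > 0) imp <- imp / total
  out <- data.frame(feature = names(imp), importance = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance, out$feature), , drop = FALSE]
}

#' Class-conditional kernel density estimates of a feature
#'
#' Gaussian kernel density of a (min-max scaled) feature within each
#' class, evaluated on a uniform grid over `[0, 1]` and renormalized to
#' integrate to 1 (trapezoid rule) so that boundary mass is not lost.
#' Bandwidth defaults to the variance-based rule of thumb
#' (`stats::bw.nrd0`).
#'
#' @param values numeric feature values in `[0, 1]`.
#' @param labels logical vector, `TRUE` = in-corona.
#' @param bandwidth optional numeric bandwidth override.
#' @param grid_n number of grid points; default 256.
#' @return A `data.frame` with columns `x`, `in_corona`, `out_corona`.
#' @export
class_kde <- function(values, labels, bandwidth = NULL, grid_n = 256) {
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("each class needs at least 2 points for a density estimate")
  one <- function(v) {
    bw <- if (is.null(bandwidth)) stats::bw.nrd0(v) else bandwidth
    if (bw <= 0) bw <- 1e-3
    d <- stats::density(v, bw = bw, from = 0, to = 1, n = grid_n)
    area <- sum(diff(d$x) * (d$y[-1] + d$y[-grid_n]) / 2)
    d$y / area
  }
  x <- seq(0, 1, length.out = grid_n)
  data.frame(x = x, in_corona = one(values[labels]),
             out_corona = one(values[!labels]))
}
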