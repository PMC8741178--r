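# Imbalance-corrected ensemble-tree classification: SMOTE minority
# synthesis, random-forest training (ranger backend), stratified
# shuffle-split validation with percentile confidence intervals,
# cross-biofluid transfer, hyperparameter grid search, and probability
# prediction. The positive class is "in-corona" throughout.

#' SMOTE configuration
#'
#' @param ratio target minority/majority ratio after augmentation,
#'   in (0, 1]; default 0.7.
#' @param k_neighbors number of minority-class nearest neighbors to
#'   interpolate towards; default 12.
#' @param seed optional integer seed.
#' @return A list of class `smote_config`.
#' @export
smote_config <- function(ratio = 0.7, k_neighbors = 12, seed = NULL) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio > 1)
    stop("ratio must lie in (0, 1]")
  if (!is.numeric(k_neighbors) || k_neighbors < 1)
    stop("k_neighbors must be >= 1")
  structure(list(ratio = ratio, k_neighbors = as.integer(k_neighbors),
                 seed = seed), class = "smote_config")
}

#' Classifier configuration
#'
#' Configuration of the ensemble-tree classifier. The backend is a
#' `ranger` random forest; classification splits use the Gini impurity
#' (the only impurity criterion the R random-forest implementations
#' offer; entropy-based splitting gives practically indistinguishable
#' forests).
#'
#' @param n_trees number of trees; default 700.
#' @param split_criterion split impurity criterion; only `"gini"` is
#'   supported.
#' @param max_depth optional maximal tree depth (`NULL` = unlimited).
#' @param seed optional integer seed.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(n_trees = 700, split_criterion = "gini",
                              max_depth = NULL, seed = NULL) {
  if (!is.numeric(n_trees) || n_trees < 1)
    stop("n_trees must be >= 1")
  if (!identical(split_criterion, "gini"))
    stop("split_criterion '", split_criterion, "' is not supported: the ",
         "ranger backend implements only the Gini impurity criterion")
  structure(list(n_trees = as.integer(n_trees),
                 split_criterion = split_criterion,
                 max_depth = if (is.null(max_depth)) NULL
                             else as.integer(max_depth),
                 seed = seed), class = "classifier_config")
}

#' Synthesize minority-class samples (SMOTE)
#'
#' Generates `max(0, ceiling(ratio * n_majority) - n_minority)` synthetic
#' samples. Each synthetic point is `x_i + u * (x_j - x_i)` where `x_i`
#' is a random minority point, `x_j` one of its `k_neighbors` nearest
#' minority neighbors (Euclidean distance; features are expected to be
#' min-max scaled), and `u ~ Uniform(0, 1)`. Deterministic given a seed.
#'
#' @param minority numeric matrix of minority-class feature rows.
#' @param n_majority majority-class size.
#' @param cfg a [smote_config].
#' @return Numeric matrix of synthetic rows (possibly 0 rows), same
#'   columns as `minority`.
#' @export
smote <- function(minority, n_majority, cfg = smote_config()) {
  minority <- as.matrix(minority)
  n_min <- nrow(minority)
  if (n_min <= cfg$k_neighbors)
    stop("minority class size (", n_min, ") must exceed k_neighbors (",
         cfg$k_neighbors, "); use a smaller k")
  n_synth <- max(0L, ceiling(cfg$ratio * n_majority) - n_min)
  if (n_synth == 0L)
    return(minority[integer(0), , drop = FALSE])
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  d <- as.matrix(stats::dist(minority))
  diag(d) <- Inf
  # k nearest minority neighbors of each minority point
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(cfg$k_neighbors)]))
  base <- sample.int(n_min, n_synth, replace = TRUE)
  pick <- sample.int(cfg$k_neighbors, n_synth, replace = TRUE)
  nbr <- nn[cbind(base, pick)]
  u <- stats::runif(n_synth)
  minority[base, , drop = FALSE] +
    u * (minority[nbr, , drop = FALSE] - minority[base, , drop = FALSE])
}

# Fit the forest on an already-scaled feature matrix. Seeds: an explicit
# cfg seed wins; otherwise a seed is drawn from the current RNG stream so
# callers control determinism with a single set.seed().
fit_forest <- function(x_scaled, labels, cfg) {
  if (ncol(x_scaled) == 0L) stop("empty feature set")
  y <- factor(ifelse(labels, "in", "out"), levels = c("out", "in"))
  seed <- if (!is.null(cfg$seed)) cfg$seed
          else sample.int(.Machine$integer.max, 1)
  ranger::ranger(x = as.data.frame(x_scaled), y = y,
                 num.trees = cfg$n_trees, probability = TRUE,
                 splitrule = "gini", importance = "impurity",
                 max.depth = if (is.null(cfg$max_depth)) NULL
                             else cfg$max_depth,
                 seed = seed, num.threads = 1)
}

#' Train the corona classifier
#'
#' Scales the features to `[0, 1]` (fitting the scaler on the supplied
#' table unless a prefitted one is passed), augments the minority class
#' with SMOTE in scaled space, and fits the random forest. The returned
#' model carries the scaler and feature registry so that prediction on
#' raw feature tables is self-contained.
#'
#' @param features feature table (matrix or data frame; an `accession` /
#'   `exposure_source` column is ignored).
#' @param labels logical vector, `TRUE` = in-corona.
#' @param cfg a [classifier_config].
#' @param smote_cfg a [smote_config], or `NULL` to skip augmentation.
#' @param scaler optional prefitted [minmax_fit].
#' @return An object of class `corona_model`.
#' @export
train <- function(features, labels, cfg = classifier_config(),
                  smote_cfg = smote_config(), scaler = NULL) {
  x <- feature_matrix(features)
  labels <- as.logical(labels)
  if (nrow(x) != length(labels))
    stop("features and labels disagree in length")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train")
  if (is.null(scaler)) scaler <- minmax_fit(x)
  xs <- minmax_apply(scaler, x)
  if (!is.null(smote_cfg)) {
    aug <- augment_minority(xs, labels, smote_cfg)
    xs <- aug$x
    labels <- aug$labels
  }
  forest <- fit_forest(xs, labels, cfg)
  structure(list(forest = forest, features = colnames(xs),
                 scaler = scaler, classifier_cfg = cfg,
                 smote_cfg = smote_cfg, n_train = nrow(xs),
                 version = as.character(utils::packageVersion("coronaRF"))),
            class = "corona_model")
}

# SMOTE the minority class of a scaled matrix; returns augmented x/labels.
augment_minority <- function(xs, labels, smote_cfg) {
  n_in <- sum(labels)
  n_out <- sum(!labels)
  minority_is_in <- n_in <= n_out
  minority <- xs[labels == minority_is_in, , drop = FALSE]
  synth <- smote(minority, max(n_in, n_out), smote_cfg)
  if (nrow(synth) > 0L) {
    xs <- rbind(xs, synth)
    labels <- c(labels, rep(minority_is_in, nrow(synth)))
  }
  list(x = xs, labels = labels)
}

#' @export
print.corona_model <- function(x, ...) {
  cat("Corona random-forest classifier\n")
  cat(sprintf("  trees: %d | features: %d | training rows: %d\n",
              x$classifier_cfg$n_trees, length(x$features), x$n_train))
  invisible(x)
}

#' Predict in-corona probabilities
#'
#' The probability is the fraction of trees voting in-corona; a protein
#' is called in the corona iff its probability is at least 0.5
#' (inclusive cutoff).
#'
#' @param model a [train]ed `corona_model`.
#' @param features feature table whose feature names match the training
#'   registry exactly.
#' @return A `data.frame` with columns `accession` (if present in
#'   `features`), `probability`, `in_corona`.
#' @export
predict_corona <- function(model, features) {
  accession <- if (is.data.frame(features) && "accession" %in% names(features))
    features$accession else NULL
  x <- feature_matrix(features)
  missing <- setdiff(model$features, colnames(x))
  extra <- setdiff(colnames(x), model$features)
  if (length(missing) || length(extra))
    stop("feature names do not match the trained model",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  xs <- minmax_apply(model$scaler, x[, model$features, drop = FALSE])
  prob <- stats::predict(model$forest,
                         data = as.data.frame(xs),
                         num.threads = 1)$predictions[, "in"]
  out <- data.frame(probability = as.numeric(prob),
                    in_corona = as.numeric(prob) >= 0.5)
  if (!is.null(accession)) out <- cbind(accession = accession, out,
                                        stringsAsFactors = FALSE)
  out
}

# Rank-statistic AUC (Mann-Whitney); NA when either class is absent.
rank_auc <- function(prob, truth) {
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

split_metrics <- function(prob, truth) {
  pred <- prob >= 0.5
  tp <- sum(pred & truth)
  c(accuracy = mean(pred == truth),
    auc = rank_auc(prob, truth),
    precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_,
    recall = if (sum(truth) > 0) tp / sum(truth) else NA_real_)
}

# Stratified sample of test indices: per class, max(1, round(frac * n)).
stratified_test_idx <- function(labels, fraction) {
  idx <- integer(0)
  for (cls in c(TRUE, FALSE)) {
    members <- which(labels == cls)
    n_take <- max(1L, round(fraction * length(members)))
    n_take <- min(n_take, length(members))
    idx <- c(idx, sample(members, n_take))
  }
  sort(idx)
}

make_validation_result <- function(splits, n_splits, test_fraction) {
  metrics <- c("accuracy", "auc", "precision", "recall")
  summary <- do.call(rbind, lapply(metrics, function(m) {
    v <- splits[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               ci_lower = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
               ci_upper = unname(stats::quantile(v, 0.975, na.rm = TRUE)),
               n_used = sum(!is.na(v)), stringsAsFactors = FALSE)
  }))
  summary$ci_lower <- pmin(pmax(summary$ci_lower, 0), 1)
  summary$ci_upper <- pmin(pmax(summary$ci_upper, 0), 1)
  structure(list(splits = splits, summary = summary, n_splits = n_splits,
                 test_fraction = test_fraction),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Stratified shuffle-split validation (%d splits, %.3g test fraction)\n",
              x$n_splits, x$test_fraction))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s mean %.3f  95%% CI [%.3f, %.3f]  (n = %d)\n",
                s$metric[i], s$mean[i], s$ci_lower[i], s$ci_upper[i],
                s$n_used[i]))
  invisible(x)
}

#' Stratified shuffle-split validation
#'
#' Repeats `n_splits` times: draw a stratified random test set of the
#' given fraction, reset the classifier, SMOTE-augment and train on the
#' remainder, and score accuracy, rank-based AUC, precision, and recall
#' on the held-out test set (positive class = in-corona). Splits whose
#' test set contains a single class get `NA` AUC, excluded from the
#' aggregate. Aggregates are the per-metric mean and percentile 95%
#' confidence interval over splits.
#'
#' By default the min-max scaler is fitted on the complete table before
#' splitting (`scale_mode = "global"`, replicating the original
#' processing order); `scale_mode = "train"` refits the scaler on each
#' training split only and is the leak-free option. `smote_before_split =
#' TRUE` applies SMOTE to the whole dataset before splitting -- a known
#' leakage mode retained for fidelity experiments only.
#'
#' @inheritParams train
#' @param n_splits number of shuffle splits; default 100.
#' @param test_fraction held-out fraction per split; default 0.1.
#' @param scale_mode `"global"` (default) or `"train"`.
#' @param smote_before_split leakage mode flag (see above).
#' @param seed optional integer seed controlling the whole run.
#' @return A `validation_result` with per-split metrics and aggregates.
#' @export
validate <- function(features, labels, n_splits = 100, test_fraction = 0.1,
                     cfg = classifier_config(), smote_cfg = smote_config(),
                     scale_mode = c("global", "train"),
                     smote_before_split = FALSE, seed = NULL) {
  scale_mode <- match.arg(scale_mode)
  x <- feature_matrix(features)
  labels <- as.logical(labels)
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("each class needs at least 2 members")
  if (!is.null(seed)) set.seed(seed)
  xs_all <- NULL
  if (scale_mode == "global") {
    scaler <- minmax_fit(x)
    xs_all <- minmax_apply(scaler, x)
  }
  if (smote_before_split) {
    if (is.null(xs_all))
      stop("smote_before_split requires scale_mode = 'global'")
    aug <- augment_minority(xs_all, labels, smote_cfg)
    xs_all <- aug$x
    labels <- aug$labels
    x <- xs_all
  }
  rows <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    test_idx <- stratified_test_idx(labels, test_fraction)
    train_idx <- setdiff(seq_along(labels), test_idx)
    if (scale_mode == "train") {
      scaler <- minmax_fit(x[train_idx, , drop = FALSE])
      xs_train <- minmax_apply(scaler, x[train_idx, , drop = FALSE])
      xs_test <- minmax_apply(scaler, x[test_idx, , drop = FALSE])
    } else {
      xs_train <- xs_all[train_idx, , drop = FALSE]
      xs_test <- xs_all[test_idx, , drop = FALSE]
    }
    y_train <- labels[train_idx]
    if (!smote_before_split && !is.null(smote_cfg)) {
      aug <- augment_minority(xs_train, y_train, smote_cfg)
      xs_train <- aug$x
      y_train <- aug$labels
    }
    forest <- fit_forest(xs_train, y_train, cfg)
    prob <- stats::predict(forest, data = as.data.frame(xs_test),
                           num.threads = 1)$predictions[, "in"]
    rows[[s]] <- c(split = s, split_metrics(prob, labels[test_idx]))
  }
  splits <- as.data.frame(do.call(rbind, rows))
  make_validation_result(splits, n_splits, test_fraction)
}

#' Cross-biofluid validation
#'
#' Trains once on the complete dataset A and repeatedly scores a
#' stratified random subset of dataset B. The tested fraction of B is
#' scaled so that the test set has the same expected size as a 10% test
#' split of the combined dataset: `f = base_fraction * n_total / n_B`,
#' capped at 1 (with a warning).
#'
#' @param features_a,labels_a training biofluid dataset.
#' @param features_b,labels_b test biofluid dataset.
#' @param n_total total protein count of the combined-biofluid dataset.
#' @param n_repeats number of scored subsets; default 100.
#' @param base_fraction baseline test fraction; default 0.1.
#' @inheritParams validate
#' @return A `validation_result`.
#' @export
cross_biofluid_validate <- function(features_a, labels_a, features_b,
                                    labels_b, n_total, n_repeats = 100,
                                    base_fraction = 0.1,
                                    cfg = classifier_config(),
                                    smote_cfg = smote_config(),
                                    seed = NULL) {
  xa <- feature_matrix(features_a)
  xb <- feature_matrix(features_b)
  labels_a <- as.logical(labels_a)
  labels_b <- as.logical(labels_b)
  if (nrow(xa) == 0L || nrow(xb) == 0L) stop("both datasets must be nonempty")
  f <- base_fraction * n_total / nrow(xb)
  if (f > 1) {
    warning("computed test fraction ", signif(f, 4), " exceeds 1; capped")
    f <- 1
  }
  if (!is.null(seed)) set.seed(seed)
  model <- train(xa, labels_a, cfg = cfg, smote_cfg = smote_cfg)
  pred_all <- predict_corona(model, xb)
  rows <- vector("list", n_repeats)
  for (s in seq_len(n_repeats)) {
    idx <- stratified_test_idx(labels_b, f)
    rows[[s]] <- c(split = s,
                   split_metrics(pred_all$probability[idx], labels_b[idx]))
  }
  splits <- as.data.frame(do.call(rbind, rows))
  make_validation_result(splits, n_repeats, f)
}

#' Hyperparameter grid search
#'
#' Scores every configuration in the grid with [validate] (typically at a
#' reduced number of splits) and returns the configuration maximizing the
#' mean of the objective metric. Ties are broken by fewer trees, then by
#' shallower maximal depth.
#'
#' @inheritParams validate
#' @param grid a `data.frame` with columns `n_trees` and optionally
#'   `max_depth` (`NA` = unlimited), or a list of [classifier_config]s.
#' @param objective one of `"accuracy"`, `"auc"`, `"precision"`,
#'   `"recall"`; default `"precision"`.
#' @return The winning [classifier_config]; the full score table is
#'   attached as attribute `"scores"`.
#' @export
grid_search <- function(features, labels, grid, objective = "precision",
                        n_splits = 20, test_fraction = 0.1,
                        smote_cfg = smote_config(), seed = NULL) {
  if (!objective %in% c("accuracy", "auc", "precision", "recall"))
    stop("unknown objective: ", objective)
  if (is.data.frame(grid)) {
    if (nrow(grid) == 0L) stop("empty hyperparameter grid")
    cfgs <- lapply(seq_len(nrow(grid)), function(i) {
      depth <- if ("max_depth" %in% names(grid) && !is.na(grid$max_depth[i]))
        grid$max_depth[i] else NULL
      classifier_config(n_trees = grid$n_trees[i], max_depth = depth)
    })
  } else {
    cfgs <- grid
    if (length(cfgs) == 0L) stop("empty hyperparameter grid")
  }
  scores <- vapply(cfgs, function(cfg) {
    v <- validate(features, labels, n_splits = n_splits,
                  test_fraction = test_fraction, cfg = cfg,
                  smote_cfg = smote_cfg, seed = seed)
    v$summary$mean[v$summary$metric == objective]
  }, numeric(1))
  depth <- vapply(cfgs, function(cfg)
    if (is.null(cfg$max_depth)) Inf else as.numeric(cfg$max_depth),
    numeric(1))
  trees <- vapply(cfgs, function(cfg) as.numeric(cfg$n_trees), numeric(1))
  best <- order(-scores, trees, depth)[1]
  out <- cfgs[[best]]
  attr(out, "scores") <- data.frame(n_trees = trees, max_depth = depth,
                                    score = scores,
                                    objective = objective)
  out
}
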