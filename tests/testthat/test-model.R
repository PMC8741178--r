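test_that("configuration objects validate their fields", {
  expect_error(smote_config(ratio = 0), "ratio")
  expect_error(smote_config(ratio = 1.2), "ratio")
  expect_error(classifier_config(n_trees = 0), "n_trees")
  expect_error(classifier_config(split_criterion = "entropy"),
               "Gini")
})

test_that("SMOTE produces the right number of convex-combination points", {
  set.seed(21)
  minority <- matrix(runif(40), ncol = 2,
                     dimnames = list(NULL, c("a", "b")))
  n_majority <- 50
  cfg <- smote_config(ratio = 0.7, k_neighbors = 5, seed = 1)
  synth <- smote(minority, n_majority, cfg)
  expect_equal(nrow(synth), ceiling(0.7 * 50) - 20)
  # convex hull: synthetic coordinates stay within minority ranges
  expect_true(all(synth[, "a"] >= min(minority[, "a"]) &
                  synth[, "a"] <= max(minority[, "a"])))

  # already at ratio: no synthesis
  expect_equal(nrow(smote(minority, 20, cfg)), 0)

  # minority too small for k
  expect_error(smote(minority[1:3, ], 50,
                     smote_config(k_neighbors = 5)), "smaller k")
})

test_that("SMOTE on two points interpolates along the segment", {
  minority <- matrix(c(0, 0, 1, 1), ncol = 2, byrow = TRUE,
                     dimnames = list(NULL, c("x", "y")))
  synth <- smote(minority, 20, smote_config(k_neighbors = 1, seed = 2))
  expect_gt(nrow(synth), 0)
  # both coordinates equal: points lie on the diagonal segment
  expect_equal(synth[, "x"], synth[, "y"], tolerance = 1e-12)
  expect_true(all(synth >= 0 & synth <= 1))

  # two identical points: synthetics equal that point
  ident <- matrix(c(3, 7, 3, 7), ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("x", "y")))
  s2 <- smote(ident, 20, smote_config(k_neighbors = 1, seed = 3))
  expect_true(all(s2[, "x"] == 3 & s2[, "y"] == 7))
})

test_that("SMOTE is deterministic given a seed", {
  set.seed(22)
  minority <- matrix(rnorm(60), ncol = 3)
  colnames(minority) <- paste0("f", 1:3)
  s1 <- smote(minority, 60, smote_config(k_neighbors = 4, seed = 7))
  s2 <- smote(minority, 60, smote_config(k_neighbors = 4, seed = 7))
  expect_identical(s1, s2)
})

test_that("training on separable data fits perfectly and reproducibly", {
  toy <- toy_classification_data(gap = 6, sd = 0.3)
  cfg <- classifier_config(n_trees = 60, seed = 5)
  sm <- smote_config(k_neighbors = 3, seed = 5)
  m <- train(toy$x, toy$labels, cfg = cfg, smote_cfg = sm)
  pred <- predict_corona(m, toy$x)
  expect_equal(mean(pred$in_corona == toy$labels), 1)

  m2 <- train(toy$x, toy$labels, cfg = cfg, smote_cfg = sm)
  expect_identical(predict_corona(m2, toy$x)$probability,
                   pred$probability)
})

test_that("train/predict error contracts", {
  toy <- toy_classification_data()
  expect_error(train(toy$x, rep(TRUE, nrow(toy$x))), "both classes")
  expect_error(train(toy$x[, 0, drop = FALSE], toy$labels))
  m <- train(toy$x, toy$labels,
             cfg = classifier_config(n_trees = 20, seed = 1),
             smote_cfg = NULL)
  bad <- toy$x
  colnames(bad)[1] <- "renamed"
  expect_error(predict_corona(m, bad), "renamed")
  pred <- predict_corona(m, toy$x)
  expect_identical(pred$in_corona, pred$probability >= 0.5)
})

test_that("rank-statistic AUC matches pROC and is monotone-invariant", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- runif(80) < 0.4
  prob <- runif(80) + truth * 0.3
  auc <- coronaRF:::rank_auc(prob, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE)))
  expect_equal(auc, ref, tolerance = 1e-12)
  # strictly monotone transform leaves the rank AUC unchanged
  expect_equal(coronaRF:::rank_auc(qlogis(prob / 2), truth), auc)
})

test_that("validation separates signal from null", {
  toy <- toy_classification_data(gap = 6, sd = 0.3)
  sm <- smote_config(k_neighbors = 5)
  v <- validate(toy$x, toy$labels, n_splits = 30,
                cfg = classifier_config(n_trees = 60), smote_cfg = sm,
                seed = 31)
  s <- v$summary
  expect_gte(s$mean[s$metric == "accuracy"], 0.95)
  expect_gte(s$mean[s$metric == "auc"], 0.95)

  set.seed(32)
  null_labels <- sample(toy$labels)
  v0 <- validate(toy$x, null_labels, n_splits = 50,
                 cfg = classifier_config(n_trees = 60), smote_cfg = sm,
                 seed = 33)
  auc0 <- v0$summary$mean[v0$summary$metric == "auc"]
  expect_gt(auc0, 0.38)
  expect_lt(auc0, 0.62)
})

test_that("validation is deterministic given a seed and CI degenerates at 1 split", {
  toy <- toy_classification_data(n_per_class = 30)
  args <- list(toy$x, toy$labels, n_splits = 5,
               cfg = classifier_config(n_trees = 30),
               smote_cfg = smote_config(k_neighbors = 5), seed = 99)
  v1 <- do.call(validate, args)
  v2 <- do.call(validate, args)
  expect_identical(v1$splits, v2$splits)

  v <- validate(toy$x, toy$labels, n_splits = 1,
                cfg = classifier_config(n_trees = 30),
                smote_cfg = smote_config(k_neighbors = 5), seed = 1)
  s <- v$summary
  expect_equal(s$ci_lower, pmin(pmax(s$mean, 0), 1))
  expect_equal(s$ci_upper, pmin(pmax(s$mean, 0), 1))
})

test_that("SMOTE-before-split leakage inflates recall relative to leak-free", {
  toy <- toy_classification_data(n_per_class = 40, gap = 0.8, sd = 1,
                                 seed = 77)
  # imbalance so SMOTE has something to do
  keep <- c(which(toy$labels)[1:16], which(!toy$labels))
  x <- toy$x[keep, ]
  y <- toy$labels[keep]
  sm <- smote_config(k_neighbors = 5)
  cfg <- classifier_config(n_trees = 80)
  leak <- validate(x, y, n_splits = 25, cfg = cfg, smote_cfg = sm,
                   smote_before_split = TRUE, seed = 41)
  fair <- validate(x, y, n_splits = 25, cfg = cfg, smote_cfg = sm,
                   seed = 41)
  rec_leak <- leak$summary$mean[leak$summary$metric == "recall"]
  rec_fair <- fair$summary$mean[fair$summary$metric == "recall"]
  expect_gte(rec_leak, rec_fair - 0.02)
})

test_that("cross-biofluid test fraction arithmetic and capping", {
  toy_a <- toy_classification_data(n_per_class = 50, gap = 4, sd = 0.5,
                                   seed = 51)
  toy_b <- toy_classification_data(n_per_class = 50, gap = 4, sd = 0.5,
                                   seed = 52)
  v <- cross_biofluid_validate(toy_a$x, toy_a$labels, toy_b$x,
                               toy_b$labels, n_total = 200,
                               n_repeats = 10,
                               cfg = classifier_config(n_trees = 40),
                               smote_cfg = smote_config(k_neighbors = 5),
                               seed = 53)
  expect_equal(v$test_fraction, 0.1 * 200 / 100)
  expect_gte(v$summary$mean[v$summary$metric == "auc"], 0.9)

  # n_B = n_total reduces to the plain 10% fraction
  v2 <- cross_biofluid_validate(toy_a$x, toy_a$labels, toy_b$x,
                                toy_b$labels, n_total = 100,
                                n_repeats = 2,
                                cfg = classifier_config(n_trees = 20),
                                smote_cfg = smote_config(k_neighbors = 5),
                                seed = 54)
  expect_equal(v2$test_fraction, 0.1)

  expect_warning(
    cross_biofluid_validate(toy_a$x, toy_a$labels, toy_b$x[1:8, ],
                            toy_b$labels[1:8], n_total = 200,
                            n_repeats = 2,
                            cfg = classifier_config(n_trees = 20),
                            smote_cfg = NULL, seed = 55),
    "capped")
})

test_that("grid search returns the argmax with deterministic tie-breaks", {
  toy <- toy_classification_data(n_per_class = 30, gap = 3, sd = 0.5)
  sm <- smote_config(k_neighbors = 5)
  single <- grid_search(toy$x, toy$labels,
                        grid = data.frame(n_trees = 25),
                        n_splits = 3, smote_cfg = sm, seed = 61)
  expect_equal(single$n_trees, 25L)

  best <- grid_search(toy$x, toy$labels,
                      grid = data.frame(n_trees = c(10, 40)),
                      n_splits = 3, smote_cfg = sm, seed = 61)
  expect_s3_class(best, "classifier_config")
  expect_equal(nrow(attr(best, "scores")), 2)

  expect_error(grid_search(toy$x, toy$labels,
                           grid = data.frame(n_trees = 10),
                           objective = "f1"), "unknown objective")
  expect_error(grid_search(toy$x, toy$labels,
                           grid = data.frame(n_trees = integer(0))),
               "empty")
})
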