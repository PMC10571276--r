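# Feature matrix, splits, stacking model and evaluation report.

test_that("feature matrix has 31 standardized columns in fixed order", {
  sep <- separable_features(n = 60, seed = 2)
  X <- build_feature_matrix(sep$records)
  expect_equal(ncol(X), 31L)
  expect_equal(colnames(X)[1:10],
               c("tpsa", "logp", "rb", "hbd", "hba", "mw", "nring", "naring",
                 "qed", "fsp3"))
  # training standardization: non-constant columns have mean 0, sd 1
  nonconst <- apply(X, 2, function(v) diff(range(v)) > 0)
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X[, nonconst], 2, sd) - 1) < 1e-9))
  # ionization one-hot block sums to 1 per row (before standardization)
  raw <- unstandardize_features(X)
  ion <- raw[, grepl("^ion_", colnames(raw))]
  expect_true(all(abs(rowSums(ion) - 1) < 1e-9))
  # round-trip of the affine transform
  M2 <- build_feature_matrix(sep$records, training_stats = attr(X, "feature_stats"))
  expect_equal(unname(M2), unname(X))
  # unseen chemical class maps to the zero reference block with a warning
  rec2 <- sep$records[1:2, ]
  rec2$chem_class <- "Martian lipids"
  expect_warning(X2 <- build_feature_matrix(rec2,
                                            training_stats = attr(X, "feature_stats")),
                 "Other")
  raw2 <- unstandardize_features(X2, attr(X, "feature_stats"))
  expect_true(all(raw2[, grepl("^class_", colnames(raw2))] == 0))
})

test_that("stratified folds balance every stratum and are deterministic", {
  strata <- rep("A", 80)
  f <- stratified_folds(strata, k = 8, seed = 4)
  expect_equal(as.integer(table(f)), rep(10L, 8))
  # pigeonhole for a 3-member class
  strata2 <- c(rep("A", 40), rep("B", 3))
  f2 <- stratified_folds(strata2, k = 8, seed = 4)
  expect_true(all(table(f2[strata2 == "B"]) == 1))
  expect_true(max(table(factor(f2[strata2 == "A"], levels = 1:8))) -
              min(table(factor(f2[strata2 == "A"], levels = 1:8))) <= 1)
  expect_identical(stratified_folds(strata2, 8, seed = 9),
                   stratified_folds(strata2, 8, seed = 9))
  expect_error(stratified_folds(rep("A", 3), k = 8), "exceeds")
})

test_that("butina clustering groups identical molecules and splits cleanly", {
  fps <- fingerprint_matrix(c("CCO", "CCO", "c1ccccc1", "CC(F)(F)F"))
  cl <- butina_cluster(fps, 0.8)
  expect_equal(cl[1], cl[2])
  expect_false(cl[1] == cl[3])
  sp <- butina_split(fps, threshold = 0.8, test_fraction = 0.25, seed = 1)
  expect_equal(cl[1], cl[2])
  both <- intersect(cl[sp$train], cl[sp$test])
  expect_length(both, 0)
  # degenerate: all identical -> one cluster -> error with guidance
  fps1 <- fingerprint_matrix(c("CCO", "CCO", "CCO"))
  expect_error(butina_split(fps1), "single")
})

test_that("the stack fits, predicts in [0,1], and dominates on separable data", {
  sep <- separable_features(n = 240, seed = 3)
  X <- build_feature_matrix(sep$records)
  tr <- seq_len(200)
  te <- 201:240
  Xtr <- X[tr, ]; attr(Xtr, "feature_stats") <- attr(X, "feature_stats")
  sl <- fit_superlearner(Xtr, sep$y[tr], cv_folds = 5, seed = 10)
  expect_s3_class(sl, "gutperm_superlearner")
  expect_equal(dim(sl$meta_features), c(200L, 9L))
  expect_false(anyNA(sl$meta_features))
  p <- predict(sl, X[te, ])
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(evaluate_predictions(sep$y[te], p)$auroc[1], 0.99)
  # hard-class prediction at the 0.5 tie-positive threshold
  cls <- predict(sl, X[te, ], type = "class")
  expect_equal(as.character(cls), ifelse(p >= 0.5, "Lingerer", "Traverser"))
  # determinism / no dependence on test labels: refit is bitwise identical
  sl2 <- fit_superlearner(Xtr, sep$y[tr], cv_folds = 5, seed = 10)
  expect_identical(sl$meta_features, sl2$meta_features)
  expect_identical(coef(sl$meta_model), coef(sl2$meta_model))
  expect_identical(p, predict(sl2, X[te, ]))
  expect_error(predict(sl, X[te, 1:30]), "columns")
  expect_error(fit_superlearner(Xtr, rep("Lingerer", 200)), "both classes")
})

test_that("evaluation metrics and the standardized row behave per contract", {
  y <- c("Lingerer", "Lingerer", "Traverser", "Traverser")
  # perfect predictor
  ev <- evaluate_predictions(y, c(0.9, 0.8, 0.1, 0.2))
  expect_equal(unname(as.matrix(ev)["all", ]), rep(1, 6))
  # FL == noFL values -> standardized equals either
  y2 <- rep(c("Lingerer", "Traverser"), 10)
  s2 <- rep(c(0.9, 0.2), 10)
  fl <- rep(c(TRUE, FALSE), each = 10)
  ev2 <- evaluate_predictions(y2, s2, fl_mask = fl)
  expect_equal(unname(as.matrix(ev2)["standardized", ]),
               unname(as.matrix(ev2)["fl", ]))
  # one-class scope: AUROC absent, propagates into the standardized row
  y3 <- c(rep("Lingerer", 6), rep(c("Lingerer", "Traverser"), 3))
  s3 <- c(rep(0.9, 6), 0.8, 0.3, 0.9, 0.2, 0.7, 0.4)
  fl3 <- rep(c(TRUE, FALSE), each = 6)
  ev3 <- evaluate_predictions(y3, s3, fl_mask = fl3)
  expect_true(is.na(ev3["fl", "auroc"]))
  expect_true(is.na(ev3["standardized", "auroc"]))
  expect_equal(ev3["fl", "auprc"], 1)
  # hard labels carry no curve metrics
  ev4 <- evaluate_predictions(y2, factor(ifelse(s2 > 0.5, "Lingerer", "Traverser")))
  expect_true(is.na(ev4["all", "auroc"]))
  expect_equal(ev4["all", "accuracy"], 1)
})

test_that("AUROC and AUPRC agree with an independent reference", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- runif(80) < 0.4
  s <- ifelse(y, rnorm(80, 1), rnorm(80))
  ev <- evaluate_predictions(y, pmin(pmax(stats::plogis(s), 0), 1))
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, stats::plogis(s)))))
  expect_equal(ev["all", "auroc"], ref, tolerance = 1e-12)
})
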