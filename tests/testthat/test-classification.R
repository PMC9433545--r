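make_planted_features <- function(n = 60, p = 20, gap = 3, seed = 1,
                                  separable = FALSE) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  if (separable) {
    # disjoint class supports: a margin of at least 2 on feature 7
    X[, 7] <- 4 * y + runif(n, -1, 1)
  } else {
    X[, 7] <- X[, 7] + gap * y        # the planted informative feature
  }
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

test_that("confusion-matrix metrics follow their definitions in percent", {
  m <- metrics_from_confusion(6, 2, 3, 12)
  expect_equal(unname(m["accuracy"]), 100 * 18 / 23, tolerance = 1e-10)
  expect_equal(unname(m["sensitivity"]), 75)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["ppv"]), 100 * 6 / 9, tolerance = 1e-10)
  expect_equal(unname(m["npv"]), 100 * 12 / 14, tolerance = 1e-10)

  expect_equal(unname(metrics_from_confusion(10, 0, 0, 10)),
               rep(100, 5))
  degen <- metrics_from_confusion(0, 5, 0, 5)
  expect_equal(unname(degen["sensitivity"]), 0)
  expect_equal(unname(degen["specificity"]), 100)
  expect_true(is.na(degen["ppv"]))
})

test_that("the three classifiers separate an easy synthetic problem", {
  pf <- make_planted_features(n = 80, gap = 4, seed = 51)
  tr <- c(1:30, 41:70)
  te <- setdiff(1:80, tr)
  for (model in c("svm", "rf", "gb")) {
    cl <- fit_classifier(model, pf$X[tr, ], pf$y[tr], seed = 52)
    acc <- mean(cl$predict(pf$X[te, ]) == pf$y[te])
    expect_gte(acc, 0.9)
    # the planted feature carries the largest importance
    expect_equal(unname(which.max(cl$importance)), 7L)
  }
})

test_that("feature assembly yields 706 named, traceable columns", {
  coh <- small_cohort()
  sweep <- c(0.2, 0.4)
  mts <- lapply(coh$subjects[1:3], function(s) {
    nets <- sweep_networks(pearson_connectivity(s$timeseries), sweep)
    compute_metric_table(nets, sweep, n_random = 2, seed = 53,
                         subject_id = s$subject_id)
  })
  fm <- assemble_features(mts)
  expect_equal(ncol(fm$X), 10 + 6 * 116)   # 706
  expect_equal(nrow(fm$X), 3)
  expect_true("global__Lp" %in% colnames(fm$X))
  expect_true("betweenness__Frontal_Mid_Orb_L" %in% colnames(fm$X))
  # the named column sits at the betweenness block position for ROI 9
  expect_equal(which(colnames(fm$X) == "betweenness__Frontal_Mid_Orb_L"),
               10 + 116 + 9)
  expect_false(any(duplicated(colnames(fm$X))))
  # identical metric tables give identical rows
  fm2 <- assemble_features(list(mts[[1]], mts[[1]]))
  expect_equal(fm2$X[1, ], fm2$X[2, ])
})

test_that("RFE keeps informative features and honors n_keep", {
  pf <- make_planted_features(seed = 54)
  sel <- rfe_select(pf$X, pf$y, "svm", n_keep = 5, seed = 55)
  expect_length(sel$selected, 5)
  expect_length(sel$elimination_order, 15)

  # n_keep = p: identity
  sel_all <- rfe_select(pf$X, pf$y, "svm", n_keep = 20, seed = 55)
  expect_equal(sel_all$selected, colnames(pf$X))

  # planted feature survives in nearly all seeded trials
  hits <- vapply(1:100, function(s) {
    pf <- make_planted_features(seed = 1000 + s)
    "f7" %in% rfe_select(pf$X, pf$y, "svm", n_keep = 5,
                         seed = 2000 + s)$selected
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # a duplicated informative feature: at least one copy retained
  pf2 <- make_planted_features(seed = 56)
  X2 <- cbind(pf2$X, f_dup = pf2$X[, 7])
  sel2 <- rfe_select(X2, pf2$y, "svm", n_keep = 5, seed = 57)
  expect_true(any(c("f7", "f_dup") %in% sel2$selected))
})

test_that("nested CV partitions subjects once each and pools counts", {
  pf <- make_planted_features(n = 54, seed = 58, separable = TRUE)
  cfg <- cv_config(k = 9, n_selected_features = 5, seed = 59)
  rep_gb <- nested_cv_classify(pf$X, pf$y, cfg, "svm")
  expect_equal(sum(rep_gb$counts), 54)
  expect_equal(unname(rep_gb$metrics["accuracy"]),
               100 * (rep_gb$counts["TP"] + rep_gb$counts["TN"]) / 54,
               ignore_attr = TRUE)
  # perfectly separable: accuracy 100%
  expect_equal(unname(rep_gb$metrics["accuracy"]), 100)
  # deterministic rerun
  rep2 <- nested_cv_classify(pf$X, pf$y, cfg, "svm")
  expect_identical(rep_gb$counts, rep2$counts)
})

test_that("with no selection pressure circular and nested modes coincide", {
  pf <- make_planted_features(n = 36, seed = 60)
  cfg <- cv_config(k = 4, n_selected_features = 20, seed = 61)
  a <- nested_cv_classify(pf$X, pf$y, cfg, "svm")
  b <- circular_cv_classify(pf$X, pf$y, cfg, "svm")
  expect_equal(a$counts, b$counts)
  expect_equal(a$mode, "nested")
  expect_equal(b$mode, "circular")
})

test_that("nested selection never looks at held-out rows", {
  pf <- make_planted_features(n = 36, seed = 62)
  cfg <- cv_config(k = 4, n_selected_features = 5, seed = 63)
  ref <- nested_cv_classify(pf$X, pf$y, cfg, "svm")
  fold <- adhdnet:::stratified_folds(pf$y, cfg$k, cfg$seed)
  for (f in 1:4) {
    X2 <- pf$X
    # garbage in the test fold must not change that fold's selected features
    set.seed(900 + f)
    X2[fold == f, ] <- matrix(rnorm(sum(fold == f) * ncol(X2), 50, 100),
                              sum(fold == f), ncol(X2))
    alt <- nested_cv_classify(X2, pf$y, cfg, "svm")
    expect_identical(alt$selected_features[[f]], ref$selected_features[[f]])
  }
})

test_that("median imputation for selection is train-fold only", {
  pf <- make_planted_features(n = 36, seed = 64)
  X <- pf$X
  X[c(3, 20), 2] <- NA
  cfg <- cv_config(k = 4, n_selected_features = 5, seed = 65)
  expect_silent(nested_cv_classify(X, pf$y, cfg, "svm"))
})
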