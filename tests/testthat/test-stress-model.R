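# labelled table where only lf_hf carries class information:
# class 0 <=> lf_hf < 2, class 1 <=> 2..4, class 2 <=> > 4
separable_table <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  tab <- as.data.frame(matrix(runif(n * 34), nrow = n,
                              dimnames = list(NULL, hrv_feature_names())))
  tab$label <- rep(0:2, each = n_per_class)
  tab$lf_hf <- c(runif(n_per_class, 0, 1.8), runif(n_per_class, 2.2, 3.8),
                 runif(n_per_class, 4.2, 8))
  tab
}

test_that("a separable single-feature problem yields a shallow exact tree", {
  tab <- separable_table(100, seed = 5)
  m <- train_stress_model(tab)
  depth <- max(floor(log2(m$nodes$node)))
  expect_lte(depth, 2)
  expect_equal(m$metadata$train_accuracy, 1.0)
  expect_true(all(m$nodes$var[!m$nodes$is_leaf] == "lf_hf"))

  probe <- tab[1, ]
  probe$lf_hf <- 5
  expect_equal(predict_stress(m, probe[, hrv_feature_names()]), 2L)
  probe$lf_hf <- 0.5
  expect_equal(predict_stress(m, probe[, hrv_feature_names()]), 0L)
})

test_that("our node-table descent reproduces rpart's own predictions", {
  tab <- generate_labeled_features(n_per_class = 60, seed = 17)
  sp <- split_train_test(tab, 0.25, seed = 3)
  m <- train_stress_model(sp$train)
  df <- sp$train[, hrv_feature_names()]
  df$.label <- factor(sp$train$label, levels = 0:2)
  ref <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(
                        maxdepth = 10, minsplit = 10, minbucket = 5,
                        cp = 0, xval = 0, maxcompete = 0, maxsurrogate = 0,
                        usesurrogate = 0))
  pred_ref <- as.integer(as.character(
    predict(ref, sp$test[, hrv_feature_names()], type = "class")))
  expect_identical(predict_stress(m, sp$test), pred_ref)
})

test_that("tiny samples force a single-leaf majority model with a warning", {
  tab <- separable_table(3, seed = 2)  # 9 rows < min_samples_split = 10
  expect_warning(m <- train_stress_model(tab), "single-leaf")
  expect_equal(nrow(m$nodes), 1)
  probe <- separable_table(2, seed = 9)
  expect_true(all(predict_stress(m, probe) == m$nodes$class[1]))
})

test_that("training is deterministic for a fixed seed and input", {
  tab <- generate_labeled_features(n_per_class = 40, seed = 23)
  probe <- generate_labeled_features(n_per_class = 10, seed = 24)
  m1 <- train_stress_model(tab)
  m2 <- train_stress_model(tab)
  expect_identical(predict_stress(m1, probe), predict_stress(m2, probe))
  expect_identical(m1$nodes, m2$nodes)
})

test_that("NaN features are rejected at train and predict time with row numbers", {
  tab <- separable_table(20, seed = 7)
  tab$sampen[4] <- NaN
  expect_error(train_stress_model(tab), "4")
  m <- train_stress_model(separable_table(20, seed = 7))
  bad <- separable_table(2, seed = 1)
  bad$sampen[2] <- NaN
  expect_error(predict_stress(m, bad), "2")
})

test_that("evaluation metrics match hand arithmetic on a fixed confusion matrix", {
  # construct predictions realizing the confusion matrix
  # [[8,2,0],[1,9,0],[0,0,10]] via a probe table and a known tree
  tab <- separable_table(50, seed = 11)
  m <- train_stress_model(tab)
  probe <- separable_table(10, seed = 13)
  # truth 0 predicted as 1 twice, truth 1 predicted as 0 once
  probe$lf_hf[probe$label == 0][1:2] <- 3    # predicted 1
  probe$lf_hf[probe$label == 1][1] <- 0.5    # predicted 0
  ev <- evaluate_stress_model(m, probe)
  expect_equal(unname(ev$confusion["0", ]), c(8, 2, 0))
  expect_equal(unname(ev$confusion["1", ]), c(1, 9, 0))
  expect_equal(unname(ev$confusion["2", ]), c(0, 0, 10))
  expect_equal(ev$accuracy, 27 / 30)
  expect_equal(unname(ev$precision["0"]), 8 / 9)
  expect_equal(unname(ev$recall["0"]), 0.8)
  expect_equal(unname(ev$f1["2"]), 1)

  perfect <- evaluate_stress_model(m, separable_table(10, seed = 14))
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$f1 == 1))
})

test_that("stratified split preserves class balance and is seed-reproducible", {
  tab <- separable_table(100, seed = 3)
  sp <- split_train_test(tab, 0.3, seed = 8)
  expect_equal(nrow(sp$train), 210)
  expect_equal(nrow(sp$test), 90)
  expect_equal(as.integer(table(sp$test$label)), rep(30L, 3))
  sp2 <- split_train_test(tab, 0.3, seed = 8)
  expect_identical(sp$test, sp2$test)
  expect_error(split_train_test(tab, 1.0), "strictly between")
})

test_that("training accuracy is monotone in max_depth", {
  tab <- generate_labeled_features(n_per_class = 60, seed = 31)
  accs <- vapply(1:10, function(d) {
    m <- train_stress_model(tab, tree_hyperparams(max_depth = d))
    m$metadata$train_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("predictions are invariant under a monotone feature transform", {
  tab <- generate_labeled_features(n_per_class = 50, seed = 37)
  sp <- split_train_test(tab, 0.3, seed = 1)
  m1 <- train_stress_model(sp$train)
  tr <- function(df) { df$mean_rr <- log(df$mean_rr); df }
  m2 <- train_stress_model(tr(sp$train))
  expect_identical(predict_stress(m1, sp$test), predict_stress(m2, tr(sp$test)))
})

test_that("model archives round-trip through JSON", {
  tab <- separable_table(40, seed = 19)
  m <- train_stress_model(tab)
  p <- withr::local_tempfile(fileext = ".json")
  save_stress_model(m, p)
  m2 <- load_stress_model(p)
  probe <- separable_table(15, seed = 20)
  expect_identical(predict_stress(m, probe), predict_stress(m2, probe))
  expect_equal(m2$hyperparams$max_depth, 10L)
  writeLines('{"format": "other"}', p)
  expect_error(load_stress_model(p), "archive")
})
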