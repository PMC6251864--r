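# small, quickly separable training fixture shared by the model tests
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim(seed = 7L)
      ds <- build_comprehensive_dataset(sim$sites, sim$transcripts,
                                        ratio = 5, seed = 7)
      cache <<- list(sim = sim, ds = ds)
    }
    cache
  }
})

test_that("all four learners train and separate motif windows on held-out
           data", {
  fx <- model_fixture()
  for (alg in c("random_forest", "logistic_regression", "naive_bayes",
                "decision_tree")) {
    hp <- if (alg == "random_forest") list(n_tree = 60) else list()
    p <- train_predictor(fx$ds$train, algorithm = alg,
                         hyperparameters = hp, seed = 1)
    sc <- predict_scores(p, fx$ds$test)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(auc(sc, fx$ds$test$label), 0.5)
  }
})

test_that("decision tree accepts the published control parameters", {
  fx <- model_fixture()
  expect_no_error(
    p <- train_predictor(fx$ds$train, "decision_tree",
                         hyperparameters = list(min_split = 35,
                                                complexity = 0.00001,
                                                max_depth = 30),
                         seed = 1))
  expect_equal(p$hyperparameters$complexity, 1e-5)
})

test_that("training rejects single-class data", {
  fx <- model_fixture()
  neg_only <- fx$ds$train[fx$ds$train$label == 0L, ]
  expect_error(train_predictor(neg_only, "random_forest", seed = 1),
               "both classes")
})

test_that("training twice with the same seed scores a probe set identically", {
  fx <- model_fixture()
  p1 <- train_predictor(fx$ds$train, "random_forest",
                        hyperparameters = list(n_tree = 60), seed = 3)
  p2 <- train_predictor(fx$ds$train, "random_forest",
                        hyperparameters = list(n_tree = 60), seed = 3)
  probe <- fx$ds$test$window[1:100]
  expect_identical(predict_scores(p1, probe), predict_scores(p2, probe))
})

test_that("scoring is order-preserving, duplicate-consistent and guards the
           window width", {
  fx <- model_fixture()
  p <- train_predictor(fx$ds$train, "random_forest",
                       hyperparameters = list(n_tree = 60), seed = 1)
  expect_identical(predict_scores(p, character(0)), numeric(0))
  probe <- fx$ds$test$window[1:30]
  sc <- predict_scores(p, probe)
  perm <- sample(length(probe))
  expect_equal(predict_scores(p, probe[perm]), sc[perm])
  expect_equal(predict_scores(p, c(probe[1], probe[1]))[1],
               predict_scores(p, c(probe[1], probe[1]))[2])
  expect_error(predict_scores(p, "ACGT"), "width")
})

test_that("threshold selection matches an enumeration oracle on controlled
           scores", {
  scores <- seq(0.1, 1.0, by = 0.1)  # ten evenly spread negative scores
  thr <- m5cpred:::threshold_from_scores(0.10, scores,
                                         convention = "conservative")
  expect_equal(thr, 0.9)
  expect_equal(sum(scores > thr), 1L)  # exactly one negative above threshold
  # enumeration oracle: smallest observed t with frac(scores > t) <= alpha
  for (alpha in c(0.1, 0.3, 0.5)) {
    cand <- sort(scores)
    oracle <- min(cand[vapply(cand, function(t) mean(scores > t) <= alpha,
                              logical(1))])
    expect_equal(m5cpred:::threshold_from_scores(alpha, scores,
                                                 "conservative"), oracle)
    # nearest convention attains the closest achievable FPR
    thr_n <- m5cpred:::threshold_from_scores(alpha, scores, "nearest")
    attain <- vapply(cand, function(t) mean(scores > t), numeric(1))
    expect_equal(abs(mean(scores > thr_n) - alpha),
                 min(abs(attain - alpha)))
  }
  # alpha = 0.5 on symmetric scores lands next to the median
  thr_med <- m5cpred:::threshold_from_scores(0.5, scores, "conservative")
  expect_equal(thr_med, 0.5)
})

test_that("calibrated thresholds are monotone across stringency levels and
           recorded with their convention", {
  fx <- model_fixture()
  p <- train_predictor(fx$ds$train, "random_forest",
                       hyperparameters = list(n_tree = 60), seed = 1)
  neg <- sample_negative_windows(
    fx$sim$transcripts, 400,
    exclude = fx$sim$sites[fx$sim$sites$label == "positive", ],
    seed = 5, w = 10)
  for (conv in c("nearest", "conservative")) {
    pc <- suppressWarnings(
      calibrate_thresholds(p, neg, convention = conv))
    lv <- unlist(pc$thresholds$levels)
    expect_true(lv["high"] >= lv["medium"])
    expect_true(lv["medium"] >= lv["low"])
    expect_true(all(lv >= 0 & lv <= 1))
    expect_equal(pc$thresholds$convention, conv)
    if (conv == "conservative") {
      # guaranteed bound: attained FPR on the calibration set <= nominal
      cal_scores <- predict_scores(pc, neg)
      for (lev in names(lv)) {
        expect_lte(mean(cal_scores > lv[[lev]]),
                   pc$thresholds$fpr_levels[[lev]])
      }
    }
  }
  expect_error(calibrate_thresholds(p, character(0)), "empty")
})

test_that("predictor bundles round-trip scores exactly and detect tampering", {
  fx <- model_fixture()
  p <- train_predictor(fx$ds$train, "random_forest",
                       hyperparameters = list(n_tree = 60), seed = 1)
  neg <- sample_negative_windows(
    fx$sim$transcripts, 300,
    exclude = fx$sim$sites[fx$sim$sites$label == "positive", ],
    seed = 5, w = 10)
  p <- calibrate_thresholds(p, neg)
  dir <- tempfile()
  save_predictor(p, dir)
  # manifest is free-standing JSON
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$algorithm, "random_forest")
  expect_equal(man$hyperparameters$n_tree, 60L)
  p2 <- load_predictor(dir)
  probe <- fx$ds$test$window[1:100]
  expect_identical(predict_scores(p, probe), predict_scores(p2, probe))
  expect_equal(p2$thresholds$levels, p$thresholds$levels)
  # tampering with the serialized learner fails the checksum
  con <- file(file.path(dir, "model.rds"), "ab")
  writeBin(as.raw(1), con)
  close(con)
  expect_error(load_predictor(dir), "Checksum|tampered")
  # version drift is an explicit incompatibility
  man_path <- file.path(dir, "manifest.json")
  man$format_version <- 999
  jsonlite::write_json(man, man_path, auto_unbox = TRUE)
  expect_error(load_predictor(dir), "format version")
})

test_that("growing the forest from 10 to 300 trees does not erode held-out
           AUC by more than 0.02", {
  fx <- model_fixture()
  p10 <- train_predictor(fx$ds$train, "random_forest",
                         hyperparameters = list(n_tree = 10), seed = 1)
  p300 <- train_predictor(fx$ds$train, "random_forest",
                          hyperparameters = list(n_tree = 300), seed = 1)
  a10 <- auc(predict_scores(p10, fx$ds$test), fx$ds$test$label)
  a300 <- auc(predict_scores(p300, fx$ds$test), fx$ds$test$label)
  expect_gte(a300, a10 - 0.02)
})

test_that("tidy and glance expose hyperparameters and model metadata", {
  fx <- model_fixture()
  p <- train_predictor(fx$ds$train, "random_forest",
                       hyperparameters = list(n_tree = 60), seed = 1)
  td <- tidy(p)
  expect_equal(td$value[td$parameter == "n_tree"], 60)
  gl <- glance(p)
  expect_equal(gl$algorithm, "random_forest")
  expect_false(gl$calibrated)
})
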