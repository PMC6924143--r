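# Small-scale ensemble and learner tests; the full-scale pipeline benchmark
# lives in test-acceptance.R.

# One small, clearly separable dataset shared across blocks.
small_data <- local({
  recs <- assign_labels(simulate_odn_dataset(
    simulation_config(150, seed = 51, noise_sd = 0.03)))
  plan <- build_plan(recs, n_repeats = 3, train_fraction = 0.8, k = 4,
                     seed = 51)
  list(recs = recs, plan = plan)
})

fit_small <- function(ntree = 150L) {
  ensemble_fit(small_data$recs, small_data$plan, ntree = ntree)
}

test_that("random-forest member tunes mtry and is deterministic", {
  recs <- small_data$recs
  dict <- build_dictionary(recs[recs$label == "high", ],
                           recs[recs$label == "low", ], 0.10)
  x <- predict(fit_feature_pipeline(featurize(recs, dict)),
               featurize(recs, dict))
  rf1 <- train_rf(x, recs$label, k = 3, seed = 5, ntree = 100)
  rf2 <- train_rf(x, recs$label, k = 3, seed = 5, ntree = 100)
  expect_equal(rf1$mtry, rf2$mtry)
  expect_equal(predict(rf1, x), predict(rf2, x))
  expect_true(rf1$mtry %in% rf1$cv$mtry)
  expect_equal(nrow(rf1$cv), length(unique(rf1$cv$mtry)))
  # training-data balanced accuracy on separable data is high
  cm <- confusion(ifelse(predict(rf1, x) >= 0.5, "high", "low"), recs$label)
  expect_gt(classification_metrics(cm)[["balanced_accuracy"]], 0.9)
  expect_error(train_rf(x, rep("high", nrow(x)), k = 3, seed = 1),
               "single class")
  expect_error(train_rf(x, recs$label, mtry_grid = ncol(x) + 1, k = 3,
                        seed = 1), "exceeds")
})

test_that("ensemble members are isolated, evaluated and reproducible", {
  ens <- fit_small()
  expect_length(ens$members, 3L)
  expect_equal(nrow(ens$metrics), 3L)
  expect_true(all(c("balanced_accuracy", "mcc", "mtry") %in%
                    colnames(ens$metrics)))
  # each member carries its own pipeline and dictionary
  expect_false(is.null(ens$members[[2]]$pipeline$kept))
  expect_false(is.null(ens$members[[2]]$dict))
  # refit with the same plan reproduces metrics exactly
  ens2 <- fit_small()
  expect_equal(ens$metrics, ens2$metrics)
  # single-repeat plan degenerates to one member
  plan1 <- build_plan(small_data$recs, n_repeats = 1, k = 4, seed = 3)
  ens1 <- ensemble_fit(small_data$recs, plan1, ntree = 100)
  expect_length(ens1$members, 1L)
})

test_that("consensus scoring, votes and ranking behave as documented", {
  ens <- fit_small()
  cands <- random_odns(80, 24, seed = 52, prefix = "CAND")
  pred <- ensemble_predict(ens, cands)
  expect_setequal(pred$id, cands$id)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_true(all(pred$votes >= 0 & pred$votes <= length(ens$members)))
  expect_equal(pred$label, ifelse(pred$score >= 0.5, "high", "low"))
  expect_equal(pred$rank, seq_len(nrow(pred)))
  expect_true(all(diff(pred$score) <= 0))
  # ranking is invariant to candidate input order
  pred_shuf <- ensemble_predict(ens, cands[withr::with_seed(1, sample(80)), ])
  expect_equal(pred_shuf, pred)
  # determinism given the fitted ensemble
  expect_equal(ensemble_predict(ens, cands), pred)
})

test_that("top-n selection is stable with deterministic tie-breaks", {
  ranked <- data.frame(id = sprintf("c%02d", 1:10),
                       sequence = random_odns(10, 8, 1)$sequence,
                       score = c(rep(0.9, 3), rep(0.5, 5), 0.4, 0.3),
                       votes = 1L, label = "high")
  ranked <- ranked[order(-ranked$score, ranked$id), ]
  ranked$rank <- 1:10
  expect_equal(nrow(select_top(ranked, 4)), 4L)
  expect_equal(select_top(ranked, 4)$id[4], "c04") # tie broken by id
  expect_equal(nrow(select_top(ranked, 0)), 0L)
  expect_error(select_top(ranked, 11), "exceeds")
})

test_that("shrinkage discriminant baseline separates Gaussian classes", {
  xy <- withr::with_seed(6, {
    x <- rbind(matrix(rnorm(200, mean = 1.5), 100, 2),
               matrix(rnorm(200, mean = -1.5), 100, 2))
    colnames(x) <- c("f1", "f2")
    rownames(x) <- sprintf("g%03d", 1:200)
    list(x = x, y = rep(c("high", "low"), each = 100))
  })
  fit <- train_baseline("sda", xy$x, xy$y, k = 4, seed = 6)
  prob <- predict(fit, xy$x)
  acc <- mean(ifelse(prob >= 0.5, "high", "low") == xy$y)
  expect_gt(acc, 0.9)
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("baseline families share the predict-probability contract", {
  recs <- small_data$recs
  dict <- build_dictionary(recs[recs$label == "high", ],
                           recs[recs$label == "low", ], 0.10)
  x <- predict(fit_feature_pipeline(featurize(recs, dict)),
               featurize(recs, dict))
  for (fam in c("gbm", "svm", "nn")) {
    fit <- train_baseline(fam, x, recs$label, k = 3, seed = 7)
    prob <- predict(fit, x)
    expect_length(prob, nrow(x))
    expect_true(all(prob >= 0 & prob <= 1), info = fam)
    cm <- confusion(ifelse(prob >= 0.5, "high", "low"), recs$label)
    expect_gt(classification_metrics(cm)[["balanced_accuracy"]], 0.7)
  }
  expect_error(train_baseline("knn", x, recs$label), "arg")
})
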