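test_that("near-zero-variance filter uses the sample SD", {
  x <- cbind(
    const = rep(1, 20),
    rare = c(1, rep(0, 19)),     # SD = sqrt(0.05*0.95*20/19) ~ 0.2236
    balanced = rep(c(0, 1), 10)  # SD ~ 0.5130
  )
  out <- nzv_filter(x, sd_threshold = 0.3)
  expect_setequal(out$dropped, c("const", "rare"))
  expect_equal(out$kept, "balanced")
  expect_equal(sd(x[, "rare"]), sqrt(0.05 * 0.95 * 20 / 19), tolerance = 1e-12)
  expect_error(nzv_filter(x[1, , drop = FALSE]), "2 rows")
})

test_that("linear-combination filter removes later dependent columns", {
  set.seed(8)
  a <- rnorm(30); b <- rnorm(30)
  x <- cbind(c1 = a, c2 = b, dup = a, sum = a + b, indep = rnorm(30))
  out <- lincomb_filter(x)
  expect_setequal(out$dropped, c("dup", "sum"))
  expect_equal(out$kept, c("c1", "c2", "indep"))

  # complementary binary columns are linearly dependent via the intercept
  z <- cbind(u = rep(c(0, 1), 10), v = rep(c(1, 0), 10))
  expect_equal(lincomb_filter(z)$dropped, "v")

  full <- matrix(rnorm(200), 20, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  expect_equal(lincomb_filter(full)$dropped, character(0))
  expect_equal(qr(cbind(1, full))$rank, 11L)
})

test_that("correlation filter drops the pair member with larger mean |r|", {
  set.seed(9)
  n <- 2000
  base <- rnorm(n)
  hub <- base + 0.2 * rnorm(n)
  x <- cbind(
    hub = hub,                       # correlated with twin AND side
    twin = base + 0.3 * rnorm(n),    # correlated with hub only
    side = 0.7 * hub + 0.6 * rnorm(n), # built from hub: leans on hub harder
    indep = rnorm(n)
  )
  r <- abs(cor(x)); diag(r) <- 0
  expect_gt(r["hub", "twin"], 0.85)
  expect_lt(r["hub", "side"], 0.85)
  expect_gt(mean(r["hub", -1]), mean(r["twin", -2])) # hub is the heavier member
  out <- correlation_filter(x, cutoff = 0.85)
  expect_equal(out$dropped, "hub")
  expect_setequal(out$kept, c("twin", "side", "indep"))

  dup <- cbind(a = base, b = base)
  expect_equal(length(correlation_filter(dup)$kept), 1L)
  weak <- cbind(a = base, b = 0.5 * base + rnorm(n))
  expect_equal(correlation_filter(weak)$dropped, character(0))
  expect_error(correlation_filter(cbind(a = rep(1, 10), b = rnorm(10))),
               "zero-variance")
})

test_that("centering and scaling applies stored training statistics", {
  x <- cbind(f = c(1, 2, 3))
  expect_equal(unname(center_scale(x)[, 1]), c(-1, 0, 1))

  train <- matrix(rnorm(60, mean = 5, sd = 2), 20, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  fit <- list(center = colMeans(train), scale = apply(train, 2, sd))
  expect_equal(center_scale(train, fit), center_scale(train),
               tolerance = 1e-12)
  # already standardized data are unchanged
  z <- center_scale(train)
  expect_equal(unname(center_scale(z)), unname(z), tolerance = 1e-10)
})

test_that("the fitted pipeline never uses test statistics", {
  recs <- assign_labels(simulate_odn_dataset(simulation_config(80, seed = 33)))
  dict <- build_dictionary(recs[recs$label == "high", ],
                           recs[recs$label == "low", ], 0.10)
  x <- featurize(recs, dict)
  fit <- fit_feature_pipeline(x[1:60, , drop = FALSE])
  refit <- fit_feature_pipeline(x[1:60, , drop = FALSE])
  expect_identical(fit, refit) # order-stable, deterministic

  test_x <- x[61:80, , drop = FALSE]
  out1 <- predict(fit, test_x)
  out2 <- predict(fit, test_x[sample(20), , drop = FALSE])
  expect_equal(out1[rownames(out2), ], out2[, ], tolerance = 1e-12)

  # retained columns satisfy the filter guarantees on the training data
  kept_train <- x[1:60, fit$kept, drop = FALSE]
  expect_true(all(apply(kept_train, 2, sd) >= fit$sd_threshold))
  numeric_kept <- setdiff(fit$kept, attr(x, "fingerprint_cols"))
  if (length(numeric_kept) >= 2) {
    r <- abs(cor(kept_train[, numeric_kept])); diag(r) <- 0
    expect_lte(max(r), fit$corr_cutoff + 1e-12)
  }
  # dropped sets are disjoint; scaling is positive
  drops <- c(fit$dropped_nzv, fit$dropped_lincomb, fit$dropped_corr)
  expect_equal(anyDuplicated(drops), 0L)
  expect_true(all(fit$scale > 0))
})

test_that("pipeline serialization round-trips exactly", {
  recs <- assign_labels(simulate_odn_dataset(simulation_config(60, seed = 34)))
  dict <- build_dictionary(recs[recs$label == "high", ],
                           recs[recs$label == "low", ], 0.10)
  x <- featurize(recs, dict)
  fit <- fit_feature_pipeline(x)
  path <- withr::local_tempfile()
  write_pipeline(fit, path)
  back <- read_pipeline(path)
  expect_equal(back$kept, fit$kept)
  expect_equal(back$center, fit$center)
  expect_equal(back$scale, fit$scale)
  expect_equal(predict(back, x), predict(fit, x))
})

test_that("the published 40-feature preset is exactly reproduced", {
  preset <- table3_preset()
  expect_length(preset, 40L)
  expect_equal(anyDuplicated(preset), 0L)
  expect_true(all(c("d_CG2_1", "GT18", "PMI1", "Mu_y", "TC9") %in% preset))
  expect_false("Rg" %in% preset)
  expect_equal(sum(grepl("^d_", preset)), 21L)
  # the preset names are a subset of featurize output when the matching
  # dictionary tokens exist
  recs <- toy_labelled(6, 6, seed = 35)
  dict <- data.frame(
    motif = c("CG", "GC", "GT", "GT", "GCG", "GT", "GT", "CGCG", "GC", "GT", "TC"),
    start = c(1L, 1L, 1L, 18L, 6L, 22L, 21L, 5L, 5L, 12L, 9L))
  dict$token <- paste0(dict$motif, dict$start)
  dict$rate_high <- 1; dict$rate_low <- 0
  class(dict) <- c("odn_dictionary", "data.frame")
  x <- featurize(recs, dict, motif_counts = FALSE)
  expect_true(all(preset %in% colnames(x)))
})
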