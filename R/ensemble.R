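# The random-forest ensemble: per-repeat training on balanced down-sampled
# instances with per-member feature pipelines, mtry tuning by stratified
# k-fold cross-validation, baseline learners for comparison, and consensus
# prediction / ranking of candidate ODNs.

# ---- single-member training ------------------------------------------------

# Cross-validated balanced accuracy of a fit/predict pair over given folds.
cv_balanced_accuracy <- function(x, y, folds, fit_fun, predict_fun) {
  bas <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- fit_fun(x[tr, , drop = FALSE], y[tr])
    pred <- predict_fun(fit, x[!tr, , drop = FALSE])
    cm <- confusion(ifelse(pred >= 0.5, "high", "low"),
                    as.character(y[!tr]))
    classification_metrics(cm)[["balanced_accuracy"]]
  }, numeric(1))
  mean(bas, na.rm = TRUE)
}

# Default mtry grid: {floor(sqrt(p)/2), floor(sqrt(p)), floor(2*sqrt(p))},
# deduplicated, clamped to [1, p].
default_mtry_grid <- function(p) {
  g <- unique(pmin(p, pmax(1L, floor(c(sqrt(p) / 2, sqrt(p), 2 * sqrt(p))))))
  sort(g)
}

#' Train one random-forest member with mtry tuning
#'
#' For each mtry candidate, the k-fold cross-validated balanced accuracy on
#' the training data is computed; the best candidate (ties resolved toward
#' the smaller mtry) is refit on the full training set with 500 trees.
#'
#' @param x numeric feature matrix (pipeline-transformed training data).
#' @param y factor or character labels over `c("high", "low")`.
#' @param mtry_grid integer candidates for mtry (default derived from the
#'   feature count).
#' @param k number of cross-validation folds (default 5).
#' @param seed integer seed governing fold assignment and forest growth.
#' @param ntree number of trees (default 500).
#' @param folds optional pre-computed named fold vector (overrides `k`).
#' @return object of class `odn_rf`: list with the fitted forest, selected
#'   `mtry`, the CV table, `seed` and `ntree`.
#' @export
train_rf <- function(x, y, mtry_grid = NULL, k = 5L, seed = 1L, ntree = 500L,
                     folds = NULL) {
  y <- factor(as.character(y), levels = c("high", "low"))
  if (nlevels(droplevels(y)) < 2L) abort("train_rf: training data has a single class")
  p <- ncol(x)
  if (is.null(mtry_grid)) mtry_grid <- default_mtry_grid(p)
  if (any(mtry_grid > p)) abort("train_rf: mtry exceeds feature count %d", p)
  if (is.null(folds)) {
    recs <- data.frame(id = rownames(x), label = as.character(y),
                       stringsAsFactors = FALSE)
    folds <- kfold(recs, k, seed)
  }
  folds <- unname(folds[rownames(x)])
  cv <- data.frame(mtry = mtry_grid, balanced_accuracy = NA_real_)
  for (i in seq_along(mtry_grid)) {
    m <- mtry_grid[i]
    cv$balanced_accuracy[i] <- cv_balanced_accuracy(
      x, y, folds,
      fit_fun = function(xt, yt) with_seed(seed, randomForest::randomForest(
        xt, yt, ntree = ntree, mtry = m)),
      predict_fun = function(fit, xv)
        predict(fit, xv, type = "prob")[, "high"]
    )
  }
  best <- cv$mtry[which.max(cv$balanced_accuracy)] # which.max -> first/smaller
  model <- with_seed(seed, randomForest::randomForest(
    x, y, ntree = ntree, mtry = best, importance = TRUE))
  structure(list(model = model, mtry = best, cv = cv, seed = seed,
                 ntree = ntree),
            class = "odn_rf")
}

#' @export
predict.odn_rf <- function(object, x, ...) {
  predict(object$model, x, type = "prob")[, "high"]
}

# ---- baseline learners -----------------------------------------------------

# Shrinkage discriminant analysis: linear discriminant with the pooled
# covariance shrunk toward its diagonal, Sigma(lambda) =
# (1-lambda) * S_pooled + lambda * diag(diag(S_pooled)). Equal priors.
fit_sda <- function(x, y, lambda) {
  cls <- levels(y)
  mus <- lapply(cls, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  centered <- x
  for (i in seq_along(cls)) {
    rows <- y == cls[i]
    centered[rows, ] <- sweep(x[rows, , drop = FALSE], 2, mus[[i]])
  }
  s <- crossprod(centered) / (nrow(x) - length(cls))
  sig <- (1 - lambda) * s + lambda * diag(diag(s), ncol(x))
  inv <- solve(sig + diag(1e-8, ncol(x)))
  list(mus = mus, inv = inv, cls = cls)
}

predict_sda <- function(fit, x) {
  # discriminant scores -> posterior probability of "high" via softmax
  d <- vapply(seq_along(fit$cls), function(i) {
    mu <- fit$mus[[i]]
    drop(x %*% (fit$inv %*% mu)) - 0.5 * drop(t(mu) %*% fit$inv %*% mu)
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  e <- exp(d - apply(d, 1, max))
  (e / rowSums(e))[, which(fit$cls == "high")]
}

#' Train a baseline learner with the shared CV protocol
#'
#' Supported families: `rf` (random forest, delegates to [train_rf()]),
#' `gbm` (gradient-boosted trees via xgboost), `sda` (shrinkage discriminant
#' analysis: linear discriminant with diagonally shrunken pooled covariance),
#' `svm` (RBF-kernel support vector machine via e1071) and `nn` (single
#' hidden-layer neural network via nnet). Each family tunes a small grid by
#' k-fold cross-validated balanced accuracy and exposes the same
#' predict-probability contract as the random forest.
#'
#' @param family one of `"rf"`, `"gbm"`, `"sda"`, `"svm"`, `"nn"`.
#' @param x numeric feature matrix.
#' @param y labels over `c("high", "low")`.
#' @param k CV folds (default 5).
#' @param seed integer seed.
#' @param folds optional pre-computed named fold vector.
#' @return object of class `odn_learner` with elements `family`, `fit`,
#'   `params`, `cv`.
#' @export
train_baseline <- function(family = c("rf", "gbm", "sda", "svm", "nn"),
                           x, y, k = 5L, seed = 1L, folds = NULL) {
  family <- match.arg(family)
  y <- factor(as.character(y), levels = c("high", "low"))
  if (nlevels(droplevels(y)) < 2L) abort("train_baseline: single-class data")
  if (family == "rf") {
    fit <- train_rf(x, y, k = k, seed = seed, folds = folds)
    return(structure(list(family = "rf", fit = fit,
                          params = list(mtry = fit$mtry), cv = fit$cv),
                     class = "odn_learner"))
  }
  if (is.null(folds)) {
    recs <- data.frame(id = rownames(x), label = as.character(y),
                       stringsAsFactors = FALSE)
    folds <- kfold(recs, k, seed)
  }
  folds <- unname(folds[rownames(x)])

  make_funs <- function(params) {
    switch(family,
      gbm = {
        if (!requireNamespace("xgboost", quietly = TRUE)) {
          abort("family 'gbm' requires the xgboost package")
        }
        list(
          fit = function(xt, yt) with_seed(seed, xgboost::xgb.train(
            params = list(objective = "binary:logistic",
                          max_depth = params$max_depth, eta = 0.1,
                          nthread = 1),
            data = xgboost::xgb.DMatrix(
              xt, label = as.numeric(yt == "high"), nthread = 1),
            nrounds = params$nrounds, verbose = 0)),
          pred = function(fit, xv)
            predict(fit, xgboost::xgb.DMatrix(xv, nthread = 1))
        )
      },
      sda = list(
        fit = function(xt, yt) fit_sda(xt, yt, params$lambda),
        pred = function(fit, xv) predict_sda(fit, xv)
      ),
      svm = {
        if (!requireNamespace("e1071", quietly = TRUE)) {
          abort("family 'svm' requires the e1071 package")
        }
        list(
          fit = function(xt, yt) with_seed(seed, e1071::svm(
            xt, yt, kernel = "radial", cost = params$cost,
            probability = TRUE, scale = FALSE)),
          pred = function(fit, xv) {
            attr(predict(fit, xv, probability = TRUE),
                 "probabilities")[, "high"]
          }
        )
      },
      nn = {
        if (!requireNamespace("nnet", quietly = TRUE)) {
          abort("family 'nn' requires the nnet package")
        }
        list(
          fit = function(xt, yt) with_seed(seed, nnet::nnet(
            xt, class.ind(yt), size = params$size, decay = 0.1,
            maxit = 200, softmax = TRUE, trace = FALSE)),
          pred = function(fit, xv) predict(fit, xv)[, "high"]
        )
      }
    )
  }
  grid <- switch(family,
    gbm = lapply(c(50L, 100L), function(n)
      list(nrounds = n, max_depth = 3L)),
    sda = lapply(c(0.1, 0.5, 0.9), function(l) list(lambda = l)),
    svm = lapply(c(0.25, 1, 4), function(cst) list(cost = cst)),
    nn = lapply(c(1L, 3L, 5L), function(s) list(size = s))
  )
  scores <- vapply(grid, function(params) {
    funs <- make_funs(params)
    cv_balanced_accuracy(x, y, folds, funs$fit, funs$pred)
  }, numeric(1))
  best <- grid[[which.max(scores)]]
  funs <- make_funs(best)
  structure(list(family = family, fit = funs$fit(x, y), params = best,
                 cv = data.frame(candidate = seq_along(grid),
                                 balanced_accuracy = scores),
                 .pred = funs$pred),
            class = "odn_learner")
}

# one-hot class indicator for nnet's softmax interface
class.ind <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' @export
predict.odn_learner <- function(object, x, ...) {
  if (object$family == "rf") return(predict(object$fit, x))
  object$.pred(object$fit, x)
}

# ---- ensemble --------------------------------------------------------------

#' Fit the ensemble of random-forest members over a split plan
#'
#' One member per plan repeat. Each member builds its fingerprint dictionary
#' from its own training records (leakage control; set `global_dictionary = TRUE`
#' to build one global dictionary from all labelled records first), fits its
#' own feature pipeline on its training data, tunes mtry by cross-validation
#' on the plan's folds, and is evaluated on its held-out test set.
#'
#' @param records labelled ODN record data.frame (the full data set).
#' @param plan a `split_plan` from [build_plan()].
#' @param dict_threshold fingerprint dictionary rate-difference threshold
#'   (default 0.10).
#' @param distance_motifs motifs for the count/distance descriptor block.
#'   The default `NULL` selects each member's motifs from its own training
#'   split ([select_distance_motifs()], top 7 by group occurrence
#'   difference); pass [default_distance_motifs()] for the fixed published
#'   preset.
#' @param sd_threshold,corr_cutoff feature-pipeline thresholds.
#' @param mtry_grid optional mtry candidates.
#' @param ntree trees per forest (default 500).
#' @param global_dictionary build a single dictionary from all labelled
#'   records instead of per-member training data (default FALSE).
#' @param consensus_rule `"mean_probability"` (default) or `"majority_vote"`.
#' @param threshold consensus decision threshold (default 0.5; a score
#'   exactly at the threshold is called high).
#' @return object of class `odn_ensemble`: `members` (each with `dict`,
#'   `motifs`, `pipeline`, `model`, `seed`, test ids), `metrics` (per-repeat
#'   held-out metrics data.frame), `consensus_rule`, `threshold`.
#' @export
ensemble_fit <- function(records, plan, dict_threshold = 0.10,
                         distance_motifs = NULL,
                         sd_threshold = 0.3, corr_cutoff = 0.85,
                         mtry_grid = NULL, ntree = 500L,
                         global_dictionary = FALSE,
                         consensus_rule = c("mean_probability", "majority_vote"),
                         threshold = 0.5) {
  consensus_rule <- match.arg(consensus_rule)
  rownames(records) <- records$id
  global <- NULL
  if (global_dictionary) {
    global <- build_dictionary(records[records$label == "high", ],
                               records[records$label == "low", ],
                               dict_threshold)
  }
  members <- vector("list", length(plan))
  metrics <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    rep_i <- plan[[i]]
    train <- records[rep_i$train, , drop = FALSE]
    test <- records[rep_i$test, , drop = FALSE]
    tr_high <- train[train$label == "high", ]
    tr_low <- train[train$label == "low", ]
    dict <- if (global_dictionary) global else
      build_dictionary(tr_high, tr_low, dict_threshold)
    motifs <- if (is.null(distance_motifs)) {
      select_distance_motifs(tr_high, tr_low)
    } else distance_motifs
    x_train <- featurize(train, dict, motifs)
    pipe <- fit_feature_pipeline(x_train, sd_threshold, corr_cutoff)
    xt <- predict(pipe, x_train)
    rf <- train_rf(xt, train$label, mtry_grid = mtry_grid,
                   seed = rep_i$seed, ntree = ntree, folds = rep_i$folds)
    x_test <- predict(pipe, featurize(test, dict, motifs))
    prob <- predict(rf, x_test)
    cm <- confusion(ifelse(prob >= threshold, "high", "low"), test$label)
    met <- classification_metrics(cm)
    members[[i]] <- list(dict = dict, motifs = motifs, pipeline = pipe,
                         model = rf, seed = rep_i$seed, test = rep_i$test)
    metrics[[i]] <- data.frame(
      repeat_index = i, family = "rf", k = attr(plan, "k"),
      mtry = rf$mtry,
      sensitivity = met[["sensitivity"]], specificity = met[["specificity"]],
      balanced_accuracy = met[["balanced_accuracy"]], mcc = met[["mcc"]],
      precision = met[["precision"]]
    )
  }
  structure(list(members = members, metrics = do.call(rbind, metrics),
                 consensus_rule = consensus_rule, threshold = threshold),
            class = "odn_ensemble")
}

#' Consensus prediction and ranking of candidate ODNs
#'
#' Each member scores every candidate with its own dictionary and pipeline;
#' the consensus score is the mean of the members' high-class probabilities
#' (or the vote fraction under `majority_vote`). A candidate is called high
#' when its score is at or above the ensemble threshold. Candidates are
#' ranked by descending score with ties broken by id, so the ranking is
#' independent of input order.
#'
#' @param ensemble an `odn_ensemble`.
#' @param candidates ODN record data.frame (activity not required).
#' @return data.frame `id`, `sequence`, `score`, `votes`, `label`, `rank`,
#'   ordered by rank.
#' @export
ensemble_predict <- function(ensemble, candidates) {
  candidates <- odn_records(candidates$id, candidates$sequence,
                            candidates$activity, candidates$label)
  # motif blocks and base descriptors depend only on the candidates, so they
  # are computed once and reused across members
  base <- base_descriptors(candidates)
  all_motifs <- unique(unlist(lapply(ensemble$members, `[[`, "motifs")))
  blocks <- lapply(all_motifs, function(m) motif_block(candidates, m))
  names(blocks) <- all_motifs
  probs <- vapply(ensemble$members, function(mem) {
    x <- do.call(cbind, c(
      list(base[, c("A", "T", "G", "C"), drop = FALSE]),
      blocks[mem$motifs],
      list(base[, c("PMI1", "PMI2", "Mu_x", "Mu_y", "Rg"), drop = FALSE]),
      list(fingerprint_matrix(candidates, mem$dict))
    ))
    predict(mem$model, predict(mem$pipeline, x))
  }, numeric(nrow(candidates)))
  probs <- matrix(probs, nrow = nrow(candidates))
  votes <- rowSums(probs >= ensemble$threshold)
  score <- if (ensemble$consensus_rule == "mean_probability") {
    rowMeans(probs)
  } else {
    votes / length(ensemble$members)
  }
  out <- data.frame(
    id = candidates$id, sequence = candidates$sequence,
    score = score, votes = as.integer(votes),
    label = ifelse(score >= ensemble$threshold, "high", "low"),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$score, out$id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select the top-ranked candidates
#'
#' @param ranked prediction data.frame from [ensemble_predict()].
#' @param n number of candidates to keep (default 100).
#' @return the first `n` rows by rank.
#' @export
select_top <- function(ranked, n = 100L) {
  if (n > nrow(ranked)) abort("select_top: n = %d exceeds %d candidates",
                              n, nrow(ranked))
  head(ranked[order(ranked$rank), , drop = FALSE], n)
}

#' Fold enrichment of motifs in a selection versus a candidate pool
#'
#' For each motif, the prevalence (fraction of ODNs containing it, position
#' free) is computed in the selected set and in the full pool; the fold
#' enrichment is their ratio. The summary `mean_fold` averages the per-motif
#' folds.
#'
#' @param selected,pool ODN record data.frames (selection a subset of pool).
#' @param motifs character vector of motifs.
#' @return list with `table` (motif, rate_selected, rate_pool, fold) and
#'   `mean_fold`.
#' @export
screen_enrichment <- function(selected, pool, motifs) {
  prevalence <- function(recs, m) mean(grepl(m, recs$sequence, fixed = TRUE))
  tab <- data.frame(
    motif = motifs,
    rate_selected = vapply(motifs, function(m) prevalence(selected, m),
                           numeric(1)),
    rate_pool = vapply(motifs, function(m) prevalence(pool, m), numeric(1))
  )
  tab$fold <- ifelse(tab$rate_pool > 0, tab$rate_selected / tab$rate_pool, NA)
  list(table = tab, mean_fold = mean(tab$fold, na.rm = TRUE))
}

#' Write ensemble predictions as delimited text
#'
#' @param predictions data.frame from [ensemble_predict()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
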