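# Deterministic construction of balanced down-sampled instances, stratified
# train/test splits, stratified k-fold partitions, and the repeated-instance
# experimental plan. Every random draw is seeded, and per-repeat seeds are
# derived from the master seed so any single repeat is reproducible alone.

#' Balance classes by down-sampling the majority class
#'
#' The minority class is kept whole; the majority class is subsampled without
#' replacement to the minority size with a seeded uniform draw, so the result
#' is 50/50.
#'
#' @param records labelled ODN record data.frame (both classes present).
#' @param seed integer seed.
#' @return record data.frame with equal class counts (original row order).
#' @export
down_sample <- function(records, seed) {
  counts <- label_counts(records)
  if (any(counts == 0L)) abort("down_sample: a class is empty")
  n_min <- min(counts)
  minority <- names(counts)[which.min(counts)]
  keep <- records$label == minority
  maj_idx <- which(!keep)
  sel <- maj_idx[with_seed(seed, sample.int(length(maj_idx), n_min))]
  keep[sort(sel)] <- TRUE
  records[keep, , drop = FALSE]
}

#' Stratified train/test split
#'
#' Within each class, `floor(train_fraction * n + 0.5)` records (rounding to
#' the nearest integer) are drawn into the training set and the rest form the
#' test set.
#'
#' @param records labelled ODN record data.frame.
#' @param train_fraction fraction of each class for training (default 0.8).
#' @param seed integer seed.
#' @return list with record data.frames `train` and `test`.
#' @export
stratified_split <- function(records, train_fraction = 0.8, seed) {
  counts <- label_counts(records)
  if (any(counts < 2L)) abort("stratified_split: a class has < 2 members")
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in c("high", "low")) {
      idx <- which(records$label == cl)
      n_train <- floor(train_fraction * length(idx) + 0.5)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  list(train = records[train_idx, , drop = FALSE],
       test = records[-train_idx, , drop = FALSE])
}

#' Stratified k-fold assignment
#'
#' Assigns each record to one of k cross-validation folds, stratified by
#' class; within each class the fold sizes differ by at most one.
#'
#' @param records labelled ODN record data.frame.
#' @param k number of folds (must not exceed the smaller class size).
#' @param seed integer seed.
#' @return named integer vector of fold numbers (1..k), names = record ids.
#' @export
kfold <- function(records, k, seed) {
  counts <- label_counts(records)
  if (k > min(counts)) abort("kfold: k = %d exceeds smallest class size %d",
                             k, min(counts))
  folds <- integer(nrow(records))
  with_seed(seed, {
    for (cl in c("high", "low")) {
      idx <- which(records$label == cl)
      folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
  })
  stats::setNames(folds, records$id)
}

#' Build the repeated down-sampling experimental plan
#'
#' Each repeat draws its own balanced instance (down-sampling the majority
#' class anew), splits it into stratified train/test sets, and assigns
#' stratified k-fold cross-validation folds to the training set. The seed of
#' repeat i is `seed + i`.
#'
#' @param records labelled ODN record data.frame.
#' @param n_repeats number of down-sampled instances (default 20).
#' @param train_fraction per-class training fraction (default 0.8).
#' @param k number of cross-validation folds (default 20).
#' @param seed master integer seed.
#' @return object of class `split_plan`: list of repeats, each with `seed`,
#'   `train` (ids), `test` (ids) and `folds` (named fold vector); attributes
#'   carry the parameters.
#' @export
build_plan <- function(records, n_repeats = 20L, train_fraction = 0.8,
                       k = 20L, seed = 1L) {
  repeats <- lapply(seq_len(n_repeats), function(i) {
    s <- as.integer(seed) + i
    balanced <- down_sample(records, s)
    sp <- stratified_split(balanced, train_fraction, s)
    folds <- kfold(sp$train, k, s)
    list(seed = s, train = sp$train$id, test = sp$test$id, folds = folds)
  })
  structure(repeats, class = "split_plan",
            seed = as.integer(seed), n_repeats = as.integer(n_repeats),
            train_fraction = train_fraction, k = as.integer(k))
}

#' Serialize / restore a split plan as delimited text
#'
#' One row per record membership: repeat index, repeat seed, record id, role
#' (train/test) and fold (NA for test records).
#'
#' @param plan a `split_plan`.
#' @param path file path.
#' @return `path` (write) or the plan (read).
#' @export
write_plan <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_along(plan), function(i) {
    r <- plan[[i]]
    rbind(
      data.frame(repeat_index = i, seed = r$seed, id = r$train,
                 role = "train", fold = unname(r$folds[r$train])),
      data.frame(repeat_index = i, seed = r$seed, id = r$test,
                 role = "test", fold = NA_integer_)
    )
  }))
  hdr <- sprintf("# split_plan seed=%d n_repeats=%d train_fraction=%.17g k=%d",
                 attr(plan, "seed"), attr(plan, "n_repeats"),
                 attr(plan, "train_fraction"), attr(plan, "k"))
  writeLines(hdr, path)
  suppressWarnings(write.table(rows, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  hdr <- readLines(path, n = 1L)
  parse_kv <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  rows <- read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  repeats <- lapply(sort(unique(rows$repeat_index)), function(i) {
    ri <- rows[rows$repeat_index == i, ]
    tr <- ri[ri$role == "train", ]
    list(seed = ri$seed[1], train = tr$id,
         test = ri$id[ri$role == "test"],
         folds = stats::setNames(as.integer(tr$fold), tr$id))
  })
  structure(repeats, class = "split_plan",
            seed = as.integer(parse_kv("seed")),
            n_repeats = as.integer(parse_kv("n_repeats")),
            train_fraction = parse_kv("train_fraction"),
            k = as.integer(parse_kv("k")))
}
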