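# Feature filtering and normalization: near-zero variance, linear
# combinations, pairwise correlation, centering/scaling. The pipeline is fit
# on training data only and applied unchanged to test or screening data.

#' Near-zero-variance filter
#'
#' Drops columns whose sample standard deviation (denominator n - 1) is below
#' the threshold; constant columns have SD 0 and always go.
#'
#' @param x numeric matrix with >= 2 rows.
#' @param sd_threshold minimum SD to keep a column (default 0.3).
#' @return list with character vectors `kept` and `dropped`.
#' @export
nzv_filter <- function(x, sd_threshold = 0.3) {
  if (nrow(x) < 2L) abort("nzv_filter: need at least 2 rows")
  s <- apply(x, 2, sd)
  list(kept = colnames(x)[s >= sd_threshold],
       dropped = colnames(x)[s < sd_threshold])
}

#' Linear-combination filter
#'
#' Removes later-ordered columns that are exact linear combinations of
#' earlier ones (an implicit intercept is included, so complementary binary
#' columns are also caught). A greedy forward pass adds each column in order
#' and keeps it only if it raises the rank of the QR decomposition
#' (tolerance 1e-8).
#'
#' @param x numeric matrix.
#' @param tol rank tolerance.
#' @return list with character vectors `kept` and `dropped`.
#' @export
lincomb_filter <- function(x, tol = 1e-8) {
  kept <- character(0)
  dropped <- character(0)
  basis <- matrix(1, nrow(x), 1) # intercept
  rank <- 1L
  for (cn in colnames(x)) {
    cand <- cbind(basis, x[, cn])
    r <- qr(cand, tol = tol)$rank
    if (r > rank) {
      basis <- cand
      rank <- r
      kept <- c(kept, cn)
    } else {
      dropped <- c(dropped, cn)
    }
  }
  list(kept = kept, dropped = dropped)
}

#' Pairwise-correlation filter
#'
#' While any column pair has |Pearson r| above the cutoff, the member of the
#' most-correlated pair with the larger mean absolute correlation to all
#' remaining columns is removed (ties broken toward the later column).
#'
#' @param x numeric matrix with >= 3 rows and no zero-variance columns.
#' @param cutoff correlation cutoff; removal requires strictly greater
#'   (default 0.85).
#' @return list with character vectors `kept` and `dropped`.
#' @export
correlation_filter <- function(x, cutoff = 0.85) {
  if (nrow(x) < 3L) abort("correlation_filter: need at least 3 rows")
  if (any(apply(x, 2, sd) == 0)) {
    abort("correlation_filter: zero-variance column present")
  }
  dropped <- character(0)
  cols <- colnames(x)
  while (length(cols) >= 2L) {
    r <- abs(cor(x[, cols, drop = FALSE]))
    diag(r) <- 0
    if (max(r) <= cutoff) break
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    meanabs <- rowMeans(r)
    i <- worst[["row"]]; j <- worst[["col"]]
    # remove the pair member with larger mean |r|; tie -> later column
    drop_idx <- if (meanabs[i] > meanabs[j]) i
                else if (meanabs[j] > meanabs[i]) j
                else max(i, j)
    dropped <- c(dropped, cols[drop_idx])
    cols <- cols[-drop_idx]
  }
  list(kept = cols, dropped = dropped)
}

#' Center and scale a feature matrix
#'
#' Subtracts per-column means and divides by per-column sample SDs. When a
#' fitted pipeline is supplied, its stored training means/SDs are applied and
#' the data are never refit.
#'
#' @param x numeric matrix.
#' @param fit optional `odn_pipeline` holding `center`/`scale` vectors.
#' @return scaled matrix with the same dimnames.
#' @export
center_scale <- function(x, fit = NULL) {
  if (is.null(fit)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
  } else {
    if (!all(colnames(x) == names(fit$center))) {
      abort("center_scale: column names do not match the fitted pipeline")
    }
    ctr <- fit$center
    scl <- fit$scale
  }
  if (any(scl == 0)) abort("center_scale: zero-SD column '%s'",
                           colnames(x)[which(scl == 0)[1]])
  scale(x, center = ctr, scale = scl)[, , drop = FALSE]
}

#' Fit the full feature-selection pipeline
#'
#' In order: (1) near-zero-variance removal on all columns; (2) removal of
#' exact linear combinations among the surviving binary fingerprint columns;
#' (3) pairwise-correlation filtering among the surviving numeric columns
#' (optionally extended to fingerprints); (4) centering and scaling of
#' everything retained.
#'
#' @param x feature matrix from [featurize()] (its `fingerprint_cols`
#'   attribute identifies the binary block; override via `fingerprint_cols`).
#' @param sd_threshold near-zero-variance SD threshold (default 0.3).
#' @param corr_cutoff correlation cutoff (default 0.85).
#' @param fingerprint_cols names of binary fingerprint columns.
#' @param corr_on_fingerprints also correlation-filter the binary block
#'   (default FALSE: fingerprints see only the NZV and linear-combination
#'   filters).
#' @return object of class `odn_pipeline`: list with `kept` (final column
#'   order), `dropped_nzv`, `dropped_lincomb`, `dropped_corr`, `center`,
#'   `scale`, and the thresholds.
#' @export
fit_feature_pipeline <- function(x, sd_threshold = 0.3, corr_cutoff = 0.85,
                                 fingerprint_cols = attr(x, "fingerprint_cols"),
                                 corr_on_fingerprints = FALSE) {
  if (is.null(fingerprint_cols)) fingerprint_cols <- character(0)
  nzv <- nzv_filter(x, sd_threshold)
  fp_cols <- intersect(nzv$kept, fingerprint_cols)
  num_cols <- setdiff(nzv$kept, fingerprint_cols)

  lc <- if (length(fp_cols)) lincomb_filter(x[, fp_cols, drop = FALSE])
        else list(kept = character(0), dropped = character(0))

  corr_cols <- if (corr_on_fingerprints) c(num_cols, lc$kept) else num_cols
  cr <- if (length(corr_cols) >= 2L) {
    correlation_filter(x[, corr_cols, drop = FALSE], corr_cutoff)
  } else list(kept = corr_cols, dropped = character(0))

  kept <- intersect(colnames(x), union(cr$kept, setdiff(lc$kept, cr$dropped)))
  xs <- x[, kept, drop = FALSE]
  fit <- list(
    kept = kept,
    dropped_nzv = nzv$dropped,
    dropped_lincomb = lc$dropped,
    dropped_corr = cr$dropped,
    center = colMeans(xs),
    scale = apply(xs, 2, sd),
    sd_threshold = sd_threshold,
    corr_cutoff = corr_cutoff
  )
  class(fit) <- "odn_pipeline"
  fit
}

#' Apply a fitted pipeline to new data
#'
#' @param object an `odn_pipeline`.
#' @param x feature matrix containing at least the retained columns.
#' @param ... unused.
#' @return scaled matrix restricted to the retained columns, using the
#'   training means and SDs.
#' @export
predict.odn_pipeline <- function(object, x, ...) {
  missing_cols <- setdiff(object$kept, colnames(x))
  if (length(missing_cols)) {
    abort("pipeline: matrix lacks column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  center_scale(x[, object$kept, drop = FALSE], object)
}

#' Serialize / restore a fitted pipeline as structured text
#'
#' @param fit an `odn_pipeline`.
#' @param path file path.
#' @return `path` (write) or the pipeline (read).
#' @export
write_pipeline <- function(fit, path) {
  lines <- c(
    sprintf("sd_threshold\t%.17g", fit$sd_threshold),
    sprintf("corr_cutoff\t%.17g", fit$corr_cutoff),
    sprintf("dropped_nzv\t%s", paste(fit$dropped_nzv, collapse = ",")),
    sprintf("dropped_lincomb\t%s", paste(fit$dropped_lincomb, collapse = ",")),
    sprintf("dropped_corr\t%s", paste(fit$dropped_corr, collapse = ",")),
    vapply(seq_along(fit$kept), function(i) {
      sprintf("column\t%s\t%.17g\t%.17g",
              fit$kept[i], fit$center[i], fit$scale[i])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pipeline
#' @export
read_pipeline <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[`, character(1), 1)
  getval <- function(k) fields[[which(key == k)[1]]][2]
  split_csv <- function(v) if (is.na(v) || !nzchar(v)) character(0)
                           else strsplit(v, ",", fixed = TRUE)[[1]]
  colrows <- fields[key == "column"]
  kept <- vapply(colrows, `[`, character(1), 2)
  fit <- list(
    kept = kept,
    dropped_nzv = split_csv(getval("dropped_nzv")),
    dropped_lincomb = split_csv(getval("dropped_lincomb")),
    dropped_corr = split_csv(getval("dropped_corr")),
    center = stats::setNames(as.numeric(vapply(colrows, `[`, character(1), 3)), kept),
    scale = stats::setNames(as.numeric(vapply(colrows, `[`, character(1), 4)), kept),
    sd_threshold = as.numeric(getval("sd_threshold")),
    corr_cutoff = as.numeric(getval("corr_cutoff"))
  )
  class(fit) <- "odn_pipeline"
  fit
}

#' The published 40-feature preset
#'
#' The fixed feature list used by the reference model: 4 nucleotide counts,
#' 21 motif-distance descriptors (CG, AG, GG, CC, TCT, TTC, TGT), 4 graph
#' features (PMI1, PMI2, Mu_x, Mu_y; the radius of gyration is not part of
#' the preset), and 11 positional fingerprint bits.
#'
#' @return ordered character vector of 40 feature names.
#' @export
table3_preset <- function() {
  c(
    "A", "T", "G", "C",
    as.vector(vapply(default_distance_motifs(),
                     function(m) paste0("d_", m, c("2_1", "3_1", "3_2")),
                     character(3))),
    "PMI1", "PMI2", "Mu_x", "Mu_y",
    "CG1", "GC1", "GT1", "GT18", "GCG6", "GT22", "GT21",
    "CGCG5", "GC5", "GT12", "TC9"
  )
}
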