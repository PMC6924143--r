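# Position-free motif enrichment between activity groups, and Mann-Whitney
# tests of the effect of motif presence on the activity score within a group.
# Motifs here are substrings regardless of position (contrast with the
# positional fingerprint dictionary).

# All distinct position-free motifs of length min_len..max_len in a record set.
all_motifs <- function(records, min_len = 2L, max_len = 6L) {
  sort(unique(unlist(lapply(records$sequence, function(s)
    unique(enumerate_motifs(s, min_len, max_len)$motif)), use.names = FALSE)))
}

# Fraction of records containing a motif anywhere (counted once per ODN).
motif_prevalence <- function(records, motif) {
  mean(grepl(motif, records$sequence, fixed = TRUE))
}

#' Occurrence-rate differences of motifs between activity groups
#'
#' For every position-free motif observed in either group, computes the
#' percentage of ODNs containing it in the high and low groups and the
#' absolute difference in percentage points, ranked descending. The top rows
#' give the most group-discriminating motifs; rows with difference of at
#' least 10 points form the classical enriched subset.
#'
#' @param high,low ODN record data.frames.
#' @param min_len,max_len motif length bounds (defaults 2 and 6).
#' @return data.frame `motif`, `pct_high`, `pct_low`, `abs_diff` (percentage
#'   points), ordered by descending `abs_diff` then motif.
#' @export
group_occurrence_diff <- function(high, low, min_len = 2L, max_len = 6L) {
  if (nrow(high) == 0L || nrow(low) == 0L) {
    abort("group_occurrence_diff: both groups must be non-empty")
  }
  motifs <- union(all_motifs(high, min_len, max_len),
                  all_motifs(low, min_len, max_len))
  ph <- vapply(motifs, function(m) motif_prevalence(high, m), numeric(1))
  pl <- vapply(motifs, function(m) motif_prevalence(low, m), numeric(1))
  out <- data.frame(motif = motifs, pct_high = 100 * ph, pct_low = 100 * pl,
                    abs_diff = 100 * abs(ph - pl), stringsAsFactors = FALSE)
  out <- out[order(-out$abs_diff, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact two-sided Mann-Whitney p by full enumeration is delegated to
# stats::wilcox.test; this helper decides the variant: exact when the
# smaller sample has at most `exact_limit` observations and there are no
# ties, otherwise the normal approximation with tie and continuity
# correction.
mw_test <- function(a, b, exact_limit = 8L) {
  no_ties <- !anyDuplicated(c(a, b))
  use_exact <- min(length(a), length(b)) <= exact_limit && no_ties
  suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                correct = TRUE)
  )$p.value
}

#' Mann-Whitney test of a motif's effect on activity within a group
#'
#' Splits one activity group into ODNs with and without the motif (position
#' free) and compares their activity scores with a two-sided Mann-Whitney U
#' test; the test is exact when the smaller subset has at most 8 ODNs and
#' the scores are tie-free, otherwise the normal approximation with tie and
#' continuity correction is used. The direction is read from the medians.
#'
#' @param records ODN record data.frame of one activity group, with activity.
#' @param motif motif string.
#' @param alpha significance threshold (default 0.05).
#' @return one-row data.frame: `motif`, `n_with`, `n_without`, `median_with`,
#'   `median_without`, `direction` (`increase`/`decrease`/`none`), `p_value`,
#'   `significant`. When a subset is empty the effect is undefined: medians
#'   and p are `NA`, direction `"none"`, `significant` `FALSE`.
#' @export
mann_whitney_effect <- function(records, motif, alpha = 0.05) {
  if (anyNA(records$activity)) abort("mann_whitney_effect: missing activity")
  has <- grepl(motif, records$sequence, fixed = TRUE)
  a <- records$activity[has]
  b <- records$activity[!has]
  if (length(a) == 0L || length(b) == 0L) {
    return(data.frame(motif = motif, n_with = length(a),
                      n_without = length(b), median_with = NA_real_,
                      median_without = NA_real_, direction = "none",
                      p_value = NA_real_, significant = FALSE,
                      stringsAsFactors = FALSE))
  }
  p <- mw_test(a, b)
  ma <- median(a); mb <- median(b)
  direction <- if (ma > mb) "increase" else if (ma < mb) "decrease" else "none"
  data.frame(motif = motif, n_with = length(a), n_without = length(b),
             median_with = ma, median_without = mb, direction = direction,
             p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
}

#' Motif-effect table for one activity group
#'
#' Runs [mann_whitney_effect()] for every motif (by default all position-free
#' motifs of length 2-6 present in, but not ubiquitous in, the group) and
#' returns the combined table. Raw p values are reported; an optional
#' Benjamini-Hochberg adjusted column can be added for convenience.
#'
#' @param records ODN record data.frame of one activity group.
#' @param motifs motifs to test (default: all informative motifs).
#' @param min_len,max_len motif length bounds for the default motif set.
#' @param alpha significance threshold (default 0.05).
#' @param bh add a `p_adjusted` Benjamini-Hochberg column (default FALSE).
#' @return data.frame, one row per motif, ordered alphabetically by motif.
#' @export
motif_effect_table <- function(records, motifs = NULL, min_len = 2L,
                               max_len = 6L, alpha = 0.05, bh = FALSE) {
  if (is.null(motifs)) {
    motifs <- all_motifs(records, min_len, max_len)
    keep <- vapply(motifs, function(m) {
      prev <- motif_prevalence(records, m)
      prev > 0 && prev < 1
    }, logical(1))
    motifs <- motifs[keep]
  }
  out <- do.call(rbind, lapply(motifs, function(m)
    mann_whitney_effect(records, m, alpha)))
  out <- out[order(out$motif), , drop = FALSE]
  if (bh) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
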