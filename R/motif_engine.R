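# Positional motif enumeration, fingerprint dictionaries, binary fingerprints
# and fingerprint-similarity deduplication.
#
# A positional motif token is a (motif, start) pair with 1-based start; its
# name concatenates the two, e.g. "CG1" is CG starting at position 1. Tokens
# of length 2..6 nucleotides are enumerated by exhaustive chopping.

#' Enumerate positional motif tokens of a sequence
#'
#' Chops the sequence into every substring of length `min_len` to `max_len`
#' and records the 1-based start position of each. Overlapping occurrences
#' are all reported. For example `"TCG"` yields TC\@1, CG\@2 and TCG\@1.
#'
#' @param sequence DNA string.
#' @param min_len,max_len motif length bounds (defaults 2 and 6).
#' @return data.frame with columns `motif`, `start` (integer) and `token`
#'   (the `"<MOTIF><START>"` name). Zero rows when the sequence is shorter
#'   than `min_len`.
#' @export
enumerate_motifs <- function(sequence, min_len = 2L, max_len = 6L) {
  L <- nchar(sequence)
  out <- vector("list", max(0L, max_len - min_len + 1L))
  j <- 0L
  for (k in seq(min_len, max_len)) {
    if (L < k) break
    starts <- seq_len(L - k + 1L)
    j <- j + 1L
    out[[j]] <- data.frame(
      motif = substring(sequence, starts, starts + k - 1L),
      start = starts, stringsAsFactors = FALSE
    )
  }
  res <- if (j) do.call(rbind, out[seq_len(j)]) else
    data.frame(motif = character(0), start = integer(0))
  res$token <- paste0(res$motif, res$start)
  res
}

# Unique token set per record, as a list of character vectors.
token_sets <- function(records, min_len = 2L, max_len = 6L) {
  lapply(records$sequence, function(s)
    unique(enumerate_motifs(s, min_len, max_len)$token))
}

#' Per-group occurrence rate of positional tokens
#'
#' The rate of a token in a group is the fraction of ODNs in the group that
#' contain it at its exact position; multiple occurrences within one ODN
#' count once.
#'
#' @param records ODN record data.frame (the group; must be non-empty).
#' @param min_len,max_len motif length bounds.
#' @return named numeric vector of rates in \[0, 1\], one entry per token
#'   observed in the group.
#' @export
occurrence_rate <- function(records, min_len = 2L, max_len = 6L) {
  if (nrow(records) == 0L) abort("occurrence_rate: empty group")
  tok <- unlist(token_sets(records, min_len, max_len), use.names = FALSE)
  counts <- table(tok)
  stats::setNames(as.numeric(counts) / nrow(records), names(counts))
}

#' Build a positional fingerprint dictionary
#'
#' Collects every positional token observed in either activity group and
#' retains those whose occurrence rates in the high and low groups differ by
#' at least `threshold` (absolute difference of fractions, inclusive).
#' Tokens are ordered by descending absolute difference, then by motif and
#' start, so the dictionary (and hence fingerprint bit order) is stable.
#'
#' @param high,low ODN record data.frames for the two activity groups.
#' @param threshold minimum absolute rate difference (default 0.10).
#' @param min_len,max_len motif length bounds.
#' @return object of class `odn_dictionary`: a data.frame with columns
#'   `motif`, `start`, `token`, `rate_high`, `rate_low`, and attribute
#'   `threshold`.
#' @export
build_dictionary <- function(high, low, threshold = 0.10,
                             min_len = 2L, max_len = 6L) {
  if (nrow(high) == 0L || nrow(low) == 0L) {
    abort("build_dictionary: both groups must be non-empty")
  }
  rh <- occurrence_rate(high, min_len, max_len)
  rl <- occurrence_rate(low, min_len, max_len)
  tokens <- union(names(rh), names(rl))
  rate_high <- ifelse(tokens %in% names(rh), rh[tokens], 0)
  rate_low <- ifelse(tokens %in% names(rl), rl[tokens], 0)
  diff <- abs(rate_high - rate_low)
  keep <- diff >= threshold - 1e-12
  d <- data.frame(
    motif = sub("[0-9]+$", "", tokens[keep]),
    start = as.integer(sub("^[A-Z]+", "", tokens[keep])),
    token = tokens[keep],
    rate_high = unname(rate_high[keep]),
    rate_low = unname(rate_low[keep]),
    stringsAsFactors = FALSE
  )
  d <- d[order(-abs(d$rate_high - d$rate_low), d$motif, d$start), ,
         drop = FALSE]
  rownames(d) <- NULL
  attr(d, "threshold") <- threshold
  class(d) <- c("odn_dictionary", "data.frame")
  d
}

#' Write / read a fingerprint dictionary as delimited text
#'
#' @param dict an `odn_dictionary`.
#' @param path file path.
#' @return `path` (write) or the dictionary (read).
#' @export
write_dictionary <- function(dict, path) {
  write.table(as.data.frame(dict)[, c("motif", "start", "rate_high", "rate_low")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$token <- paste0(d$motif, d$start)
  d <- d[, c("motif", "start", "token", "rate_high", "rate_low")]
  class(d) <- c("odn_dictionary", "data.frame")
  d
}

#' Encode the binary fingerprint of one sequence
#'
#' Bit i is 1 exactly when dictionary token i occurs in the sequence at its
#' stored start position; sequences too short for a token simply get 0.
#'
#' @param sequence DNA string.
#' @param dict an `odn_dictionary`.
#' @return named integer vector of 0/1 bits in dictionary order.
#' @export
encode_fingerprint <- function(sequence, dict) {
  if (nrow(dict) == 0L) return(stats::setNames(integer(0), character(0)))
  bits <- as.integer(
    substring(sequence, dict$start, dict$start + nchar(dict$motif) - 1L) ==
      dict$motif
  )
  stats::setNames(bits, dict$token)
}

#' Binary fingerprint matrix for a record set
#'
#' @param records ODN record data.frame.
#' @param dict an `odn_dictionary`.
#' @return integer matrix, rows = records (rownames = ids), columns =
#'   dictionary tokens.
#' @export
fingerprint_matrix <- function(records, dict) {
  n <- nrow(records)
  m <- matrix(0L, n, nrow(dict),
              dimnames = list(records$id, dict$token))
  for (j in seq_len(nrow(dict))) {
    m[, j] <- as.integer(
      substring(records$sequence, dict$start[j],
                dict$start[j] + nchar(dict$motif[j]) - 1L) == dict$motif[j]
    )
  }
  m
}

#' Tanimoto (Jaccard) similarity of two binary fingerprints
#'
#' Defined as |a AND b| / |a OR b|, and as 1 when both vectors are all-zero
#' (two featureless items are indistinguishable).
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) abort("tanimoto: fingerprint lengths differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# Greedy leader clustering on the rows of a fingerprint matrix: row i is
# removed iff its Tanimoto similarity to an already-kept row is >= cutoff.
# Returns a logical keep vector.
leader_keep <- function(fps, cutoff) {
  n <- nrow(fps)
  keep <- logical(n)
  kept_idx <- integer(0)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in kept_idx) {
      if (tanimoto(fps[i, ], fps[j, ]) >= cutoff) { dup <- TRUE; break }
    }
    if (!dup) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  keep
}

#' Deduplicate ODNs by fingerprint similarity
#'
#' Greedy leader clustering in input order: a record is removed when its
#' Tanimoto similarity to any already-kept record reaches the cutoff, so the
#' first-seen member of each similarity cluster is retained.
#'
#' @param records ODN record data.frame.
#' @param dict an `odn_dictionary` used for fingerprinting.
#' @param cutoff similarity cutoff (default 0.85).
#' @return list with elements `kept` and `removed` (record data.frames).
#' @export
dedup_by_similarity <- function(records, dict, cutoff = 0.85) {
  if (nrow(records) == 0L) {
    return(list(kept = records, removed = records))
  }
  keep <- leader_keep(fingerprint_matrix(records, dict), cutoff)
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}
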