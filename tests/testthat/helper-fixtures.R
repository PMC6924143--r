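# Shared fixture builders and independent oracles. Everything is generated
# in code; nothing is read from disk.

# The two worked-example sequences used throughout the descriptor tests.
S1 <- "TATGCGTTCGTACTTGATCTGAC"
S2 <- "TGCTTTCTTGTCGTGCGGGCTGT"

# A small labelled record set with a fixed class split: n_high records with
# activity 0.8 and n_low with activity 0.1.
toy_labelled <- function(n_high, n_low, seed = 7) {
  recs <- random_odns(n_high + n_low, 24, seed = seed)
  recs$activity <- c(rep(0.8, n_high), rep(0.1, n_low))
  assign_labels(recs)
}

# A synthetic dictionary whose tokens are single positions of base G over a
# fixed-length window, so fingerprints can be written down directly: bit k of
# a sequence is 1 iff its k-th base is G.
positional_g_dictionary <- function(n_positions = 20L) {
  d <- data.frame(
    motif = rep("G", n_positions),
    start = seq_len(n_positions),
    token = paste0("G", seq_len(n_positions)),
    rate_high = 1, rate_low = 0,
    stringsAsFactors = FALSE
  )
  class(d) <- c("odn_dictionary", "data.frame")
  d
}

# Sequence over {A,G} of given length with G exactly at `g_at`.
ag_sequence <- function(g_at, len = 20L) {
  chars <- rep("A", len)
  chars[g_at] <- "G"
  paste(chars, collapse = "")
}

# Brute-force substring enumeration oracle for positional motif tokens.
oracle_tokens <- function(sequence, min_len = 2L, max_len = 6L) {
  out <- character(0)
  L <- nchar(sequence)
  for (k in min_len:max_len) {
    if (L < k) next
    for (s in 1:(L - k + 1)) {
      out <- c(out, paste0(substr(sequence, s, s + k - 1), s))
    }
  }
  out
}

# Brute-force sliding-window oracle for motif occurrence positions.
oracle_positions <- function(sequence, motif) {
  L <- nchar(sequence); m <- nchar(motif)
  if (L < m) return(integer(0))
  which(vapply(1:(L - m + 1), function(s)
    substr(sequence, s, s + m - 1) == motif, logical(1)))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments of the pooled observations
# (tie-free data assumed).
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  mu <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct metric recomputation from raw label vectors (independent of the
# package's confusion/metric code paths).
oracle_metrics <- function(pred, truth) {
  tp <- sum(pred == "high" & truth == "high")
  tn <- sum(pred == "low" & truth == "low")
  fp <- sum(pred == "high" & truth == "low")
  fn <- sum(pred == "low" & truth == "high")
  se <- tp / (tp + fn); sp <- tn / (tn + fp)
  list(se = se, sp = sp, ba = (se + sp) / 2,
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
       prec = tp / (tp + fp))
}
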