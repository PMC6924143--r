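# Numeric sequence descriptors: nucleotide counts, motif occurrence counts,
# motif-distance descriptors, and rigid-body features of a 2D graphical
# sequence embedding.

#' Count A/T/G/C nucleotides in a sequence
#'
#' Characters outside A, C, G, T (ambiguity codes, gaps) are ignored.
#'
#' @param sequence DNA string (uppercased internally).
#' @return named integer vector `c(A=, T=, G=, C=)`.
#' @export
count_nucleotides <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  vapply(c(A = "A", T = "T", G = "G", C = "C"),
         function(b) sum(chars == b), integer(1))
}

#' All (overlapping) occurrence positions of a motif
#'
#' @param sequence DNA string.
#' @param motif motif string, length >= 1.
#' @return ascending integer vector of 1-based start positions (possibly
#'   empty). Overlapping matches are all reported, e.g. AA in "AAA" gives
#'   positions 1 and 2.
#' @export
motif_positions <- function(sequence, motif) {
  stopifnot(nchar(motif) >= 1L)
  hits <- gregexpr(paste0("(?=", motif, ")"), sequence, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

# Vectorized occurrence positions over many sequences: list of integer
# vectors, one per sequence.
motif_positions_many <- function(sequences, motif) {
  if (!length(sequences)) return(list())
  hits <- gregexpr(paste0("(?=", motif, ")"), sequences, perl = TRUE)
  lapply(hits, function(h) if (h[1] == -1L) integer(0) else as.integer(h))
}

# Distance descriptors from an occurrence-position vector.
distances_from_positions <- function(p) {
  c(d2_1 = if (length(p) >= 2L) (p[2] - p[1]) + (p[2] - 1L) else 0,
    d3_1 = if (length(p) >= 3L) (p[3] - p[1]) + (p[3] - 1L) else 0,
    d3_2 = if (length(p) >= 3L) (p[3] - p[2]) + (p[3] - 1L) else 0)
}

#' Motif-distance descriptors
#'
#' For the first three occurrences of a motif at positions p1 < p2 < p3, the
#' descriptors are the positional gap between two occurrences plus the number
#' of nucleotides preceding the latter occurrence (which anchors the pair
#' within the ODN, so that equal gaps at different locations remain
#' distinguishable):
#' \deqn{d2\_1 = p_2 - p_1 + (p_2 - 1)}
#' \deqn{d3\_1 = p_3 - p_1 + (p_3 - 1)}
#' \deqn{d3\_2 = p_3 - p_2 + (p_3 - 1)}
#' A descriptor whose required occurrence is absent is 0.
#'
#' @param sequence DNA string.
#' @param motif motif string.
#' @return named numeric vector `c(d2_1=, d3_1=, d3_2=)`.
#' @export
distance_descriptors <- function(sequence, motif) {
  distances_from_positions(motif_positions(sequence, motif))
}

#' Embed a sequence as a 2D walk of unit material points
#'
#' Each base moves the walk one unit step: A up (0,+1), T down (0,-1),
#' G right (+1,0), C left (-1,0), starting from the origin. The point placed
#' for base i is the walk position after step i, with unit mass. Characters
#' outside A/C/G/T contribute no point.
#'
#' @param sequence DNA string.
#' @return numeric matrix with columns `x`, `y`, one row per base (0 rows for
#'   an empty sequence).
#' @export
graph_embed <- function(sequence) {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% c("A", "T", "G", "C")]
  dx <- c(A = 0, T = 0, G = 1, C = -1)[chars]
  dy <- c(A = 1, T = -1, G = 0, C = 0)[chars]
  cbind(x = cumsum(as.numeric(dx)), y = cumsum(as.numeric(dy)))
}

#' Rigid-body features of an embedded sequence
#'
#' Treats the embedded points as unit point masses of a rigid body: computes
#' the center of mass (mu_x, mu_y), the principal moments of inertia
#' I11 >= I22 (eigenvalues of the planar inertia tensor about the center of
#' mass, with Ixx = sum (y - mu_y)^2, Iyy = sum (x - mu_x)^2,
#' Ixy = -sum (x - mu_x)(y - mu_y)), and the radius of gyration
#' Rg = sqrt((I11 + I22) / N).
#'
#' @param points matrix of 2D points as returned by [graph_embed()]; at least
#'   one point.
#' @return named numeric vector `c(mu_x, mu_y, I11, I22, Rg)`.
#' @export
graph_features <- function(points) {
  n <- nrow(points)
  if (is.null(n) || n == 0L) abort("graph_features: empty point set")
  mu <- colMeans(points)
  xc <- points[, 1] - mu[1]
  yc <- points[, 2] - mu[2]
  ixx <- sum(yc^2)
  iyy <- sum(xc^2)
  ixy <- -sum(xc * yc)
  tr <- ixx + iyy
  disc <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  i11 <- tr / 2 + disc
  i22 <- max(tr / 2 - disc, 0)
  c(mu_x = unname(mu[1]), mu_y = unname(mu[2]),
    I11 = i11, I22 = i22, Rg = sqrt(tr / n))
}

#' The published distance-motif preset
#'
#' The seven motifs whose occurrence counts and inter-occurrence distances
#' form the fixed descriptor preset: CG, AG, GG, CC, TCT, TTC, TGT.
#'
#' @return character vector of motifs.
#' @export
default_distance_motifs <- function() {
  c("CG", "AG", "GG", "CC", "TCT", "TTC", "TGT")
}

#' Select group-discriminating motifs from training data
#'
#' Ranks position-free motifs by the absolute difference of their occurrence
#' rates between the high and low activity groups (see
#' [group_occurrence_diff()]) and keeps those whose difference is at least
#' `threshold` (the same 10% occurrence-difference rule that defines the
#' fingerprint dictionary). This is the data-driven counterpart of the fixed
#' preset in [default_distance_motifs()]: the motif list used for
#' count/distance descriptors is itself a property of the training data, and
#' redundancy among the selected motifs is left to the downstream feature
#' pipeline. Set `n_motifs` to cap the list at the top n instead.
#'
#' @param high,low ODN record data.frames of the two activity groups.
#' @param threshold minimum absolute occurrence-rate difference as a
#'   fraction (default 0.10).
#' @param n_motifs optional cap on the number of motifs (default `NULL`, no
#'   cap).
#' @param min_len,max_len motif length bounds (defaults 2 and 6).
#' @return character vector of motifs, ordered by descending discrimination;
#'   falls back to [default_distance_motifs()] if no motif reaches the
#'   threshold.
#' @export
select_distance_motifs <- function(high, low, threshold = 0.10,
                                   n_motifs = NULL,
                                   min_len = 2L, max_len = 6L) {
  tab <- group_occurrence_diff(high, low, min_len, max_len)
  motifs <- tab$motif[tab$abs_diff >= 100 * threshold - 1e-9]
  if (!is.null(n_motifs)) motifs <- head(motifs, n_motifs)
  if (!length(motifs)) motifs <- default_distance_motifs()
  motifs
}

# Per-motif numeric block: occurrence count plus the three distance
# descriptors, vectorized over records. Columns n_<m>, d_<m>2_1/3_1/3_2.
motif_block <- function(records, motif, motif_counts = TRUE) {
  pos <- motif_positions_many(records$sequence, motif)
  d <- t(vapply(pos, distances_from_positions, numeric(3)))
  cols <- paste0("d_", motif, c("2_1", "3_1", "3_2"))
  if (motif_counts) {
    out <- cbind(lengths(pos), d)
    colnames(out) <- c(paste0("n_", motif), cols)
  } else {
    out <- d
    colnames(out) <- cols
  }
  out
}

# Base numeric block shared by all configurations: nucleotide counts and
# graph-derived rigid-body features.
base_descriptors <- function(records) {
  seqs <- records$sequence
  count_char <- function(b) nchar(seqs) - nchar(gsub(b, "", seqs, fixed = TRUE))
  g <- t(vapply(seqs, function(s) graph_features(graph_embed(s)),
                c(mu_x = 0, mu_y = 0, I11 = 0, I22 = 0, Rg = 0)))
  out <- cbind(A = count_char("A"), T = count_char("T"),
               G = count_char("G"), C = count_char("C"),
               PMI1 = g[, "I11"], PMI2 = g[, "I22"],
               Mu_x = g[, "mu_x"], Mu_y = g[, "mu_y"], Rg = g[, "Rg"])
  rownames(out) <- records$id
  out
}

# Full numeric descriptor block. Column order: A,T,G,C; per-motif counts;
# per-motif distance descriptors; graph features.
numeric_descriptors <- function(records,
                                distance_motifs = default_distance_motifs(),
                                motif_counts = TRUE) {
  base <- base_descriptors(records)
  blocks <- lapply(distance_motifs, function(m)
    motif_block(records, m, motif_counts))
  x <- do.call(cbind, c(list(base[, c("A", "T", "G", "C"), drop = FALSE]),
                        blocks,
                        list(base[, c("PMI1", "PMI2", "Mu_x", "Mu_y", "Rg"),
                                  drop = FALSE])))
  rownames(x) <- records$id
  x
}

#' Assemble the full feature matrix for a record set
#'
#' Columns, in order: nucleotide counts `A,T,G,C`; per-motif occurrence
#' counts `n_<motif>` and motif-distance descriptors
#' `d_<motif>2_1 / 3_1 / 3_2` for each configured motif; graph features
#' `PMI1, PMI2, Mu_x, Mu_y, Rg`; then one binary column per fingerprint
#' dictionary token (named like `CG1`, `GT18`).
#'
#' @param records ODN record data.frame.
#' @param dict an `odn_dictionary` for the fingerprint block.
#' @param distance_motifs motifs for the count/distance block (default the
#'   published preset CG, AG, GG, CC, TCT, TTC, TGT; see
#'   [select_distance_motifs()] for the data-driven alternative).
#' @param motif_counts include the `n_<motif>` occurrence-count columns
#'   (default TRUE).
#' @return numeric matrix with rownames = record ids and attribute
#'   `fingerprint_cols` naming the binary columns.
#' @export
featurize <- function(records, dict,
                      distance_motifs = default_distance_motifs(),
                      motif_counts = TRUE) {
  num <- numeric_descriptors(records, distance_motifs, motif_counts)
  fp <- fingerprint_matrix(records, dict)
  x <- cbind(num, fp)
  attr(x, "fingerprint_cols") <- colnames(fp)
  x
}

#' Write a feature matrix as tab-delimited text
#'
#' @param x feature matrix (rownames = ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
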