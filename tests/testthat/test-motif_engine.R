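test_that("motif chopping enumerates every positional substring", {
  tok <- enumerate_motifs("TCG")
  expect_setequal(tok$token, c("TC1", "CG2", "TCG1"))

  expect_equal(nrow(enumerate_motifs("A")), 0L)
  expect_equal(enumerate_motifs("AA")$token, "AA1")
  expect_equal(nrow(enumerate_motifs("ACGTAC")), 15L) # 5+4+3+2+1

  # closed form and brute-force oracle on random sequences
  for (s in random_odns(25, 24, seed = 2)$sequence) {
    tok <- enumerate_motifs(s)
    L <- nchar(s)
    expect_equal(nrow(tok), sum(L - (2:6) + 1))
    expect_setequal(paste0(tok$motif, tok$start), oracle_tokens(s))
  }
})

test_that("occurrence rates count each ODN once", {
  recs <- odn_records(c("a", "b", "c", "d"),
                      c("CGT", "CGA", "TTT", "CGT"))
  rates <- occurrence_rate(recs)
  expect_equal(unname(rates["CG1"]), 3 / 4)
  expect_equal(unname(rates["TT1"]), 1 / 4) # TTT has TT at 1 and 2: one ODN
  expect_false("GG1" %in% names(rates))
  expect_error(occurrence_rate(recs[0, ]), "empty")
})

test_that("dictionary keeps tokens at or above the rate-difference threshold", {
  high <- odn_records(c("h1", "h2"), c("CGT", "CGA"))
  low <- odn_records(c("l1", "l2"), c("TTT", "CGT"))
  dict <- build_dictionary(high, low, threshold = 0.10)
  cg1 <- dict[dict$token == "CG1", ]
  expect_equal(nrow(cg1), 1L)
  expect_equal(cg1$rate_high, 1.0)
  expect_equal(cg1$rate_low, 0.5)
  # equal-rate tokens are excluded: GT2 occurs in one of each group
  expect_false("GT2" %in% dict$token)
  # threshold zero keeps every token seen in either group
  dict0 <- build_dictionary(high, low, threshold = 0)
  expect_setequal(
    dict0$token,
    union(names(occurrence_rate(high)), names(occurrence_rate(low)))
  )
  # ordering: descending |difference|, then motif, then start
  d <- abs(dict$rate_high - dict$rate_low)
  expect_true(all(diff(d) <= 1e-12))
  expect_error(build_dictionary(high[0, ], low), "non-empty")
})

test_that("dictionary serialization round-trips", {
  high <- toy_labelled(10, 10, seed = 4)
  dict <- build_dictionary(high[1:10, ], high[11:20, ], threshold = 0.2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(dict, path)
  back <- read_dictionary(path)
  expect_equal(back$token, dict$token)
  expect_equal(back$rate_high, dict$rate_high, tolerance = 1e-12)
})

test_that("fingerprints encode exact positional presence", {
  d <- data.frame(motif = c("CG", "TC", "GG"), start = c(1L, 1L, 3L),
                  token = c("CG1", "TC1", "GG3"),
                  rate_high = 1, rate_low = 0)
  class(d) <- c("odn_dictionary", "data.frame")
  expect_equal(unname(encode_fingerprint("CGG", d)), c(1L, 0L, 0L))
  expect_length(encode_fingerprint("ACGT", d[0, ]), 0L)

  # consistency with enumeration: bit = token membership
  s <- random_odns(1, 24, seed = 9)$sequence
  dict <- build_dictionary(odn_records("x", s), odn_records("y", "AAAAAAAA"),
                           threshold = 0)
  bits <- encode_fingerprint(s, dict)
  expect_equal(unname(bits),
               as.integer(dict$token %in% enumerate_motifs(s)$token))
})

test_that("tanimoto similarity handles boundary cases", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "lengths")
})

test_that("greedy leader deduplication keeps the first-seen representative", {
  dict <- positional_g_dictionary(20)
  # A: G at 1..18; B: G at 1..17,19 (sim to A = 17/19 = 0.895)
  # C: G at 1..16,19,20 (sim to A = 16/20 = 0.80, sim to B = 17/19 = 0.895)
  recs <- odn_records(
    c("A", "B", "C"),
    c(ag_sequence(1:18), ag_sequence(c(1:17, 19)),
      ag_sequence(c(1:16, 19, 20)))
  )
  fps <- fingerprint_matrix(recs, dict)
  expect_equal(tanimoto(fps["A", ], fps["B", ]), 17 / 19)
  expect_equal(tanimoto(fps["A", ], fps["C", ]), 16 / 20)
  expect_equal(tanimoto(fps["B", ], fps["C", ]), 17 / 19)
  dd <- dedup_by_similarity(recs, dict, cutoff = 0.85)
  # B is similar to kept A and goes; C is only similar to removed B and stays
  expect_equal(dd$kept$id, c("A", "C"))
  expect_equal(dd$removed$id, "B")

  # identical sequences: second removed
  two <- odn_records(c("x", "y"), c("ACGTACGT", "ACGTACGT"))
  dict2 <- build_dictionary(two[1, ], odn_records("z", "TTTTTTTT"), 0.1)
  dd2 <- dedup_by_similarity(two, dict2)
  expect_equal(dd2$kept$id, "x")
  expect_equal(dd2$removed$id, "y")
})

test_that("deduplication is idempotent and partitions the input", {
  recs <- random_odns(40, 12, seed = 31)
  labelled <- assign_labels(
    simulate_activity(recs, simulation_config(40, 12, seed = 31)))
  dict <- build_dictionary(labelled[labelled$label == "high", ],
                           labelled[labelled$label == "low", ], 0.1)
  dd <- dedup_by_similarity(recs, dict, cutoff = 0.6)
  expect_setequal(c(dd$kept$id, dd$removed$id), recs$id)
  dd2 <- dedup_by_similarity(dd$kept, dict, cutoff = 0.6)
  expect_equal(dd2$kept$id, dd$kept$id)
  expect_equal(nrow(dd2$removed), 0L)
})
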