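# Column conservation scores and consensus patterns.

aln_from <- function(seqs) alignment_block(sprintf("s%d", seq_along(seqs)), seqs)

test_that("entropy is 0 for invariant and log2(20) for uniform columns", {
  a <- aln_from(rep("L", 8))
  sc <- score_columns(a, methods = "entropy")
  expect_equal(sc$entropy, 0)
  expect_equal(sc$entropy_score, 1)

  u <- aln_from(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  su <- score_columns(u, methods = "entropy")
  expect_equal(su$entropy, log2(20))
  expect_equal(su$entropy_score, 0)
})

test_that("matrix scores equal the hand-computed pairwise mean", {
  a <- aln_from(c("L", "L", "I", "V"))
  sc <- score_columns(a, methods = "matrix", matrix = "BLOSUM62")
  B <- scoring_matrix("BLOSUM62")
  # 6 unordered pairs: LL, LI, LV, LI, LV, IV
  hand <- mean(c(B["L", "L"], B["L", "I"], B["L", "V"],
                 B["L", "I"], B["L", "V"], B["I", "V"]))
  expect_equal(sc$matrix_score,
               (hand - min(B)) / (max(B) - min(B)))
  # same computation under BLOSUM45 differs but stays in [0, 1]
  sc45 <- score_columns(a, methods = "matrix", matrix = "BLOSUM45")
  expect_true(sc45$matrix_score >= 0 && sc45$matrix_score <= 1)
  expect_error(score_columns(a, methods = "matrix", matrix = "PAM999"))
})

test_that("scores are permutation-invariant and gaps are excluded", {
  seqs <- c("LD-", "LDK", "IDK", "VD-")
  a <- aln_from(seqs)
  b <- aln_from(seqs[c(3, 1, 4, 2)])
  expect_equal(score_columns(a)$average_conservation,
               score_columns(b)$average_conservation)
  sc <- score_columns(a)
  expect_equal(sc$gap_fraction, c(0, 0, 0.5))
  expect_equal(sc$entropy[2], 0)          # gaps out, all-D column
  expect_equal(sc$entropy[3], 0)          # two K after gap removal
})

test_that("Henikoff weighting makes duplicated sequences innocuous", {
  base <- c("LDKE", "IDRE", "VNKD")
  dup <- c(base, base[1], base[1])        # sequence 1 duplicated twice
  w <- henikoff_weights(aln_from(dup))
  expect_lt(w[1] + w[4] + w[5], 3 * w[2]) # copies share weight
  s0 <- score_columns(aln_from(base), methods = "weighted")
  s1 <- score_columns(aln_from(dup), methods = "weighted")
  s_plain <- score_columns(aln_from(dup), methods = "matrix")
  # weighted scores of the duplicated alignment stay closer to the original
  d_w <- mean(abs(s1$weighted_score - s0$weighted_score))
  d_p <- mean(abs(s_plain$matrix_score - s0$weighted_score))
  expect_lt(d_w, d_p)
})

test_that("PET91-style matrix is a valid symmetric log-odds table", {
  M <- scoring_matrix("PET91")
  expect_equal(dim(M), c(20, 20))
  expect_equal(M, t(M))
  expect_true(all(diag(M) > 0))                   # identities favoured
  expect_gt(M["L", "I"], M["L", "D"])             # conservative > radical
  expect_gt(M["D", "E"], M["D", "W"])
  sc <- score_columns(aln_from(c("L", "L", "I")), methods = "matrix",
                      matrix = "PET91")
  expect_true(sc$matrix_score > 0 && sc$matrix_score <= 1)
})

test_that("consensus emits literal, pair, class and x symbols by frequency", {
  a10 <- make_toy_alignment(10, list(
    list(type = "mix", freqs = c(D = 0.8, E = 0.2)),
    list(type = "literal", aa = "P"),
    list(type = "class", class = "h"),
    list(type = "gap", gap_fraction = 0.8)
  ), seed = 21)$alignment
  p70 <- consensus_pattern(a10, 0.70)
  expect_equal(p70[1], "D")
  expect_equal(p70[2], "P")
  expect_true(p70[3] %in% c("h", "x") == (p70[3] == "h"))  # class column -> h
  expect_equal(p70[4], "-")
  p90 <- consensus_pattern(a10, 0.90)
  expect_equal(p90[1], "(D,E)")
  expect_equal(consensus_pattern(a10, 0.90, class_over_pair = TRUE)[1], "n")
})

test_that("identical sequences give back the sequence as consensus", {
  a <- alignment_block(c("a", "b", "c"), rep("ILHDPGW", 3))
  expect_equal(attr(consensus_pattern(a, 0.8), "pattern"), "ILHDPGW")
})

test_that("raising the threshold never makes a symbol more specific", {
  spec_rank <- function(s) {
    if (s == "-") return(0)
    if (nchar(s) == 1 && s %in% LETTERS) return(4)   # literal
    if (startsWith(s, "(")) return(3)                # pair
    if (s %in% c("h", "u", "n")) return(2)           # class
    1                                                # x
  }
  set.seed(17)
  designs <- replicate(10, {
    fr <- stats::runif(4)
    names(fr) <- sample(c("D", "E", "A", "G"), 4)
    list(type = "mix", freqs = fr / sum(fr))
  }, simplify = FALSE)
  a <- make_toy_alignment(12, designs, seed = 8)$alignment
  for (cl in c(FALSE, TRUE)) {
    p1 <- consensus_pattern(a, 0.70, class_over_pair = cl)
    p2 <- consensus_pattern(a, 0.80, class_over_pair = cl)
    p3 <- consensus_pattern(a, 0.95, class_over_pair = cl)
    r <- vapply(list(p1, p2, p3), function(p) vapply(p, spec_rank, numeric(1)),
                numeric(a$ncol))
    expect_true(all(r[, 2] <= r[, 1] | r[, 1] == 1))
    expect_true(all(r[, 3] <= r[, 2] | r[, 2] == 1))
  }
})
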