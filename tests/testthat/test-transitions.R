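seq_tbl <- function(seqs, phase = "p") {
  tibble::tibble(conversation_id = paste0("c", seq_along(seqs)),
                 phase = phase, labels = seqs, length = lengths(seqs))
}

test_that("counts and probabilities match direct pair enumeration", {
  m <- estimate_transition_model(seq_tbl(list(c("anger", "sadness", "sadness", "fear"))))
  expect_equal(m$C[["anger", "sadness"]], 1L)
  expect_equal(m$C[["sadness", "sadness"]], 1L)
  expect_equal(m$C[["sadness", "fear"]], 1L)
  expect_equal(sum(m$C), 3)
  expect_equal(m$P[["anger", "sadness"]], 1.0)
  expect_equal(m$P[["sadness", "sadness"]], 0.5)
  expect_equal(m$P[["sadness", "fear"]], 0.5)
  # unseen source emotions are undefined, not smoothed
  expect_true(all(is.na(m$P["joy", ])))
  # constant sequence is a self-loop
  mj <- estimate_transition_model(seq_tbl(list(c("joy", "joy", "joy"))))
  expect_equal(mj$P[["joy", "joy"]], 1)
})

test_that("estimates agree with the brute-force oracle on random sequences", {
  set.seed(21)
  seqs <- replicate(100, sample(plutchik_emotions(), sample(2:8, 1),
                                replace = TRUE), simplify = FALSE)
  m <- estimate_transition_model(seq_tbl(seqs))
  C <- brute_force_transition_counts(seqs)
  expect_identical(m$C, C)
  rs <- rowSums(C)
  for (i in which(rs > 0)) {
    expect_equal(m$P[i, ], C[i, ] / rs[i])
    expect_equal(sum(m$P[i, ]), 1, tolerance = 1e-9)
  }
  # counts conserved; transitions never cross conversations
  expect_equal(sum(m$C), sum(lengths(seqs) - 1))
  m_perm <- estimate_transition_model(seq_tbl(rev(seqs)))
  expect_identical(m_perm$C, m$C)
})

test_that("disjoint corpora concatenate additively", {
  set.seed(3)
  s1 <- replicate(20, sample(plutchik_emotions(), 4, replace = TRUE),
                  simplify = FALSE)
  s2 <- replicate(30, sample(plutchik_emotions(), 3, replace = TRUE),
                  simplify = FALSE)
  mall <- estimate_transition_model(seq_tbl(c(s1, s2)))
  expect_identical(mall$C,
                   estimate_transition_model(seq_tbl(s1))$C +
                     estimate_transition_model(seq_tbl(s2))$C)
})

test_that("degenerate inputs are rejected and smoothing defines all rows", {
  expect_error(estimate_transition_model(seq_tbl(list("joy"))), "length >= 2")
  m <- estimate_transition_model(seq_tbl(list(c("joy", "fear"))), smoothing = 1)
  expect_false(anyNA(m$P))
  expect_equal(rowSums(m$P), setNames(rep(1, 8), plutchik_emotions()),
               tolerance = 1e-9)
})

test_that("top transitions sort by probability with deterministic tie-breaks", {
  m <- estimate_transition_model(seq_tbl(list(c("anger", "sadness", "sadness", "fear"))))
  top <- top_transitions(m, 2)
  expect_equal(top$from, c("anger", "sadness"))
  expect_equal(top$to, c("sadness", "sadness"))
  expect_equal(top$probability, c(1.0, 0.5))
  # k beyond the number of observed transitions returns all of them
  expect_equal(nrow(top_transitions(m, 50)), 3)
})

test_that("simulated chains recover the generating matrix", {
  emo <- plutchik_emotions()
  set.seed(5)
  P <- matrix(rexp(64), 8, dimnames = list(emo, emo))
  P <- P / rowSums(P)
  seqs <- simulate_emotion_sequences(P, n_sequences = 100,
                                     length_per_sequence = 101, seed = 33)
  m <- estimate_transition_model(seq_tbl(seqs))
  expect_equal(sum(m$C), 10000)
  expect_lte(max(abs(m$P - P)), 0.05)
})

test_that("DOT export lists edges above the threshold", {
  m <- estimate_transition_model(seq_tbl(list(c("anger", "sadness", "sadness", "fear"))))
  path <- withr::local_tempfile(fileext = ".dot")
  write_transition_dot(m, path, threshold = 0.6)
  txt <- readLines(path)
  expect_true(any(grepl("anger -> sadness", txt)))
  expect_false(any(grepl("sadness -> fear", txt)))
})
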