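test_that("negation flips a match to its Plutchik opposite", {
  lex <- tiny_lexicon(list(list("joy", "happy", 1)))
  pe <- score_post(c("not", "happy"), lex, window = 3)
  expect_equal(pe$scores[["sadness"]], 1)
  expect_equal(pe$scores[["joy"]], 0)
  expect_equal(pe$dominant, "sadness")
  expect_true(pe$matches$negated[1])
})

test_that("double negation is an involution", {
  lex <- tiny_lexicon(list(list("joy", "happy", 1)))
  pe <- score_post(c("not", "not", "happy"), lex, window = 3)
  expect_equal(pe$dominant, "joy")
  expect_equal(pe$scores[["joy"]], 1)
  # triple flips again
  pe3 <- score_post(c("not", "not", "not", "happy"), lex, window = 3)
  expect_equal(pe3$dominant, "sadness")
})

test_that("modifiers compose multiplicatively within the window", {
  lex <- tiny_lexicon(list(list("fear", "scared", 0.8)))
  pe <- score_post(c("very", "scared"), lex)
  expect_equal(pe$scores[["fear"]], 1.2)
  # stacked intensifier and inhibitor: 0.8 * 1.5 * 0.5
  pe2 <- score_post(c("very", "slightly", "scared"), lex)
  expect_equal(pe2$scores[["fear"]], 0.6)
  # modifier outside the window is ignored
  pe3 <- score_post(c("very", "a", "b", "c", "scared"), lex, window = 3)
  expect_equal(pe3$scores[["fear"]], 0.8)
})

test_that("posts without lexicon matches are neutral", {
  lex <- tiny_lexicon(list(list("joy", "happy", 1)))
  pe <- score_post(c("just", "a", "plain", "post"), lex)
  expect_true(all(pe$scores == 0))
  expect_true(is.na(pe$dominant))
})

test_that("discard mode drops negated mass instead of flipping", {
  lex <- tiny_lexicon(list(list("joy", "happy", 1)))
  pe <- score_post(c("not", "happy"), lex, negation_mode = "discard")
  expect_true(all(pe$scores == 0))
  expect_true(is.na(pe$dominant))
})

test_that("scores are scale-equivariant and dominants tie-break in fixed order", {
  lex <- tiny_lexicon(list(list("joy", "happy", 0.7),
                           list("fear", "scared", 0.5)))
  lex2 <- lex
  lex2$weight <- lex2$weight * 3
  toks <- c("happy", "scared", "happy")
  expect_equal(score_post(toks, lex2)$scores, 3 * score_post(toks, lex)$scores)
  expect_equal(score_post(toks, lex2)$dominant, score_post(toks, lex)$dominant)
  # exact tie: anger precedes joy in the canonical order
  lext <- tiny_lexicon(list(list("joy", "happy", 1), list("anger", "mad", 1)))
  expect_equal(score_post(c("happy", "mad"), lext)$dominant, "anger")
})

test_that("sequences are chronological, per conversation, and skip neutral posts", {
  sc <- tibble::tibble(
    post_id = c("p3", "p1", "p2", "p4", "p5"),
    conversation_id = c("c1", "c1", "c1", "c2", "c2"),
    phase = "first_lockdown",
    timestamp = as.POSIXct("2020-03-01", tz = "UTC") + c(300, 100, 200, 50, 60),
    dominant = c("fear", "sadness", "sadness", NA, "joy"))
  seqs <- build_sequences(sc)
  expect_equal(nrow(seqs), 2)
  s1 <- seqs$labels[[which(seqs$conversation_id == "c1")]]
  expect_equal(s1, c("sadness", "sadness", "fear"))
  s2 <- seqs$labels[[which(seqs$conversation_id == "c2")]]
  expect_equal(s2, "joy")
  # all-neutral conversation emits nothing
  sc_none <- tibble::tibble(post_id = "p9", conversation_id = "c9",
                            phase = "x",
                            timestamp = as.POSIXct("2020-03-01", tz = "UTC"),
                            dominant = NA_character_)
  expect_equal(nrow(build_sequences(sc_none)), 0)
  # timestamp ties broken by post id
  tied <- tibble::tibble(post_id = c("b", "a"), conversation_id = "c",
                         phase = "x",
                         timestamp = as.POSIXct("2020-03-01", tz = "UTC"),
                         dominant = c("fear", "joy"))
  expect_equal(build_sequences(tied)$labels[[1]], c("joy", "fear"))
})

test_that("scoring a generated corpus recovers the planted labels", {
  g <- small_corpus()
  pp <- preprocess_corpus(g$posts)
  v <- build_default_vocabulary()
  # score with the ground-truth lexicon (seeds + satellites, weight 1)
  lex <- tiny_lexicon(unlist(lapply(plutchik_emotions(), function(e) {
    lapply(c(v$seeds[[e]], v$satellites[[e]]), function(t) list(e, t, 1))
  }), recursive = FALSE))
  sc <- score_posts(pp$posts, lex)
  gt <- g$ground_truth$post_labels
  truth <- gt$emotion[match(sc$post_id, gt$post_id)]
  expect_gt(mean(sc$dominant == truth, na.rm = TRUE), 0.95)
})
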