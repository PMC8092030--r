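test_that("default vocabulary covers the eight emotions with disjoint term sets", {
  v <- build_default_vocabulary()
  expect_setequal(names(v$seeds), plutchik_emotions())
  expect_setequal(names(v$satellites), plutchik_emotions())
  expect_true(all(lengths(v$seeds) >= 5))
  expect_true(all(lengths(v$satellites) >= 10))
  all_terms <- unlist(c(v$seeds, v$satellites))
  expect_equal(anyDuplicated(all_terms), 0)
  expect_gte(length(v$negators), 3)
  expect_gte(length(v$intensifiers), 3)
  expect_gte(length(v$inhibitors), 3)
  expect_gte(length(v$topic_vocab), 4)
  expect_true(all(v$intensifiers > 1))
  expect_true(all(v$inhibitors > 0 & v$inhibitors < 1))
  expect_identical(build_default_vocabulary(1), build_default_vocabulary(99))
})

test_that("corpus generation is deterministic and conserves the post count", {
  v <- build_default_vocabulary()
  scen <- default_scenarios(c(50, 80, 30, 40))
  g1 <- generate_corpus(v, scen, n_users = 30, bot_fraction = 0, seed = 5)
  g2 <- generate_corpus(v, scen, n_users = 30, bot_fraction = 0, seed = 5)
  expect_identical(g1$posts, g2$posts)
  expect_identical(g1$ground_truth$post_labels, g2$ground_truth$post_labels)
  expect_equal(nrow(g1$posts), 50 + 80 + 30 + 40)
  expect_length(g1$ground_truth$bot_users, 0)
})

test_that("every post stays inside its scenario window and carries a usable label", {
  g <- small_corpus()
  gt <- g$ground_truth$post_labels
  win <- default_phase_windows()
  d <- as.Date(g$posts$timestamp, tz = "UTC")
  ph <- gt$phase[match(g$posts$post_id, gt$post_id)]
  for (i in seq_len(nrow(win))) {
    in_ph <- ph == win$name[i]
    expect_true(all(d[in_ph] >= win$start[i] & d[in_ph] <= win$end[i]))
  }
  # label-text consistency: at least one token of the labeled emotion
  v <- build_default_vocabulary()
  lex_of <- function(e) c(v$seeds[[e]], v$satellites[[e]])
  toks <- strsplit(g$posts$text, " ", fixed = TRUE)
  lab <- gt$emotion[match(g$posts$post_id, gt$post_id)]
  ok <- vapply(seq_along(toks), function(i) any(toks[[i]] %in% lex_of(lab[i])), TRUE)
  expect_true(all(ok))
  # >= 60% of non-filler tokens from the true emotion vocabulary
  frac <- vapply(seq_along(toks), function(i) {
    nf <- toks[[i]][!(toks[[i]] %in% c(v$filler, v$negators))]
    mean(nf %in% lex_of(lab[i]))
  }, 0)
  expect_true(all(frac >= 0.6))
})

test_that("degenerate mixture produces a single emotion and invalid inputs are rejected", {
  v <- build_default_vocabulary()
  mix <- setNames(c(0, 1, 0, 0, 0, 0, 0, 0), plutchik_emotions())
  sc <- phase_scenario("prepandemic", c("2020-01-01", "2020-02-29"), mix,
                       c(health = 1), n_posts = 60)
  g <- generate_corpus(v, list(sc), n_users = 10, seed = 3)
  expect_true(all(g$ground_truth$post_labels$emotion == "sadness"))

  expect_error(phase_scenario("p", c("2020-01-01", "2020-02-29"),
                              setNames(rep(0.2, 8), plutchik_emotions()),
                              c(health = 1), 10),
               "sum to 1")
  overlapping <- list(
    phase_scenario("a", c("2020-01-01", "2020-03-15"),
                   setNames(rep(1 / 8, 8), plutchik_emotions()), c(health = 1), 5),
    phase_scenario("b", c("2020-03-01", "2020-05-31"),
                   setNames(rep(1 / 8, 8), plutchik_emotions()), c(health = 1), 5))
  expect_error(generate_corpus(v, overlapping, n_users = 5, seed = 1),
               "disjoint")
  expect_error(generate_corpus(v, list(sc), n_users = 5, bot_fraction = 1),
               "bot_fraction")
})

test_that("empirical emotion frequencies match the configured mixture at large n", {
  v <- build_default_vocabulary()
  mix <- setNames(c(0.10, 0.28, 0.07, 0.20, 0.17, 0.03, 0.08, 0.07),
                  plutchik_emotions())
  sc <- phase_scenario("first_lockdown", c("2020-03-01", "2020-05-31"), mix,
                       c(health = 0.5, economy = 0.5), n_posts = 10000)
  g <- generate_corpus(v, list(sc), n_users = 200, seed = 42)
  emp <- table(factor(g$ground_truth$post_labels$emotion,
                      levels = plutchik_emotions())) / 10000
  expect_lt(max(abs(as.numeric(emp) - mix)), 0.02)
})

test_that("bot accounts flood with duplicated text at >= 20x the median volume", {
  v <- build_default_vocabulary()
  scen <- default_scenarios(150)
  g <- generate_corpus(v, scen, n_users = 40, bot_fraction = 0.1, seed = 9)
  bots <- g$ground_truth$bot_users
  expect_gt(length(bots), 0)
  expect_true(all(bots %in% g$posts$user_id))
  counts <- table(g$posts$user_id)
  organic <- counts[setdiff(names(counts), bots)]
  for (b in bots) {
    expect_gte(counts[[b]], 20 * median(organic))
    expect_equal(length(unique(g$posts$text[g$posts$user_id == b])), 1)
  }
})

test_that("corpus JSONL round-trips", {
  g <- small_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(g$posts[1:50, ], path)
  back <- read_corpus_jsonl(path)
  expect_equal(back$post_id, g$posts$post_id[1:50])
  expect_equal(back$text, g$posts$text[1:50])
  expect_equal(as.numeric(back$timestamp),
               round(as.numeric(g$posts$timestamp[1:50])))
})
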