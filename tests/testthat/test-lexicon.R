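test_that("embedding training is deterministic and honors min_count", {
  docs <- rep(list(c("scared", "terrified", "virus"),
                   c("scared", "terrified", "lockdown"),
                   c("happy", "joyful", "weekend"),
                   c("happy", "joyful", "sunshine")), 40)
  m1 <- train_embeddings(docs, d = 16, min_count = 3, epochs = 3, seed = 7)
  m2 <- train_embeddings(docs, d = 16, min_count = 3, epochs = 3, seed = 7)
  expect_identical(m1$vectors, m2$vectors)
  # a term below min_count is absent
  docs2 <- c(docs, list(c("rareword", "scared")))
  m3 <- train_embeddings(docs2, d = 8, min_count = 2, epochs = 1, seed = 1)
  expect_false("rareword" %in% rownames(m3$vectors))
  expect_error(train_embeddings(list(c("a", "b")), min_count = 5),
               "vocabulary empty")
  expect_error(train_embeddings(list()), "non-empty")
})

test_that("planted co-occurrence yields higher cosine than unrelated terms", {
  set.seed(2)
  fear_docs <- replicate(120, sample(c("scared", "terrified", "panic",
                                       sample(letters, 3))), simplify = FALSE)
  joy_docs <- replicate(120, sample(c("happy", "joyful", "cheerful",
                                      sample(LETTERS, 3))), simplify = FALSE)
  m <- train_embeddings(c(fear_docs, joy_docs), d = 24, min_count = 3,
                        epochs = 8, seed = 4)
  expect_gt(embedding_similarity(m, "scared", "terrified"),
            embedding_similarity(m, "scared", "happy"))
})

test_that("tau = 1 keeps exactly the seeds", {
  g <- small_corpus()
  toks <- tokenize_posts(g$posts$text[1:400])
  m <- train_embeddings(toks, d = 24, epochs = 2, seed = 1)
  lex <- expand_lexicons(m, k = 10, tau = 1.0)
  expect_true(all(lex$provenance == "seed"))
  expect_setequal(lex$term, unlist(default_seed_lexicon()))
  expect_true(all(lex$weight[lex$provenance == "seed"] == 1))
})

test_that("candidates near several emotions go to the argmax emotion", {
  # hand-built unit vectors: cosine(cand, fear seed) = 0.6,
  # cosine(cand, anger seed) = 0.5
  vec <- rbind(
    scared = c(1, 0, 0),
    angry = c(0, 1, 0),
    cand = c(0.6, 0.5, sqrt(1 - 0.6^2 - 0.5^2)))
  m <- fake_embedding(vec)
  lex <- expand_lexicons(m, seeds = list(anger = "angry", fear = "scared"),
                         k = 5, tau = 0.3)
  row <- lex[lex$term == "cand", ]
  expect_equal(row$emotion, "fear")
  expect_equal(row$weight, 0.6, tolerance = 1e-12)
  # exact tie goes to the lexicographically first emotion
  vec2 <- rbind(angry = c(1, 0), scared = c(0, 1),
                tied = c(1, 1) / sqrt(2))
  lex2 <- expand_lexicons(fake_embedding(vec2),
                          seeds = list(fear = "scared", anger = "angry"),
                          k = 5, tau = 0.3)
  expect_equal(lex2$emotion[lex2$term == "tied"], "anger")
})

test_that("expanded lexicons are disjoint and monotone in tau", {
  g <- small_corpus()
  toks <- tokenize_posts(g$posts$text)
  m <- train_embeddings(toks, d = 32, epochs = 3, seed = 2)
  lex_hi <- expand_lexicons(m, k = 15, tau = 0.6)
  lex_lo <- expand_lexicons(m, k = 15, tau = 0.3)
  expect_equal(anyDuplicated(lex_hi$term), 0)
  expect_equal(anyDuplicated(lex_lo$term), 0)
  expect_true(all(lex_hi$term %in% lex_lo$term))
  expect_true(all(lex_lo$weight[lex_lo$provenance == "expanded"] >= 0.3))
})

test_that("out-of-vocabulary seeds warn but stay in the lexicon", {
  vec <- rbind(angry = c(1, 0), furious = c(0.9, sqrt(1 - 0.81)))
  m <- fake_embedding(vec)
  expect_warning(
    lex <- expand_lexicons(m, seeds = list(anger = c("angry", "nosuchword")),
                           k = 3, tau = 0.5),
    "nosuchword")
  expect_true("nosuchword" %in% lex$term)
  expect_equal(lex$weight[lex$term == "nosuchword"], 1)
})

test_that("lexicon TSV round-trips", {
  lex <- tiny_lexicon(list(list("joy", "happy", 1),
                           list("fear", "scared", 0.8, "expanded")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, path)
  back <- read_lexicon_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(lex))
})
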