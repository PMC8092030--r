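test_that("degenerate topic counts behave", {
  docs <- replicate(10, sample(letters[1:6], 5, replace = TRUE),
                    simplify = FALSE)
  m1 <- fit_topics(docs, K = 1, seed = 1)
  expect_equal(m1$shares, 100)
  expect_equal(m1$volumes, 10L)
  expect_error(fit_topics(docs, K = 11, seed = 1), "exceeds")
  expect_error(fit_topics(list(character(0)), K = 1), "non-empty")
})

test_that("share arithmetic and the sum-to-100 invariant hold", {
  expect_equal(round(topic_shares(c(6021, 15302 - 6021))[1], 2), 39.35)
  set.seed(4)
  v <- sample(1:500, 7)
  expect_equal(sum(topic_shares(v)), 100, tolerance = 1e-9)
  docs <- replicate(40, sample(letters, 6, replace = TRUE), simplify = FALSE)
  m <- fit_topics(docs, K = 3, seed = 2, prominence_margin = 0)
  expect_equal(sum(m$shares), 100, tolerance = 1e-9)
  # deterministic under a fixed seed
  m2 <- fit_topics(docs, K = 3, seed = 2, prominence_margin = 0)
  expect_identical(m$doc_topic, m2$doc_topic)
})

test_that("two planted disjoint vocabularies are recovered at K = 2", {
  set.seed(12)
  vocab_a <- paste0("alpha", 1:10)
  vocab_b <- paste0("beta", 1:10)
  docs <- c(replicate(80, sample(vocab_a, 8, replace = TRUE), simplify = FALSE),
            replicate(80, sample(vocab_b, 8, replace = TRUE), simplify = FALSE))
  truth <- rep(1:2, each = 80)
  m <- fit_topics(docs, K = 2, seed = 6)
  tab <- table(m$doc_topic$dominant_topic, truth)
  purity <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(purity, 0.9)
})

test_that("RAKE scores match hand-computed degree/frequency arithmetic", {
  kp <- extract_keyphrases(list(c("panic", "buying", "spreads"),
                                c("panic", "buying", "continues")),
                           stop_words = c("spreads", "continues"))
  expect_equal(kp$phrase[1], "panic buying")
  expect_equal(kp$score[1], 4)
  expect_equal(kp$n[1], 2L)

  single <- extract_keyphrases(list("covid"), stop_words = character())
  expect_equal(single$phrase, "covid")
  expect_equal(single$score, 1)

  expect_equal(nrow(extract_keyphrases(list(c("the", "and")),
                                       stop_words = c("the", "and"))), 0)
})

test_that("topic association links shared vocabularies across phases", {
  # orthogonal embedding for two planted vocabularies
  terms <- c(paste0("alpha", 1:5), paste0("beta", 1:5))
  vec <- rbind(matrix(rep(c(1, 0), each = 5), 5),
               matrix(rep(c(0, 1), each = 5), 5))
  rownames(vec) <- terms
  emb <- fake_embedding(vec)
  mk_model <- function(phase, vocabs) {
    K <- length(vocabs)
    tt <- do.call(rbind, lapply(seq_len(K), function(t) {
      tibble::tibble(topic = t, rank = 1:5, term = vocabs[[t]],
                     weight = rep(0.2, 5))
    }))
    structure(list(K = K, phase = phase, topic_terms = tt,
                   labels = vapply(vocabs, function(v) paste(v[1:3], collapse = "+"), ""),
                   volumes = rep(10L, K), shares = topic_shares(rep(10L, K))),
              class = "topic_model")
  }
  m1 <- mk_model("prepandemic", list(paste0("alpha", 1:5)))
  m2 <- mk_model("first_lockdown", list(paste0("alpha", 1:5), paste0("beta", 1:5)))
  assoc <- associate_topics(list(m1, m2), emb, m = 5, threshold = 0.5)
  # identical term sets across phases: similarity 1
  expect_equal(nrow(assoc$edges), 1)
  expect_equal(assoc$edges$similarity, 1, tolerance = 1e-12)
  expect_equal(assoc$edges$topic_a, 1)
  # orthogonal vocabularies never connect; raising the threshold never adds edges
  assoc_hi <- associate_topics(list(m1, m2), emb, m = 5, threshold = 0.99)
  expect_lte(nrow(assoc_hi$edges), nrow(assoc$edges))
  expect_error(associate_topics(list(m1), emb), ">= 2 phases")
})

test_that("a vocabulary planted in all four phases forms one connected component", {
  set.seed(31)
  shared <- paste0("common", 1:8)
  phases <- default_phase_windows()$name
  models <- lapply(phases, function(ph) {
    own <- paste0(substr(ph, 1, 4), 1:8)
    docs <- c(replicate(40, sample(shared, 6, replace = TRUE), simplify = FALSE),
              replicate(40, sample(own, 6, replace = TRUE), simplify = FALSE))
    fit_topics(docs, K = 2, seed = 7, phase = ph)
  })
  all_terms <- unique(unlist(lapply(models, function(m) m$topic_terms$term)))
  # embedding: shared terms on one axis, phase-specific terms orthogonal per phase
  axis <- 1 + as.integer(factor(sub("[0-9]+$", "", all_terms)))
  vec <- matrix(0, length(all_terms), max(axis))
  vec[cbind(seq_along(all_terms), axis)] <- 1
  rownames(vec) <- all_terms
  assoc <- associate_topics(models, fake_embedding(vec), m = 5, threshold = 0.8)
  comp <- association_components(assoc)
  sizes <- table(comp)
  expect_gte(max(sizes), 4) # the shared topic spans all four phases
})

test_that("coherence-based selection finds the planted topic count", {
  set.seed(14)
  vocabs <- list(paste0("a", 1:8), paste0("b", 1:8), paste0("c", 1:8))
  docs <- unlist(lapply(vocabs, function(v) {
    replicate(50, sample(v, 6, replace = TRUE), simplify = FALSE)
  }), recursive = FALSE)
  expect_equal(select_topic_count(docs, grid = 2:4, seed = 3), 3)
})
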