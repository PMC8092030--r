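# Shared fixtures, all generated in code.

# A tiny hand-made lexicon for scoring tests.
tiny_lexicon <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r) {
    tibble::tibble(emotion = r[[1]], term = r[[2]],
                   weight = as.numeric(r[[3]]),
                   provenance = if (length(r) > 3) r[[4]] else "seed")
  }))
  structure(df, class = c("emotion_lexicon", class(df)))
}

# A small synthetic corpus shared by several tests (cheap: ~800 posts).
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      v <- build_default_vocabulary()
      scen <- default_scenarios(200)
      cache <<- generate_corpus(v, scen, n_users = 60, bot_fraction = 0,
                                seed = 101)
    }
    cache
  }
})

# Hand-built embedding model with unit vectors at chosen angles; enough for
# expand_lexicons, which only reads $vectors.
fake_embedding <- function(vectors) {
  structure(list(vectors = vectors,
                 counts = setNames(rep(10L, nrow(vectors)), rownames(vectors)),
                 params = list(d = ncol(vectors))),
            class = "embedding_model")
}

# Independent brute-force oracle: count adjacent pairs by direct enumeration
# over all (i, i+1) index pairs of each sequence.
brute_force_transition_counts <- function(seqs) {
  emo <- plutchik_emotions()
  C <- matrix(0L, 8, 8, dimnames = list(emo, emo))
  for (s in seqs) {
    if (length(s) < 2) next
    for (i in seq_len(length(s) - 1)) {
      C[s[i], s[i + 1]] <- C[s[i], s[i + 1]] + 1L
    }
  }
  C
}

# Two well-separated Gaussian blobs in [0,1]^4 (the planted-cluster GSOM
# benchmark).
gaussian_blobs <- function(n_per = 200, sd = 0.05, seed = 11) {
  set.seed(seed)
  c1 <- c(0.2, 0.2, 0.8, 0.8)
  c2 <- c(0.8, 0.8, 0.2, 0.2)
  X <- rbind(
    matrix(rep(c1, each = n_per), n_per) + matrix(rnorm(4 * n_per, 0, sd), n_per),
    matrix(rep(c2, each = n_per), n_per) + matrix(rnorm(4 * n_per, 0, sd), n_per))
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- paste0("u", seq_len(2 * n_per))
  list(X = X, blob = rep(1:2, each = n_per))
}

# Published two-lockdown normalized intensity columns (percent) and their
# observation counts, used by the statistical-reproduction tests.
published_lockdown_profiles <- function() {
  first <- c(anger = 13.84, sadness = 31.36, disgust = 9.81, fear = 17.58,
             joy = 16.94, surprise = 1.32, trust = 6.56, anticipation = 2.59)
  second <- c(anger = 15.97, sadness = 31.01, disgust = 12.06, fear = 19.66,
              joy = 12.56, surprise = 0.74, trust = 5.63, anticipation = 2.37)
  list(
    first = intensity_profile_from_percentages(first, 36317, "first_lockdown"),
    second = intensity_profile_from_percentages(second, 10604, "second_lockdown"))
}
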