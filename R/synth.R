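# Synthetic tweet-stream generator with known ground truth. Every downstream
# stage (lexicon expansion, emotion scoring, transitions, topics, GSOM,
# statistics) can be exercised against the planted truth without any
# platform data.

#' Build the default synthetic vocabulary specification
#'
#' Returns a deterministic vocabulary with, per Plutchik emotion, a set of
#' seed terms (these double as the packaged seed lexicon) and a larger set of
#' satellite terms planted to co-occur with the seeds, so that embedding
#' training can recover them as lexicon neighbors. Also carries negators,
#' multiplicative intensifiers (> 1) and inhibitors (in (0,1)), four topical
#' vocabularies, and neutral filler terms. All emotion term sets are pairwise
#' disjoint.
#'
#' @param seed Integer; kept for interface symmetry — the default vocabulary
#'   is a fixed list, so any seed yields the identical specification.
#' @return A list of class `vocabulary_spec` with elements `seeds`,
#'   `satellites`, `intensifiers`, `inhibitors`, `negators`, `topic_vocab`,
#'   `filler`.
#' @export
#' @examples
#' v <- build_default_vocabulary()
#' names(v$seeds)
build_default_vocabulary <- function(seed = 1L) {
  seeds <- list(
    anger        = c("angry", "furious", "rage", "outraged", "irritated", "mad"),
    sadness      = c("sad", "grief", "sorrow", "miserable", "heartbroken", "depressed"),
    disgust      = c("disgusted", "revolting", "gross", "repulsive", "vile", "sickened"),
    fear         = c("scared", "afraid", "terrified", "panic", "dread", "frightening"),
    joy          = c("happy", "delighted", "cheerful", "glad", "thrilled", "joyful"),
    surprise     = c("surprised", "astonished", "shocked", "unexpected", "stunned", "startling"),
    trust        = c("trust", "faith", "reliable", "confident", "assured", "dependable"),
    anticipation = c("anticipation", "expecting", "hopeful", "eager", "awaiting", "keen")
  )
  satellites <- list(
    anger        = c("fuming", "seething", "livid", "irate", "enraged", "resentful",
                     "hostile", "annoyed", "aggravated", "wrathful", "indignant", "incensed"),
    sadness      = c("mournful", "tearful", "gloomy", "despair", "sorrowful", "downcast",
                     "dejected", "melancholy", "weeping", "heartache", "forlorn", "grieving"),
    disgust      = c("nauseating", "sickening", "repugnant", "foul", "loathsome", "distasteful",
                     "offensive", "putrid", "revulsion", "abhorrent", "yucky", "grotesque"),
    fear         = c("frightened", "fearful", "horrified", "anxious", "alarmed", "panicked",
                     "terrifying", "dreadful", "uneasy", "apprehensive", "spooked", "petrified"),
    joy          = c("elated", "ecstatic", "jubilant", "gleeful", "blissful", "merry",
                     "upbeat", "overjoyed", "radiant", "euphoric", "smiling", "laughing"),
    surprise     = c("startled", "amazed", "astounded", "flabbergasted", "dumbfounded",
                     "speechless", "bewildered", "staggering", "jawdropping", "unforeseen",
                     "sudden", "baffled"),
    trust        = c("trustworthy", "loyal", "faithful", "credible", "honest", "sincere",
                     "steadfast", "devoted", "reassuring", "safeguard", "certainty", "believing"),
    anticipation = c("expectant", "forthcoming", "upcoming", "optimistic", "longing",
                     "foresee", "preparing", "readiness", "countdown", "yearning",
                     "impatient", "planning")
  )
  topic_vocab <- list(
    lockdown_policy = c("lockdown", "restrictions", "curfew", "government", "rules",
                        "mandate", "border", "police"),
    health          = c("hospital", "vaccine", "virus", "symptoms", "testing", "cases",
                        "doctor", "ward"),
    economy         = c("jobs", "economy", "payment", "business", "wages",
                        "unemployment", "rent", "market"),
    education       = c("school", "students", "homeschool", "university", "teachers",
                        "classes", "exams", "assignments")
  )
  vocab <- list(
    seeds = seeds,
    satellites = satellites,
    intensifiers = c(very = 1.5, extremely = 1.5, really = 1.5),
    inhibitors = c(slightly = 0.5, somewhat = 0.5, barely = 0.5),
    negators = c("not", "never", "no", "hardly"),
    topic_vocab = topic_vocab,
    filler = c("weekend", "morning", "weather", "coffee", "street", "update",
               "thread", "thinking", "watching", "reading", "evening", "walk")
  )
  class(vocab) <- "vocabulary_spec"
  validate_vocabulary(vocab)
  vocab
}

validate_vocabulary <- function(vocab) {
  emo <- plutchik_emotions()
  stopifnot(setequal(names(vocab$seeds), emo), setequal(names(vocab$satellites), emo))
  sets <- lapply(emo, function(e) c(vocab$seeds[[e]], vocab$satellites[[e]]))
  all_terms <- unlist(sets)
  if (anyDuplicated(all_terms)) {
    stop("emotion term sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_terms[duplicated(all_terms)]), collapse = ", "))
  }
  if (any(lengths(vocab$seeds) < 1) || any(lengths(vocab$satellites) < 1)) {
    stop("every emotion needs at least one seed and one satellite term")
  }
  mult <- c(vocab$intensifiers, vocab$inhibitors)
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("modifier multipliers must be finite and positive")
  }
  invisible(vocab)
}

#' Define a phase scenario for the synthetic generator
#'
#' @param phase Phase name.
#' @param window Length-2 `Date` (or coercible) vector, inclusive start/end;
#'   must lie in 2020-01-01..2020-09-30.
#' @param emotion_mixture Named (or canonical-order) vector of 8 non-negative
#'   weights summing to 1.
#' @param topic_mixture Named weights over topic names summing to 1.
#' @param n_posts Number of posts to generate for this phase.
#' @param transition_matrix Optional 8x8 row-stochastic matrix; when given,
#'   consecutive posts in a conversation carry emotion labels sampled from
#'   this chain (first post from `emotion_mixture`).
#' @return A list of class `phase_scenario`.
#' @export
phase_scenario <- function(phase, window, emotion_mixture, topic_mixture,
                           n_posts, transition_matrix = NULL) {
  emo <- plutchik_emotions()
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[1] > window[2]) {
    stop("window must be two ordered dates")
  }
  if (window[1] < as.Date("2020-01-01") || window[2] > as.Date("2020-09-30")) {
    stop("window must lie within 2020-01-01..2020-09-30")
  }
  if (is.null(names(emotion_mixture))) names(emotion_mixture) <- emo
  emotion_mixture <- emotion_mixture[emo]
  check_mixture(emotion_mixture, "emotion_mixture")
  check_mixture(topic_mixture, "topic_mixture")
  if (!is.null(transition_matrix)) {
    check_row_stochastic(transition_matrix)
    if (nrow(transition_matrix) != 8) stop("transition_matrix must be 8x8")
    dimnames(transition_matrix) <- list(emo, emo)
  }
  structure(list(phase = phase, window = window,
                 emotion_mixture = emotion_mixture,
                 topic_mixture = topic_mixture,
                 n_posts = as.integer(n_posts),
                 transition_matrix = transition_matrix),
            class = "phase_scenario")
}

#' Generate a synthetic post corpus with ground truth
#'
#' Posts are threaded into conversations of geometric length (mean
#' `mean_thread_len`), timestamps drawn uniformly within each scenario
#' window, and each post carries a true emotion label drawn from the
#' scenario's mixture (or its transition chain within a conversation). Token
#' composition per post: about 30% neutral filler; of the non-filler tokens
#' at least 70% come from the true emotion's seed+satellite vocabulary
#' (guaranteeing the >=60% contract), the remainder from a topic vocabulary.
#' With probability `negation_prob` a negator is inserted immediately before
#' one emotion term. Bot accounts (a `bot_fraction` of users) re-emit
#' duplicated text at 20x the median per-user organic volume, on top of the
#' organic `sum(n_posts)` posts.
#'
#' @param vocab A `vocabulary_spec`.
#' @param scenarios List of `phase_scenario`s with disjoint windows.
#' @param n_users Number of user accounts.
#' @param bot_fraction Fraction of users that behave as bots (in [0, 1)).
#' @param negation_prob Per-post probability of inserting a negator before an
#'   emotion term.
#' @param mean_thread_len Mean conversation length (geometric).
#' @param n_user_clusters Number of planted user behavior clusters; cluster
#'   members prefer one topic vocabulary with probability
#'   `cluster_topic_bias`.
#' @param cluster_topic_bias Probability a post's topical tokens come from
#'   the author's cluster-preferred topic rather than the conversation topic.
#' @param seed Integer seed; identical inputs give identical corpora.
#' @return List with `posts` (tibble: post_id, user_id, conversation_id,
#'   timestamp, text) and `ground_truth` (per-phase mixtures and transition
#'   matrices, per-term emotion assignment, per-post labels, user clusters,
#'   bot user ids).
#' @export
generate_corpus <- function(vocab, scenarios, n_users = 200,
                            bot_fraction = 0, negation_prob = 0.1,
                            mean_thread_len = 4, n_user_clusters = 2,
                            cluster_topic_bias = 0.7, seed = 1L) {
  validate_vocabulary(vocab)
  if (inherits(scenarios, "phase_scenario")) scenarios <- list(scenarios)
  if (bot_fraction < 0 || bot_fraction >= 1) stop("bot_fraction must be in [0, 1)")
  windows <- lapply(scenarios, `[[`, "window")
  if (length(scenarios) > 1) {
    ord <- order(vapply(windows, function(w) as.numeric(w[1]), 0))
    for (i in seq_len(length(ord) - 1)) {
      if (windows[[ord[i]]][2] >= windows[[ord[i + 1]]][1]) {
        stop("scenario windows must be disjoint")
      }
    }
  }
  emo <- plutchik_emotions()
  topics <- names(vocab$topic_vocab)

  with_seed(seed, {
    n_bots <- as.integer(floor(bot_fraction * n_users))
    user_ids <- sprintf("user%04d", seq_len(n_users))
    bot_ids <- if (n_bots > 0) sample(user_ids, n_bots) else character(0)
    organic_users <- setdiff(user_ids, bot_ids)
    cluster_of <- setNames(
      rep_len(seq_len(max(1, n_user_clusters)), length(organic_users)),
      organic_users)
    pref_topic <- topics[(cluster_of - 1) %% length(topics) + 1]
    names(pref_topic) <- organic_users

    rows <- vector("list", sum(vapply(scenarios, `[[`, 0L, "n_posts")))
    labels <- character(length(rows))
    post_topics <- character(length(rows))
    phases <- character(length(rows))
    negated <- logical(length(rows))
    ri <- 0L
    conv_counter <- 0L

    for (sc in scenarios) {
      remaining <- sc$n_posts
      t0 <- as.POSIXct(paste(sc$window[1], "00:00:00"), tz = "UTC")
      t1 <- as.POSIXct(paste(sc$window[2] + 1, "00:00:00"), tz = "UTC")
      span <- as.numeric(difftime(t1, t0, units = "secs"))
      while (remaining > 0) {
        conv_counter <- conv_counter + 1L
        len <- min(rgeom(1, 1 / mean_thread_len) + 1L, remaining)
        conv_id <- sprintf("conv%06d", conv_counter)
        conv_topic <- sample(names(sc$topic_mixture), 1, prob = sc$topic_mixture)
        times <- sort(t0 + runif(len, 0, span - 1))
        lab <- character(len)
        lab[1] <- sample(emo, 1, prob = sc$emotion_mixture)
        if (len > 1) {
          for (j in 2:len) {
            lab[j] <- if (is.null(sc$transition_matrix)) {
              sample(emo, 1, prob = sc$emotion_mixture)
            } else {
              sample(emo, 1, prob = sc$transition_matrix[lab[j - 1], ])
            }
          }
        }
        authors <- sample(organic_users, len, replace = TRUE)
        for (j in seq_len(len)) {
          ri <- ri + 1L
          topic_j <- if (runif(1) < cluster_topic_bias) pref_topic[[authors[j]]] else conv_topic
          gen <- synth_post_text(vocab, lab[j], topic_j, negation_prob)
          rows[[ri]] <- list(post_id = sprintf("post%07d", ri),
                             user_id = authors[j],
                             conversation_id = conv_id,
                             timestamp = times[j],
                             text = gen$text)
          labels[ri] <- lab[j]
          post_topics[ri] <- topic_j
          phases[ri] <- sc$phase
          negated[ri] <- gen$negated
        }
        remaining <- remaining - len
      }
    }

    posts <- tibble::tibble(
      post_id = vapply(rows, `[[`, "", "post_id"),
      user_id = vapply(rows, `[[`, "", "user_id"),
      conversation_id = vapply(rows, `[[`, "", "conversation_id"),
      timestamp = as.POSIXct(vapply(rows, function(r) as.numeric(r$timestamp), 0),
                             origin = "1970-01-01", tz = "UTC"),
      text = vapply(rows, `[[`, "", "text"))

    post_labels <- tibble::tibble(post_id = posts$post_id, phase = phases,
                                  emotion = labels, topic = post_topics,
                                  negated = negated)

    # bot traffic: duplicated text at >= 20x the median organic volume
    if (n_bots > 0) {
      med <- stats::median(table(posts$user_id))
      per_bot <- as.integer(ceiling(20 * med))
      bot_rows <- vector("list", n_bots)
      for (b in seq_len(n_bots)) {
        src <- sample(nrow(posts), 1)
        sc <- scenarios[[sample(length(scenarios), 1,
                                prob = vapply(scenarios, `[[`, 0L, "n_posts"))]]
        t0 <- as.POSIXct(paste(sc$window[1], "00:00:00"), tz = "UTC")
        t1 <- as.POSIXct(paste(sc$window[2] + 1, "00:00:00"), tz = "UTC")
        tt <- sort(t0 + runif(per_bot, 0, as.numeric(difftime(t1, t0, units = "secs")) - 1))
        bot_rows[[b]] <- tibble::tibble(
          post_id = sprintf("bot%02dpost%05d", b, seq_len(per_bot)),
          user_id = bot_ids[b],
          conversation_id = sprintf("botconv%04d", b),
          timestamp = tt,
          text = posts$text[src])
      }
      posts <- rbind(posts, do.call(rbind, bot_rows))
    }

    term_emotions <- unlist(lapply(emo, function(e) {
      trms <- c(vocab$seeds[[e]], vocab$satellites[[e]])
      setNames(rep(e, length(trms)), trms)
    }))

    ground_truth <- list(
      emotion_mixtures = setNames(lapply(scenarios, `[[`, "emotion_mixture"),
                                  vapply(scenarios, `[[`, "", "phase")),
      transition_matrices = setNames(lapply(scenarios, `[[`, "transition_matrix"),
                                     vapply(scenarios, `[[`, "", "phase")),
      term_emotions = term_emotions,
      post_labels = post_labels,
      user_clusters = cluster_of,
      bot_users = bot_ids)

    list(posts = posts, ground_truth = ground_truth)
  })
}

# One post's token string. At least one token from the true emotion's
# vocabulary; >= 70% of non-filler tokens are emotion terms.
synth_post_text <- function(vocab, emotion, topic, negation_prob) {
  n_tok <- sample(8:25, 1)
  n_filler <- round(0.3 * n_tok)
  n_nf <- n_tok - n_filler
  n_emo <- max(1L, as.integer(ceiling(0.7 * n_nf)))
  n_top <- n_nf - n_emo
  emo_terms <- sample(c(vocab$seeds[[emotion]], vocab$satellites[[emotion]]),
                      n_emo, replace = TRUE)
  top_terms <- if (n_top > 0) {
    sample(vocab$topic_vocab[[topic]], n_top, replace = TRUE)
  } else character(0)
  fill <- sample(vocab$filler, n_filler, replace = TRUE)
  toks <- sample(c(emo_terms, top_terms, fill))
  neg <- FALSE
  if (runif(1) < negation_prob) {
    at <- which(toks %in% emo_terms)
    pos <- at[sample(length(at), 1)]
    toks <- append(toks, sample(vocab$negators, 1), after = pos - 1)
    neg <- TRUE
  }
  list(text = paste(toks, collapse = " "), negated = neg)
}

#' Write / read a corpus as JSON-lines
#'
#' One JSON object per line with fields `post_id`, `user_id`,
#' `conversation_id`, `timestamp` (ISO-8601 UTC) and `text`.
#'
#' @param posts Tibble as produced by [generate_corpus()].
#' @param path File path.
#' @return `write_corpus_jsonl` returns `path` invisibly; `read_corpus_jsonl`
#'   returns the posts tibble with POSIXct timestamps.
#' @export
write_corpus_jsonl <- function(posts, path) {
  df <- posts
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, "w")
  on.exit(close(con))
  jsonlite::stream_out(df, con, verbose = FALSE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tibble::as_tibble(df)
}
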