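# Post-level emotion scoring with negation flipping and valence modifiers,
# and per-conversation chronological emotion sequences.

#' Default negators and valence modifiers
#'
#' Modifiers compose multiplicatively; intensifiers have factor 1.5,
#' inhibitors 0.5. Negators flip a match to its Plutchik opposite (odd
#' number of negators in the window; an even count cancels out).
#'
#' @return `default_negators()`: character vector. `default_modifiers()`:
#'   named numeric vector of multiplicative factors.
#' @export
default_negators <- function() c("not", "never", "no", "hardly")

#' @rdname default_negators
#' @export
default_modifiers <- function() {
  c(very = 1.5, extremely = 1.5, really = 1.5,
    slightly = 0.5, somewhat = 0.5, barely = 0.5)
}

#' Score one post against the eight emotion lexicons
#'
#' Every lexicon match of term `t` (emotion `e`, weight `w`) contributes
#' `w * prod(modifier factors within `window` tokens before t)` to `e`. If
#' an odd number of negators occurs in that window the contribution goes to
#' the Plutchik opposite of `e` instead (or is discarded under
#' `negation_mode = "discard"`). The dominant emotion is the argmax of the
#' scores, ties broken by the fixed order
#' anger < sadness < disgust < fear < joy < surprise < trust < anticipation;
#' a post with no match has dominant `NA`.
#'
#' @param tokens Character vector of clean tokens.
#' @param lexicon An `emotion_lexicon`.
#' @param negators Character vector of negation terms.
#' @param modifiers Named numeric vector of multiplicative valence factors.
#' @param window Look-back window (tokens before the match) for negators and
#'   modifiers; must be >= 1.
#' @param negation_mode `"opposite"` (default) routes negated mass to the
#'   polar opposite emotion; `"discard"` drops it.
#' @return List of class `post_emotion`: `scores` (named length-8 vector),
#'   `dominant` (emotion name or `NA`), `matches` (tibble).
#' @export
#' @examples
#' lex <- structure(tibble::tibble(emotion = "joy", term = "happy",
#'   weight = 1, provenance = "seed"), class = c("emotion_lexicon", "tbl_df",
#'   "tbl", "data.frame"))
#' score_post(c("not", "happy"), lex)$dominant  # "sadness"
score_post <- function(tokens, lexicon, negators = default_negators(),
                       modifiers = default_modifiers(), window = 3,
                       negation_mode = c("opposite", "discard")) {
  negation_mode <- match.arg(negation_mode)
  if (window < 1) stop("window must be >= 1")
  emo <- plutchik_emotions()
  scores <- setNames(numeric(8), emo)
  term_emotion <- setNames(lexicon$emotion, lexicon$term)
  term_weight <- setNames(lexicon$weight, lexicon$term)

  hit <- which(tokens %in% names(term_emotion))
  m_term <- character(0); m_emo <- character(0)
  m_w <- numeric(0); m_f <- numeric(0); m_neg <- logical(0)
  for (i in hit) {
    t <- tokens[i]
    e <- term_emotion[[t]]
    w <- term_weight[[t]]
    span <- if (i > 1) tokens[max(1, i - window):(i - 1)] else character(0)
    fac <- prod(modifiers[span[span %in% names(modifiers)]])
    negd <- sum(span %in% negators) %% 2 == 1
    target <- e
    if (negd) {
      if (negation_mode == "discard") {
        m_term <- c(m_term, t); m_emo <- c(m_emo, e)
        m_w <- c(m_w, w); m_f <- c(m_f, fac); m_neg <- c(m_neg, TRUE)
        next
      }
      target <- plutchik_opposite(e)
    }
    scores[target] <- scores[target] + w * fac
    m_term <- c(m_term, t); m_emo <- c(m_emo, target)
    m_w <- c(m_w, w); m_f <- c(m_f, fac); m_neg <- c(m_neg, negd)
  }
  dominant <- if (max(scores) > 0) emo[which.max(scores)] else NA_character_
  structure(list(scores = scores, dominant = dominant,
                 matches = tibble::tibble(term = m_term, emotion = m_emo,
                                          weight = m_w, modifier_factor = m_f,
                                          negated = m_neg)),
            class = "post_emotion")
}

#' @export
print.post_emotion <- function(x, ...) {
  cat("<post_emotion> dominant:", ifelse(is.na(x$dominant), "none", x$dominant), "\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' Score a corpus of preprocessed posts
#'
#' Applies [score_post()] to every post and returns a per-post emotion
#' table.
#'
#' @param posts Tibble with `post_id`, `clean_tokens` (list-column), and
#'   optionally `phase`, `conversation_id`, `timestamp` (carried through).
#' @inheritParams score_post
#' @return Tibble: carried id columns, one numeric column per emotion,
#'   `dominant`, and `n_matches`.
#' @export
score_posts <- function(posts, lexicon, negators = default_negators(),
                        modifiers = default_modifiers(), window = 3,
                        negation_mode = "opposite") {
  emo <- plutchik_emotions()
  res <- lapply(posts$clean_tokens, score_post, lexicon = lexicon,
                negators = negators, modifiers = modifiers, window = window,
                negation_mode = negation_mode)
  sc <- do.call(rbind, lapply(res, `[[`, "scores"))
  carried <- intersect(c("post_id", "conversation_id", "timestamp", "phase"),
                       names(posts))
  out <- tibble::as_tibble(posts[, carried, drop = FALSE])
  out <- cbind(out, tibble::as_tibble(as.data.frame(sc)))
  out$dominant <- vapply(res, `[[`, "", "dominant")
  out$n_matches <- vapply(res, function(r) nrow(r$matches), 0L)
  tibble::as_tibble(out)
}

#' Build chronological per-conversation emotion sequences
#'
#' One sequence per conversation per phase, ordered by timestamp (ties by
#' post id); posts without a dominant emotion are skipped, so sequences
#' never contain neutral entries. Conversations whose posts are all neutral
#' emit no sequence.
#'
#' @param scored Tibble from [score_posts()] with `conversation_id`,
#'   `timestamp`, `post_id`, `phase`, `dominant`.
#' @return Tibble with `conversation_id`, `phase`, `labels` (list-column of
#'   emotion label vectors) and `length`.
#' @export
build_sequences <- function(scored) {
  keep <- scored[!is.na(scored$dominant), , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble::tibble(conversation_id = character(0), phase = character(0),
                          labels = list(), length = integer(0)))
  }
  keep <- keep[order(keep$timestamp, keep$post_id), , drop = FALSE]
  grp <- split(keep$dominant, paste(keep$conversation_id, keep$phase, sep = "\r"))
  ids <- strsplit(names(grp), "\r", fixed = TRUE)
  tibble::tibble(
    conversation_id = vapply(ids, `[[`, "", 1),
    phase = vapply(ids, `[[`, "", 2),
    labels = unname(grp),
    length = lengths(grp))
}
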