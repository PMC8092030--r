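# Cleaning, bot/duplicate filtering, anonymization and phase assignment.

#' Tokenize and clean one raw post
#'
#' Lowercases, removes URLs and @-handles, reduces `#tag` to `tag`, splits
#' into maximal alphabetic runs, and drops stop words. Terms listed in
#' `protect` (by default negators and valence modifiers, which the scoring
#' rules need) survive stop-word removal.
#'
#' @param raw A single character string (UTF-8).
#' @param stop_words Character vector of stop words.
#' @param protect Terms never removed even if they are stop words.
#' @return Character vector of clean tokens (possibly empty).
#' @export
#' @examples
#' clean_text("Check https://t.co/abc COVID!! @user", stop_words = "check")
clean_text <- function(raw, stop_words = character(),
                       protect = default_protected_terms()) {
  stopifnot(length(raw) == 1)
  if (is.na(raw) || !nzchar(raw)) return(character(0))
  x <- tolower(raw)
  x <- gsub("https?://\\S+|www\\.\\S+", " ", x)
  x <- gsub("@\\w+", " ", x)
  toks <- regmatches(x, gregexpr("[a-z]+", x))[[1]]
  drop <- setdiff(tolower(stop_words), tolower(protect))
  toks[!(toks %in% drop)]
}

#' Tokenize a vector of raw posts
#'
#' @param texts Character vector.
#' @inheritParams clean_text
#' @return List of token vectors, one per input text.
#' @export
tokenize_posts <- function(texts, stop_words = character(),
                           protect = default_protected_terms()) {
  lapply(texts, clean_text, stop_words = stop_words, protect = protect)
}

#' Terms protected from stop-word removal
#'
#' Negators and the default valence modifiers must survive cleaning for the
#' negation-flip and intensity rules to apply.
#'
#' @return Character vector.
#' @export
default_protected_terms <- function() {
  c(default_negators(), names(default_modifiers()))
}

#' Default English stop words
#'
#' A compact stop-word list shipped with the package (one term per line in
#' `inst/extdata/stopwords.txt`).
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  readLines(system.file("extdata", "stopwords.txt", package = "emovista"),
            warn = FALSE)
}

#' Remove bot/news accounts and duplicated posts; anonymize authors
#'
#' Users whose post count exceeds the `volume_percentile` quantile of
#' per-user counts are removed entirely (the paper filters accounts with an
#' unusual posting volume; a quantile rule makes that reproducible). Within
#' a user, a text repeated more than `dup_threshold` times keeps only its
#' first occurrence. Remaining user ids are replaced by salted hashes.
#'
#' @param posts Posts tibble with `user_id` and `text` columns.
#' @param volume_percentile Quantile in (0, 1] for the volume cut.
#' @param dup_threshold Maximum tolerated repetitions of an identical text
#'   per user before deduplication kicks in.
#' @param salt Salt for the anonymizing hash.
#' @return List with `posts` (filtered, user ids hashed) and `removed_users`
#'   (original ids of removed accounts).
#' @export
filter_accounts <- function(posts, volume_percentile = 0.99,
                            dup_threshold = 1, salt = "emovista") {
  if (nrow(posts) == 0) stop("posts must be non-empty")
  if (volume_percentile <= 0 || volume_percentile > 1) {
    stop("volume_percentile must be in (0, 1]")
  }
  counts <- table(posts$user_id)
  cut <- stats::quantile(as.numeric(counts), volume_percentile, names = FALSE)
  removed <- names(counts)[as.numeric(counts) > cut]
  kept <- posts[!(posts$user_id %in% removed), , drop = FALSE]

  # per-user duplicate collapse: texts repeated more than dup_threshold
  # times keep only the first occurrence (chronological input order)
  key <- paste(kept$user_id, kept$text, sep = "\r")
  reps <- ave(seq_along(key), key, FUN = seq_along)
  tot <- ave(seq_along(key), key, FUN = length)
  keep_row <- tot <= dup_threshold | reps == 1
  kept <- kept[keep_row, , drop = FALSE]

  kept$user_id <- salted_hash(kept$user_id, salt = salt)
  list(posts = kept, removed_users = removed)
}

#' Default pandemic phase windows
#'
#' Literal month boundaries of the four 2020 phases: prepandemic
#' (January-February), first lockdown (March-May), easing of restrictions
#' (June), second lockdown (July-September).
#'
#' @return Tibble with columns `name`, `start`, `end` (inclusive dates).
#' @export
default_phase_windows <- function() {
  tibble::tibble(
    name = c("prepandemic", "first_lockdown", "easing_restrictions", "second_lockdown"),
    start = as.Date(c("2020-01-01", "2020-03-01", "2020-06-01", "2020-07-01")),
    end = as.Date(c("2020-02-29", "2020-05-31", "2020-06-30", "2020-09-30")))
}

#' Assign timestamps to pandemic phases
#'
#' @param timestamp Date/POSIXct vector.
#' @param windows Phase windows as from [default_phase_windows()].
#' @return Character vector of phase names.
#' @export
#' @examples
#' assign_phase(as.Date("2020-01-15"))  # "prepandemic"
assign_phase <- function(timestamp, windows = default_phase_windows()) {
  d <- as.Date(timestamp, tz = "UTC")
  out <- rep(NA_character_, length(d))
  for (i in seq_len(nrow(windows))) {
    hit <- d >= windows$start[i] & d <= windows$end[i]
    out[hit] <- windows$name[i]
  }
  if (anyNA(out)) {
    stop("timestamp(s) outside all phase windows: ",
         paste(unique(format(d[is.na(out)])), collapse = ", "))
  }
  out
}

#' Run the full preprocessing stage on a raw corpus
#'
#' Filters accounts and duplicates, anonymizes, tokenizes, and assigns
#' phases.
#'
#' @param posts Raw posts tibble.
#' @inheritParams filter_accounts
#' @param stop_words Stop words for tokenization.
#' @param windows Phase windows.
#' @return List with `posts` (tibble incl. `clean_tokens` list-column and
#'   `phase`) and `removed_users`.
#' @export
preprocess_corpus <- function(posts, volume_percentile = 0.99,
                              dup_threshold = 1, salt = "emovista",
                              stop_words = default_stopwords(),
                              windows = default_phase_windows()) {
  flt <- filter_accounts(posts, volume_percentile, dup_threshold, salt)
  out <- flt$posts
  out$clean_tokens <- tokenize_posts(out$text, stop_words = stop_words)
  out$phase <- assign_phase(out$timestamp, windows)
  list(posts = out, removed_users = flt$removed_users)
}
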