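# Per-phase normalized emotion intensity profiles.

#' Aggregate post-level scores into a phase intensity profile
#'
#' Raw intensity of an emotion is the sum of its post-level scores over the
#' phase; normalized intensities rescale the eight raw totals to sum to
#' 100%. `n_observations` counts (post, emotion) cells with a nonzero
#' contribution — an observation-level denominator, since a single post can
#' express several emotions.
#'
#' @param scored Tibble from [score_posts()] (must contain the eight emotion
#'   columns and a `phase` column unless `phase` is `NULL` and the whole
#'   table is one phase).
#' @param phase Phase to profile; `NULL` uses all rows.
#' @return Object of class `intensity_profile`: `phase`, `raw`,
#'   `normalized` (percentages summing to 100), `n_observations`.
#' @export
phase_intensity_profile <- function(scored, phase = NULL) {
  emo <- plutchik_emotions()
  rows <- if (is.null(phase)) scored else scored[scored$phase %in% phase, , drop = FALSE]
  if (nrow(rows) == 0) stop("no posts in phase ", phase)
  m <- as.matrix(rows[, emo, drop = FALSE])
  raw <- colSums(m)
  if (sum(raw) == 0) stop("all emotion scores are zero in phase ", phase)
  structure(list(phase = if (is.null(phase)) NA_character_ else phase,
                 raw = raw,
                 normalized = 100 * raw / sum(raw),
                 n_observations = sum(m > 0)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("<intensity_profile> phase: %s (n=%d observations)\n",
              x$phase, x$n_observations))
  print(round(x$normalized, 2))
  invisible(x)
}

#' Construct an intensity profile directly from printed percentages
#'
#' Useful for comparing against published tables where only the normalized
#' column and its n are available.
#'
#' @param normalized Named length-8 vector of percentages (summing to 100).
#' @param n_observations Observation count behind the percentages.
#' @param phase Phase name.
#' @return An `intensity_profile`.
#' @export
intensity_profile_from_percentages <- function(normalized, n_observations,
                                               phase = NA_character_) {
  emo <- plutchik_emotions()
  if (is.null(names(normalized))) names(normalized) <- emo
  normalized <- normalized[emo]
  if (abs(sum(normalized) - 100) > 0.02) {
    stop("normalized percentages must sum to 100")
  }
  structure(list(phase = phase, raw = normalized,
                 normalized = 100 * normalized / sum(normalized),
                 n_observations = as.integer(n_observations)),
            class = "intensity_profile")
}

#' Tidy table of one or more intensity profiles
#'
#' @param profiles A single `intensity_profile` or a list of them.
#' @return Tibble with `phase`, `emotion`, `raw`, `normalized`, `n`.
#' @export
intensity_table <- function(profiles) {
  if (inherits(profiles, "intensity_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    tibble::tibble(phase = p$phase, emotion = names(p$normalized),
                   raw = unname(p$raw), normalized = unname(p$normalized),
                   n = p$n_observations)
  }))
}
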