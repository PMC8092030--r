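# First-order Markov emotion-transition models estimated from
# per-conversation emotion sequences.

#' Estimate a Markov emotion-transition model
#'
#' Counts adjacent label pairs within each conversation sequence (never
#' across conversations) and row-normalizes to transition probabilities.
#' Rows whose source emotion was never observed are undefined (`NA`) unless
#' Laplace smoothing is requested.
#'
#' @param sequences Tibble from [build_sequences()] (or a plain list of
#'   label vectors).
#' @param phase Optional phase filter.
#' @param smoothing Laplace pseudo-count alpha added to every cell before
#'   normalization; 0 (default) reproduces raw frequency normalization.
#' @return Object of class `transition_model`: `phase`, `labels`, `C`
#'   (8x8 integer count matrix), `P` (8x8 row-stochastic, `NA` rows where
#'   undefined), `n_transitions`.
#' @export
estimate_transition_model <- function(sequences, phase = NULL, smoothing = 0) {
  emo <- plutchik_emotions()
  seqs <- if (is.data.frame(sequences)) {
    if (!is.null(phase)) {
      sequences$labels[sequences$phase %in% phase]
    } else {
      sequences$labels
    }
  } else {
    sequences
  }
  seqs <- seqs[lengths(seqs) >= 2]
  if (length(seqs) == 0) stop("no sequence of length >= 2",
                              if (!is.null(phase)) paste0(" in phase ", phase))
  C <- matrix(0L, 8, 8, dimnames = list(emo, emo))
  for (s in seqs) {
    from <- s[-length(s)]
    to <- s[-1]
    for (i in seq_along(from)) C[from[i], to[i]] <- C[from[i], to[i]] + 1L
  }
  rs <- rowSums(C)
  P <- matrix(NA_real_, 8, 8, dimnames = list(emo, emo))
  for (i in seq_len(8)) {
    denom <- rs[i] + 8 * smoothing
    if (denom > 0) P[i, ] <- (C[i, ] + smoothing) / denom
  }
  structure(list(phase = if (is.null(phase)) NA_character_ else phase,
                 labels = emo, C = C, P = P, n_transitions = sum(C)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> phase: %s, %d transitions, undefined rows: %d\n",
              x$phase, x$n_transitions, sum(is.na(x$P[, 1]))))
  print(round(x$P, 3))
  invisible(x)
}

#' Top-k emotion transitions by probability
#'
#' Observed transitions (count >= 1) sorted by probability descending, ties
#' by count descending then by the fixed label order.
#'
#' @param model A `transition_model`.
#' @param k Number of transitions to return.
#' @return Tibble with `from`, `to`, `count`, `probability`.
#' @export
top_transitions <- function(model, k = 5) {
  emo <- model$labels
  idx <- which(model$C >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(from = character(0), to = character(0),
                          count = integer(0), probability = numeric(0)))
  }
  df <- tibble::tibble(from = emo[idx[, 1]], to = emo[idx[, 2]],
                       count = model$C[idx],
                       probability = model$P[idx])
  ord <- order(-df$probability, -df$count,
               match(df$from, emo), match(df$to, emo))
  head(df[ord, ], k)
}

#' Simulate emotion sequences from a known transition matrix
#'
#' Used for parameter-recovery checks: sequences start from `init`
#' (default uniform) and follow the chain `P`.
#'
#' @param P 8x8 row-stochastic matrix (canonical emotion order).
#' @param n_sequences Number of sequences.
#' @param length_per_sequence Length of each sequence.
#' @param init Initial state distribution (default uniform).
#' @param seed Integer seed.
#' @return List of character label vectors.
#' @export
simulate_emotion_sequences <- function(P, n_sequences, length_per_sequence,
                                       init = NULL, seed = 1L) {
  emo <- plutchik_emotions()
  check_row_stochastic(P)
  if (is.null(init)) init <- rep(1 / 8, 8)
  with_seed(seed, {
    lapply(seq_len(n_sequences), function(i) {
      s <- character(length_per_sequence)
      s[1] <- sample(emo, 1, prob = init)
      for (j in seq_len(length_per_sequence - 1)) {
        s[j + 1] <- sample(emo, 1, prob = P[s[j], ])
      }
      s
    })
  })
}

#' Export a transition model as a DOT graph
#'
#' Edges above `threshold` are emitted with probability labels, mirroring
#' the transition-diagram figures as plain data.
#'
#' @param model A `transition_model`.
#' @param path Output file.
#' @param threshold Minimum probability for an edge.
#' @return `path`, invisibly.
#' @export
write_transition_dot <- function(model, path, threshold = 0.2) {
  lines <- c("digraph transitions {", "  rankdir=LR;")
  for (i in model$labels) {
    for (j in model$labels) {
      p <- model$P[i, j]
      if (!is.na(p) && p >= threshold) {
        lines <- c(lines, sprintf("  %s -> %s [label=\"%.3f\"];", i, j, p))
      }
    }
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
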