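# Emotion lexicon expansion: seed terms plus embedding nearest neighbors.

#' Packaged Plutchik seed lexicon
#'
#' Seed terms for the eight basic emotions, shipped as a TSV
#' (`inst/extdata/plutchik_seeds.tsv`). The paper tradition names the eight
#' emotions; the concrete seed words are package defaults.
#'
#' @return Named list: emotion -> character vector of seed terms.
#' @export
default_seed_lexicon <- function() {
  df <- utils::read.delim(system.file("extdata", "plutchik_seeds.tsv",
                                      package = "emovista"),
                          stringsAsFactors = FALSE)
  split(df$term, factor(df$emotion, levels = plutchik_emotions()))
}

#' Expand seed lexicons with embedding nearest neighbors
#'
#' For each emotion, each in-vocabulary seed contributes its `k` nearest
#' neighbors with cosine similarity >= `tau`; a neighbor's weight for an
#' emotion is its maximum cosine over that emotion's seeds. A candidate term
#' close to several emotions is assigned to the emotion of maximum
#' similarity (ties broken by lexicographic emotion order), which makes the
#' expanded lexicons pairwise disjoint by construction. Seeds are always
#' included with weight 1.
#'
#' @param model An `embedding_model`.
#' @param seeds Named list emotion -> seed terms (default the packaged
#'   Plutchik seeds).
#' @param k Neighbors per seed.
#' @param tau Cosine threshold in [0, 1].
#' @return Object of class `emotion_lexicon`: a tibble with columns
#'   `emotion`, `term`, `weight`, `provenance` (`"seed"` or `"expanded"`).
#' @export
expand_lexicons <- function(model, seeds = default_seed_lexicon(),
                            k = 20, tau = 0.35) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  if (any(lengths(seeds) == 0)) stop("every emotion needs at least one seed")
  nv <- normalized_vectors(model)
  vocab <- rownames(nv)
  all_seeds <- unique(unlist(seeds))

  cand <- list() # candidate term -> named numeric (emotion -> best cosine)
  for (emo in names(seeds)) {
    for (s in seeds[[emo]]) {
      if (!(s %in% vocab)) {
        warning("seed term not in embedding vocabulary: ", s,
                " (kept with weight 1, contributes no neighbors)")
        next
      }
      sims <- drop(nv %*% nv[s, ])
      sims <- sims[!(names(sims) %in% all_seeds)]
      ord <- order(-sims, names(sims))
      top <- head(ord, k)
      for (i in top) {
        if (sims[i] < tau) break
        trm <- names(sims)[i]
        w <- unname(sims[i])
        prev <- cand[[trm]][emo]
        if (is.null(cand[[trm]]) || is.na(prev) || w > prev) {
          cand[[trm]][emo] <- w
        }
      }
    }
  }

  rows <- lapply(names(seeds), function(emo) {
    tibble::tibble(emotion = emo, term = seeds[[emo]], weight = 1,
                   provenance = "seed")
  })
  if (length(cand) > 0) {
    assigned <- vapply(names(cand), function(trm) {
      sims <- cand[[trm]]
      best <- sort(names(sims)[sims == max(sims)])[1] # lexicographic tie-break
      best
    }, "")
    weights <- vapply(names(cand), function(trm) max(cand[[trm]]), 0)
    rows <- c(rows, list(tibble::tibble(emotion = unname(assigned),
                                        term = names(cand),
                                        weight = unname(weights),
                                        provenance = "expanded")))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$emotion, plutchik_emotions()), -out$weight, out$term), ]
  structure(out, class = c("emotion_lexicon", class(out)))
}

#' Write / read an emotion lexicon as TSV
#'
#' Columns: `emotion`, `term`, `weight`, `provenance`.
#'
#' @param lexicon An `emotion_lexicon`.
#' @param path File path.
#' @return The path (write) or the lexicon (read).
#' @export
write_lexicon_tsv <- function(lexicon, path) {
  utils::write.table(as.data.frame(lexicon), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path) {
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  structure(df, class = c("emotion_lexicon", class(df)))
}
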