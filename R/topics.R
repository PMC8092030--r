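# LDA topic models, RAKE keyphrases, and cross-phase topic association.

#' Fit an LDA topic model to tokenized documents
#'
#' Collapsed Gibbs sampling with symmetric Dirichlet priors (the sampler is
#' the package's own implementation, deterministically seeded). Each
#' document is hard-assigned its argmax topic; documents whose maximum topic
#' probability falls below `1/K + prominence_margin` are treated as general
#' conversation without a prominent topic and excluded from the volume
#' counts. Shares are percentages of the counted volume.
#'
#' @param docs List of character token vectors.
#' @param K Number of topics (>= 1); must not exceed the number of
#'   documents.
#' @param seed Integer seed.
#' @param alpha Document-topic concentration (default `50 / K`).
#' @param beta Topic-term concentration.
#' @param iters Gibbs sweeps.
#' @param prominence_margin Margin above the uniform probability `1/K`
#'   required for a document to count as having a prominent topic.
#' @param n_top_terms Ranked terms kept per topic.
#' @param phase Optional phase tag carried in the result.
#' @return Object of class `topic_model`: `K`, `topic_terms` (tibble),
#'   `doc_topic` (tibble with dominant topic, its probability and
#'   prominence flag), `volumes`, `shares`, `labels`, `phase`.
#' @export
fit_topics <- function(docs, K, seed = 1L, alpha = NULL, beta = 0.1,
                       iters = 200, prominence_margin = 0.05,
                       n_top_terms = 10, phase = NA_character_) {
  keep <- lengths(docs) > 0
  if (!any(keep)) stop("docs must be non-empty")
  if (K < 1) stop("K must be >= 1")
  if (K > sum(keep)) stop("K exceeds the number of non-empty documents")
  if (is.null(alpha)) alpha <- 50 / K
  used <- docs[keep]
  vocab <- sort(unique(unlist(used)))
  idx <- setNames(seq_along(vocab) - 1L, vocab)
  enc <- lapply(used, function(t) as.integer(unname(idx[t])))
  fit <- .lda_gibbs(enc, length(vocab), as.integer(K), alpha, beta,
                    as.integer(iters), as.integer(seed))
  theta <- fit$doc_topic
  phi <- fit$topic_term
  dominant <- max.col(theta, ties.method = "first")
  maxp <- theta[cbind(seq_len(nrow(theta)), dominant)]
  prominent <- maxp >= min(1 / K + prominence_margin, 1)

  topic_terms <- do.call(rbind, lapply(seq_len(K), function(t) {
    ord <- order(-phi[t, ], vocab)
    top <- head(ord, n_top_terms)
    tibble::tibble(topic = t, rank = seq_along(top), term = vocab[top],
                   weight = phi[t, top])
  }))
  labels <- vapply(seq_len(K), function(t) {
    paste(topic_terms$term[topic_terms$topic == t][1:min(3, n_top_terms)],
          collapse = "+")
  }, "")
  volumes <- vapply(seq_len(K), function(t) sum(dominant == t & prominent), 0L)
  shares <- topic_shares(volumes)

  doc_topic <- tibble::tibble(doc = which(keep), dominant_topic = dominant,
                              max_prob = maxp, prominent = prominent)
  structure(list(K = K, phase = phase, topic_terms = topic_terms,
                 doc_topic = doc_topic, volumes = volumes, shares = shares,
                 labels = labels,
                 params = list(alpha = alpha, beta = beta, iters = iters,
                               seed = seed,
                               prominence_margin = prominence_margin)),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("<topic_model> K=%d, phase: %s\n", x$K, x$phase))
  print(topic_table(x))
  invisible(x)
}

#' Volume shares as percentages
#'
#' `shares = 100 * volume / sum(volume)` — the share arithmetic used for
#' per-phase topic volume tables.
#'
#' @param volumes Non-negative topic volumes.
#' @return Numeric vector of percentages summing to 100 (all zero if the
#'   total volume is zero).
#' @export
#' @examples
#' topic_shares(c(6021, 9281))[1]
topic_shares <- function(volumes) {
  tot <- sum(volumes)
  if (tot == 0) return(rep(0, length(volumes)))
  100 * volumes / tot
}

#' Tidy per-topic volume/share table
#'
#' @param model A `topic_model`.
#' @return Tibble with `phase`, `topic`, `label`, `volume`, `share_pct`.
#' @export
topic_table <- function(model) {
  tibble::tibble(phase = model$phase, topic = seq_len(model$K),
                 label = model$labels, volume = model$volumes,
                 share_pct = model$shares)
}

#' Select the topic count by UMass coherence over a grid
#'
#' Fits a model per candidate `K` and returns the `K` whose topics have the
#' highest mean UMass coherence of their top terms.
#'
#' @param docs List of token vectors.
#' @param grid Candidate topic counts.
#' @param seed Integer seed.
#' @param iters Gibbs sweeps per candidate fit.
#' @param n_top_terms Terms per topic entering the coherence score.
#' @return The selected K (integer).
#' @export
select_topic_count <- function(docs, grid = 2:6, seed = 1L, iters = 100,
                               n_top_terms = 8) {
  scores <- vapply(grid, function(K) {
    fit <- fit_topics(docs, K, seed = seed, iters = iters,
                      n_top_terms = n_top_terms)
    mean(vapply(seq_len(K), function(t) {
      terms <- fit$topic_terms$term[fit$topic_terms$topic == t]
      umass_coherence(terms, docs)
    }, 0))
  }, 0)
  grid[which.max(scores)]
}

# UMass coherence: mean over ordered term pairs of
# log((co-doc-frequency + 1) / doc-frequency).
umass_coherence <- function(terms, docs) {
  present <- lapply(terms, function(t) vapply(docs, function(d) t %in% d, TRUE))
  total <- 0
  npairs <- 0
  for (i in seq_along(terms)[-1]) {
    for (j in seq_len(i - 1)) {
      dfj <- sum(present[[j]])
      if (dfj == 0) next
      co <- sum(present[[i]] & present[[j]])
      total <- total + log((co + 1) / dfj)
      npairs <- npairs + 1
    }
  }
  if (npairs == 0) -Inf else total / npairs
}

#' RAKE-style keyphrase extraction
#'
#' Candidate phrases are maximal runs of non-stop-word tokens. Each word
#' scores `degree / frequency`, where frequency counts candidate occurrences
#' and degree sums the lengths of the candidates it appears in; a phrase
#' scores the sum of its word scores.
#'
#' @param docs List of character token vectors.
#' @param stop_words Character vector of stop words (phrase delimiters).
#' @return Tibble with `phrase`, `score`, `n` (occurrences), ranked by
#'   score descending.
#' @export
#' @examples
#' extract_keyphrases(list(c("panic", "buying", "spreads"),
#'                         c("panic", "buying", "continues")),
#'                    stop_words = c("spreads", "continues"))
extract_keyphrases <- function(docs, stop_words = default_stopwords()) {
  phrases <- list()
  for (d in docs) {
    if (length(d) == 0) next
    is_stop <- d %in% stop_words
    runs <- split(d[!is_stop], cumsum(is_stop)[!is_stop])
    phrases <- c(phrases, unname(runs))
  }
  phrases <- phrases[lengths(phrases) > 0]
  if (length(phrases) == 0) {
    return(tibble::tibble(phrase = character(0), score = numeric(0),
                          n = integer(0)))
  }
  words <- unlist(phrases)
  freq <- table(words)
  degree <- tapply(rep(lengths(phrases), lengths(phrases)), words, sum)
  wscore <- degree[names(freq)] / as.numeric(freq)
  key <- vapply(phrases, paste, "", collapse = " ")
  pscore <- vapply(phrases, function(p) sum(wscore[p]), 0)
  agg <- tibble::tibble(phrase = key, score = pscore)
  agg <- unique(agg)
  nocc <- table(key)
  agg$n <- as.integer(nocc[agg$phrase])
  agg[order(-agg$score, agg$phrase), ]
}

#' Associate topics across phases by embedding-centroid similarity
#'
#' Each topic is represented by the weight-averaged embedding centroid of
#' its top `m` terms (terms missing from the embedding are skipped; topics
#' with no embeddable term are excluded with a warning). The similarity of
#' two topics is the cosine of their centroids, truncated at 0 so it lies in
#' [0, 1]; edges connect topics of distinct phases with similarity >=
#' `threshold`.
#'
#' @param models List of `topic_model`s (>= 2 phases).
#' @param embedding An `embedding_model` trained on the same corpus.
#' @param m Top terms per topic entering the centroid.
#' @param threshold Similarity threshold for an edge.
#' @return Object of class `topic_association`: `nodes` (tibble: phase,
#'   topic, label) and `edges` (tibble: phase_a, topic_a, phase_b, topic_b,
#'   similarity).
#' @export
associate_topics <- function(models, embedding, m = 10, threshold = 0.5) {
  phases <- vapply(models, function(x) x$phase, "")
  if (length(unique(phases)) < 2) stop("need topic models for >= 2 phases")
  nv <- normalized_vectors(embedding)
  cents <- list()
  nodes <- list()
  for (mod in models) {
    for (t in seq_len(mod$K)) {
      tt <- mod$topic_terms[mod$topic_terms$topic == t, ]
      tt <- head(tt[order(tt$rank), ], m)
      inv <- tt$term %in% rownames(nv)
      if (!any(inv)) {
        warning(sprintf("topic %d of phase %s has no embeddable terms; excluded",
                        t, mod$phase))
        next
      }
      w <- tt$weight[inv]
      cent <- colSums(nv[tt$term[inv], , drop = FALSE] * w) / sum(w)
      key <- paste(mod$phase, t, sep = "\r")
      cents[[key]] <- cent
      nodes[[key]] <- tibble::tibble(phase = mod$phase, topic = t,
                                     label = mod$labels[t])
    }
  }
  nodes <- do.call(rbind, unname(nodes))
  keys <- paste(nodes$phase, nodes$topic, sep = "\r")
  edges <- list()
  if (nrow(nodes) > 1) {
    for (i in seq_len(nrow(nodes) - 1)) {
      for (j in (i + 1):nrow(nodes)) {
        if (nodes$phase[i] == nodes$phase[j]) next
        sim <- max(0, cosine_sim(cents[[keys[i]]], cents[[keys[j]]]))
        if (sim >= threshold) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            phase_a = nodes$phase[i], topic_a = nodes$topic[i],
            phase_b = nodes$phase[j], topic_b = nodes$topic[j],
            similarity = sim)
        }
      }
    }
  }
  edges <- if (length(edges) > 0) {
    do.call(rbind, edges)
  } else {
    tibble::tibble(phase_a = character(0), topic_a = integer(0),
                   phase_b = character(0), topic_b = integer(0),
                   similarity = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "topic_association")
}

#' @export
print.topic_association <- function(x, ...) {
  cat(sprintf("<topic_association> %d nodes, %d edges (threshold %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Connected components of a topic association map
#'
#' @param assoc A `topic_association`.
#' @return Integer vector of component ids, named by `phase.topic`.
#' @export
association_components <- function(assoc) {
  keys <- paste(assoc$nodes$phase, assoc$nodes$topic, sep = ".")
  comp <- setNames(seq_along(keys), keys)
  if (nrow(assoc$edges) > 0) {
    ea <- paste(assoc$edges$phase_a, assoc$edges$topic_a, sep = ".")
    eb <- paste(assoc$edges$phase_b, assoc$edges$topic_b, sep = ".")
    repeat {
      changed <- FALSE
      for (k in seq_along(ea)) {
        m <- min(comp[ea[k]], comp[eb[k]])
        if (comp[ea[k]] != m || comp[eb[k]] != m) {
          comp[comp == comp[ea[k]] | comp == comp[eb[k]]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  comp
}
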