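# Skip-gram word embeddings. The trainer is the package's own single-thread
# SGNS implementation (src/sgns.cpp), so repeated runs with the same seed
# give bit-identical vectors.

#' Train skip-gram word embeddings on a tokenized corpus
#'
#' Skip-gram with negative sampling, dynamic context window, unigram^0.75
#' negative-sampling distribution and linearly decaying learning rate.
#' Single-threaded: a fixed seed reproduces vectors exactly.
#'
#' @param corpus List of character token vectors (one per post).
#' @param d Embedding dimension.
#' @param window Maximum context window (tokens each side).
#' @param min_count Terms occurring fewer than `min_count` times are dropped
#'   from the vocabulary.
#' @param epochs Training passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate.
#' @param seed Integer seed.
#' @return Object of class `embedding_model`: `vectors` (terms x d matrix
#'   with term rownames), `counts`, and `params`.
#' @export
train_embeddings <- function(corpus, d = 100, window = 5, min_count = 3,
                             epochs = 10, negative = 5, alpha = 0.025,
                             seed = 1L) {
  if (length(corpus) == 0) stop("corpus must be non-empty")
  counts <- table(unlist(corpus))
  counts <- counts[counts >= min_count]
  if (length(counts) == 0) stop("vocabulary empty after min_count filtering")
  # deterministic vocabulary order: frequency desc, then alphabetical
  counts <- counts[order(-as.numeric(counts), names(counts))]
  vocab <- names(counts)
  idx <- setNames(seq_along(vocab) - 1L, vocab)
  docs <- lapply(corpus, function(toks) {
    v <- idx[toks[toks %in% vocab]]
    as.integer(unname(v))
  })
  docs <- docs[lengths(docs) > 1]
  if (length(docs) == 0) stop("no document retains >= 2 in-vocabulary tokens")
  vec <- .sgns_train(docs, length(vocab), as.numeric(counts), as.integer(d),
                     as.integer(window), as.integer(negative),
                     as.integer(epochs), alpha, as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vectors = vec,
                 counts = setNames(as.integer(counts), vocab),
                 params = list(d = d, window = window, min_count = min_count,
                               epochs = epochs, negative = negative,
                               alpha = alpha, seed = seed)),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %d terms, %d dimensions (window=%d, epochs=%d)\n",
              nrow(x$vectors), ncol(x$vectors),
              x$params$window, x$params$epochs))
  invisible(x)
}

# L2-normalized copy of the vectors, for cosine queries.
normalized_vectors <- function(model) {
  v <- model$vectors
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v / nrm
}

#' Cosine similarity between two terms of an embedding model
#'
#' @param model An `embedding_model`.
#' @param a,b Terms.
#' @return Cosine similarity, or `NA` if a term is out of vocabulary.
#' @export
embedding_similarity <- function(model, a, b) {
  v <- model$vectors
  if (!(a %in% rownames(v)) || !(b %in% rownames(v))) return(NA_real_)
  cosine_sim(v[a, ], v[b, ])
}

#' Nearest neighbors of a term by cosine similarity
#'
#' @param model An `embedding_model`.
#' @param term Query term.
#' @param k Number of neighbors.
#' @return Tibble with `term` and `similarity`, most similar first.
#' @export
nearest_neighbors <- function(model, term, k = 10) {
  nv <- normalized_vectors(model)
  if (!(term %in% rownames(nv))) stop("term not in vocabulary: ", term)
  sims <- drop(nv %*% nv[term, ])
  sims <- sims[names(sims) != term]
  ord <- order(-sims, names(sims))
  top <- head(ord, k)
  tibble::tibble(term = names(sims)[top], similarity = unname(sims[top]))
}

#' Persist embedding vectors as a portable TSV
#'
#' First column the term, remaining columns the vector entries.
#'
#' @param model An `embedding_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(model, path) {
  df <- data.frame(term = rownames(model$vectors), model$vectors,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
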