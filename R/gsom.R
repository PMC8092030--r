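# Growing self-organizing map (GSOM) for behavior profiling. The map starts
# as a 2x2 grid and grows boundary nodes where accumulated quantization
# error exceeds the growth threshold GT = -D * ln(SF).

#' GSOM growth threshold
#'
#' `GT = -D * ln(SF)`: the accumulated-error level at which a winning node
#' spawns new neighbors. Lower spread factors give higher thresholds and
#' hence coarser maps; GT is linear in the data dimension so SF controls
#' granularity independently of D.
#'
#' @param D Input dimension (>= 1).
#' @param SF Spread factor in (0, 1).
#' @return The growth threshold (positive scalar).
#' @export
#' @examples
#' growth_threshold(2, 0.5)  # 1.3863
growth_threshold <- function(D, SF) {
  if (SF <= 0 || SF >= 1) stop("SF must be in (0, 1)")
  if (D < 1) stop("D must be >= 1")
  -D * log(SF)
}

#' GSOM hyperparameter configuration
#'
#' @param sf Spread factor in (0, 1).
#' @param alpha0 Initial learning rate in (0, 1].
#' @param fd Error-distribution factor in (0, 1): fraction by which a
#'   non-boundary winner's neighbors inflate their own error when the
#'   winner's error is redistributed.
#' @param growth_epochs Epochs of the growing phase.
#' @param smooth_epochs Epochs of the smoothing phase (no growth, halved
#'   rate, radius 1).
#' @param neighborhood0 Initial neighborhood radius (grid distance).
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `gsom_config`.
#' @export
gsom_config <- function(sf = 0.3, alpha0 = 0.3, fd = 0.5,
                        growth_epochs = 50, smooth_epochs = 50,
                        neighborhood0 = 3, seed = 1L) {
  if (sf <= 0 || sf >= 1) stop("sf must be in (0, 1)")
  if (alpha0 <= 0 || alpha0 > 1) stop("alpha0 must be in (0, 1]")
  if (fd <= 0 || fd >= 1) stop("fd must be in (0, 1)")
  structure(list(sf = sf, alpha0 = alpha0, fd = fd,
                 growth_epochs = as.integer(growth_epochs),
                 smooth_epochs = as.integer(smooth_epochs),
                 neighborhood0 = neighborhood0, seed = as.integer(seed)),
            class = "gsom_config")
}

# von Neumann neighbor offsets
.gsom_dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))

#' Train a growing self-organizing map
#'
#' Starts from a 2x2 grid with seeded-random weights in `[0,1]^D`. For each
#' input (fixed presentation order) the Euclidean-nearest node wins; the
#' winner and grid neighbors within the current radius move toward the input
#' (Gaussian neighborhood kernel, learning rate and radius decaying over the
#' growth phase). The winner accumulates squared quantization error; when it
#' exceeds GT, a boundary winner grows a new node in every free adjacent
#' grid position (weights by the standard GSOM interpolation/extrapolation
#' rules) and resets its error to GT/2, while an interior winner resets to
#' GT/2 and inflates each neighbor's error by the factor `fd`. The smoothing
#' phase runs with no growth, halved initial rate, and radius 1.
#' Deterministic under a fixed seed and input order.
#'
#' @param X Numeric matrix (rows = observations) or data frame; optionally
#'   with rownames used as ids.
#' @param config A `gsom_config`.
#' @return Object of class `gsom_map`: `coords` (node grid positions),
#'   `weights` (node x D), `error`, `hits` (final winner counts over `X`),
#'   `config`, `GT`.
#' @export
train_gsom <- function(X, config = gsom_config()) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("X must be non-empty")
  D <- ncol(X)
  GT <- growth_threshold(D, config$sf)

  coords <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  W <- with_seed(config$seed, matrix(runif(4 * D), 4, D))
  E <- numeric(4)

  find_node <- function(x, y) {
    which(coords[, 1] == x & coords[, 2] == y)[1]
  }

  grow_at <- function(parent) {
    px <- coords[parent, 1]; py <- coords[parent, 2]
    for (k in seq_len(4)) {
      nx <- px + .gsom_dirs[k, 1]; ny <- py + .gsom_dirs[k, 2]
      if (!is.na(find_node(nx, ny))) next
      # weight initialization, standard GSOM case rules:
      # (a) a consecutive neighbor beyond the new node -> average with it;
      # (b) else a neighbor opposite the growth direction -> extrapolate
      #     past the parent; (c) else copy the parent.
      beyond <- find_node(nx + .gsom_dirs[k, 1], ny + .gsom_dirs[k, 2])
      opposite <- find_node(px - .gsom_dirs[k, 1], py - .gsom_dirs[k, 2])
      w_new <- if (!is.na(beyond)) {
        (W[parent, ] + W[beyond, ]) / 2
      } else if (!is.na(opposite)) {
        2 * W[parent, ] - W[opposite, ]
      } else {
        W[parent, ]
      }
      w_new <- pmin(pmax(w_new, 0), 1)
      coords <<- rbind(coords, c(nx, ny))
      W <<- rbind(W, w_new)
      E <<- c(E, 0)
    }
  }

  present <- function(x, lr, radius, grow) {
    d2 <- rowSums((W - rep(x, each = nrow(W)))^2)
    win <- which.min(d2)
    gd2 <- (coords[, 1] - coords[win, 1])^2 + (coords[, 2] - coords[win, 2])^2
    upd <- gd2 <= radius^2
    h <- exp(-gd2[upd] / (2 * radius^2))
    W[upd, ] <<- W[upd, ] + lr * h * (matrix(x, sum(upd), length(x),
                                             byrow = TRUE) - W[upd, , drop = FALSE])
    if (grow) {
      E[win] <<- E[win] + d2[win]
      if (E[win] > GT) {
        neigh <- vapply(seq_len(4), function(k) {
          find_node(coords[win, 1] + .gsom_dirs[k, 1],
                    coords[win, 2] + .gsom_dirs[k, 2])
        }, 0L)
        if (anyNA(neigh)) {
          grow_at(win)
          E[win] <<- GT / 2
        } else {
          E[win] <<- GT / 2
          E[neigh] <<- E[neigh] * (1 + config$fd)
        }
      }
    }
  }

  ge <- config$growth_epochs
  for (ep in seq_len(ge)) {
    frac <- if (ge > 1) (ep - 1) / (ge - 1) else 0
    radius <- max(1, config$neighborhood0 * (1 - frac) + 1 * frac)
    lr <- config$alpha0 * (1 - 0.9 * frac)
    for (i in seq_len(nrow(X))) present(X[i, ], lr, radius, grow = TRUE)
  }
  for (ep in seq_len(config$smooth_epochs)) {
    for (i in seq_len(nrow(X))) {
      present(X[i, ], config$alpha0 / 2, 1, grow = FALSE)
    }
  }

  map <- structure(list(coords = coords, weights = W, error = E,
                        config = config, GT = GT),
                   class = "gsom_map")
  map$hits <- tabulate(map_nodes(map, X), nbins = nrow(coords))
  map
}

#' @export
print.gsom_map <- function(x, ...) {
  cat(sprintf("<gsom_map> %d nodes, D=%d, GT=%.4f (SF=%.2f)\n",
              nrow(x$coords), ncol(x$weights), x$GT, x$config$sf))
  invisible(x)
}

#' Map observations to their winning GSOM node
#'
#' @param map A trained `gsom_map`.
#' @param X Numeric matrix of observations.
#' @return Integer vector of node indices (rows of `map$coords`).
#' @export
map_nodes <- function(map, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(map$weights)) stop("dimension mismatch")
  vapply(seq_len(nrow(X)), function(i) {
    which.min(rowSums((map$weights - rep(X[i, ], each = nrow(map$weights)))^2))
  }, 0L)
}

#' Derive labeled behavior profiles from a trained map
#'
#' Nodes with at least `min_hits` mapped observations are merged
#' agglomeratively: grid-adjacent qualifying nodes whose weight distance is
#' below a map-wide reference adjacent-node weight distance join the same
#' profile. The reference is the mean adjacent distance by default: within a
#' data cluster adjacent nodes sit close together while the few edges that
#' straddle cluster boundaries are many times larger, so the heavy-tailed
#' mean separates the two regimes where the median falls inside the
#' within-cluster distribution and fragments it (`"median"` is available as
#' an option). Each profile carries its member observations, their mean
#' feature vector, and a label naming its `m` strongest feature dimensions.
#'
#' @param map A trained `gsom_map`.
#' @param X Numeric matrix of observations (rownames used as member ids).
#' @param min_hits Minimum observations mapped to a node for it to enter a
#'   profile.
#' @param m Number of feature names in the label.
#' @param merge_stat Statistic of the adjacent-node weight distances used as
#'   the merge threshold: `"mean"` (default) or `"median"`.
#' @return Object of class `profile_set`: tibble `profiles` (profile_id,
#'   label, n_members, node count) plus `members` (list of id vectors),
#'   `mean_vectors`, and `assignment` (node -> profile).
#' @export
derive_profiles <- function(map, X, min_hits = 2, m = 3,
                            merge_stat = c("mean", "median")) {
  merge_stat <- match.arg(merge_stat)
  X <- as.matrix(X)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  node_of <- map_nodes(map, X)
  hits <- tabulate(node_of, nbins = nrow(map$coords))
  qualify <- which(hits >= min_hits)
  if (length(qualify) == 0) stop("no node reaches min_hits = ", min_hits)

  # map-wide reference weight distance over all grid-adjacent node pairs
  adj_d <- c()
  for (i in seq_len(nrow(map$coords))) {
    for (k in seq_len(4)) {
      nx <- map$coords[i, 1] + .gsom_dirs[k, 1]
      ny <- map$coords[i, 2] + .gsom_dirs[k, 2]
      j <- which(map$coords[, 1] == nx & map$coords[, 2] == ny)[1]
      if (!is.na(j) && j > i) {
        adj_d <- c(adj_d, sqrt(sum((map$weights[i, ] - map$weights[j, ])^2)))
      }
    }
  }
  med <- if (merge_stat == "mean") mean(adj_d) else stats::median(adj_d)

  # union-find over all nodes: low-hit nodes inside a dense region keep it
  # grid-connected, while boundary nodes never link clusters because their
  # adjacent distances exceed the threshold
  comp <- seq_len(nrow(map$coords))
  for (i in seq_len(nrow(map$coords))) {
    for (k in seq_len(4)) {
      nx <- map$coords[i, 1] + .gsom_dirs[k, 1]
      ny <- map$coords[i, 2] + .gsom_dirs[k, 2]
      j <- which(map$coords[, 1] == nx & map$coords[, 2] == ny)[1]
      if (is.na(j) || j <= i) next
      dij <- sqrt(sum((map$weights[i, ] - map$weights[j, ])^2))
      if (dij < med) {
        ci <- comp[i]; cj <- comp[j]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
  }
  # a component forms a profile only if it holds qualifying (well-hit) nodes
  comp_ids <- unique(comp[qualify])
  feat_names <- colnames(X)
  if (is.null(feat_names)) feat_names <- paste0("f", seq_len(ncol(X)))

  members <- list(); mean_vecs <- list(); rows <- list()
  assignment <- setNames(rep(NA_integer_, nrow(map$coords)),
                         seq_len(nrow(map$coords)))
  for (p in seq_along(comp_ids)) {
    nodes_p <- which(comp == comp_ids[p] & hits > 0)
    assignment[nodes_p] <- p
    mem <- ids[node_of %in% nodes_p]
    mv <- colMeans(X[node_of %in% nodes_p, , drop = FALSE])
    names(mv) <- feat_names
    lab <- paste(feat_names[order(-mv)][seq_len(min(m, length(mv)))],
                 collapse = "+")
    members[[p]] <- mem
    mean_vecs[[p]] <- mv
    rows[[p]] <- tibble::tibble(profile_id = p, label = lab,
                                n_members = length(mem),
                                n_nodes = length(nodes_p))
  }
  structure(list(profiles = do.call(rbind, rows), members = members,
                 mean_vectors = mean_vecs, assignment = assignment,
                 merge_threshold = med),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d profiles\n", nrow(x$profiles)))
  print(x$profiles)
  invisible(x)
}

#' Build per-user topic + emotion feature vectors
#'
#' Concatenates each user's topic-proportion block (distribution of their
#' posts' dominant topics) and normalized emotion-intensity block (their
#' summed post scores rescaled to 1). Users with no emotion matches or no
#' prominent-topic posts are dropped.
#'
#' @param scored Tibble from [score_posts()] joined with a `user_id` column.
#' @param topic_docs Tibble with `user_id` and `dominant_topic` per post
#'   (e.g. derived from a `topic_model`'s `doc_topic`).
#' @param K Number of topics (block width).
#' @return Numeric matrix, rows = users (rownames = user ids), columns =
#'   topic proportions then emotion proportions; each block sums to 1.
#' @export
user_feature_vectors <- function(scored, topic_docs, K) {
  emo <- plutchik_emotions()
  users <- intersect(unique(scored$user_id), unique(topic_docs$user_id))
  rows <- lapply(users, function(u) {
    sc <- scored[scored$user_id == u, emo, drop = FALSE]
    esum <- colSums(as.matrix(sc))
    if (sum(esum) == 0) return(NULL)
    tcount <- tabulate(topic_docs$dominant_topic[topic_docs$user_id == u],
                       nbins = K)
    if (sum(tcount) == 0) return(NULL)
    c(tcount / sum(tcount), esum / sum(esum))
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[keep])
  rownames(out) <- users[keep]
  colnames(out) <- c(paste0("topic", seq_len(K)), emo)
  out
}
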