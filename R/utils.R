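# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Salted deterministic hash of identifiers
#'
#' FNV-1a 64-bit hash used to anonymize user ids and checksum run outputs.
#' Deterministic for a fixed salt; without the salt the mapping is not
#' practically invertible for arbitrary ids.
#'
#' @param x Character vector to hash.
#' @param salt Single string mixed into every hash.
#' @return Character vector of 16-character lowercase hex digests.
#' @export
#' @examples
#' salted_hash(c("user1", "user2"), salt = "pepper")
salted_hash <- function(x, salt = "emovista") {
  stopifnot(is.character(salt), length(salt) == 1)
  .fnv1a64(as.character(x), salt)
}

# Assert that a numeric vector is a probability mixture summing to 1.
check_mixture <- function(x, what, tol = 1e-9) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be non-negative and finite")
  }
  if (abs(sum(x) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(x), digits = 12), ")")
  }
  invisible(x)
}

# Row-stochasticity check for transition matrices.
check_row_stochastic <- function(P, what = "transition_matrix", tol = 1e-9) {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop(what, " must be square")
  if (any(!is.finite(P)) || any(P < 0)) stop(what, " must be non-negative")
  if (any(abs(rowSums(P) - 1) > tol)) stop(what, " rows must sum to 1")
  invisible(P)
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
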