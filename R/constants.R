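#' The eight Plutchik basic emotions in the package's canonical order
#'
#' The canonical order is used everywhere a fixed emotion order matters:
#' score vectors, transition-matrix dimensions, and deterministic tie-breaks
#' when picking a dominant emotion.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' plutchik_emotions()
plutchik_emotions <- function() {
  c("anger", "sadness", "disgust", "fear",
    "joy", "surprise", "trust", "anticipation")
}

#' Polar opposite of a Plutchik emotion
#'
#' Opposites follow the Plutchik wheel: joy-sadness, trust-disgust,
#' fear-anger, anticipation-surprise. Negated emotion terms contribute to
#' the opposite emotion under the default negation mode.
#'
#' @param emotion Character vector of emotion names.
#' @return Character vector of the polar opposites.
#' @export
#' @examples
#' plutchik_opposite("joy")   # "sadness"
#' plutchik_opposite(plutchik_opposite("fear")) # involution
plutchik_opposite <- function(emotion) {
  opp <- c(anger = "fear", fear = "anger",
           sadness = "joy", joy = "sadness",
           disgust = "trust", trust = "disgust",
           surprise = "anticipation", anticipation = "surprise")
  bad <- setdiff(emotion, names(opp))
  if (length(bad) > 0) {
    stop("unknown emotion(s): ", paste(bad, collapse = ", "))
  }
  unname(opp[emotion])
}
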