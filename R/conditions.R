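# Canonical condition grid of the priming design: 4 face primes x 2 target
# word valences, in a fixed order used for parameter indexing everywhere.

napt_faces <- c("scrambled", "neutral", "happy", "angry")
napt_valences <- c("positive", "negative")

#' Condition grid of the priming design
#'
#' The eight face-by-valence conditions in canonical order (faces:
#' scrambled, neutral, happy, angry; valences: positive, negative). All
#' condition-indexed parameters follow this order.
#'
#' @return data.frame with columns `face`, `valence`, `label`.
#' @export
napt_conditions <- function() {
  g <- expand.grid(valence = napt_valences, face = napt_faces,
                   stringsAsFactors = FALSE)[, c("face", "valence")]
  g$label <- paste(g$face, g$valence, sep = ":")
  rownames(g) <- NULL
  g
}

condition_index <- function(face, valence) {
  fi <- match(face, napt_faces)
  vi <- match(valence, napt_valences)
  if (anyNA(fi)) stop("unknown face label", call. = FALSE)
  if (anyNA(vi)) stop("unknown valence label", call. = FALSE)
  (fi - 1L) * 2L + vi
}
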