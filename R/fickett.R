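# Fickett TESTCODE lookup tables (position asymmetry and base content
# probabilities with their weights), as published for the statistic and
# used by alignment-free coding-potential tools.

FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)

FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

# First table entry whose threshold is <= value.
fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1]]
}

fickett_one <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  total <- sum(keep)
  if (total == 0) return(0)
  pos <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (base in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(chars == base & pos == p), numeric(1))
    position_par <- max(counts) / (min(counts) + 1)
    content_par <- sum(counts) / total
    score <- score +
      fickett_lookup(position_par, FICKETT_POSITION_PARA,
                     FICKETT_POSITION_PROB[[base]]) *
        FICKETT_POSITION_WEIGHT[[base]] +
      fickett_lookup(content_par, FICKETT_CONTENT_PARA,
                     FICKETT_CONTENT_PROB[[base]]) *
        FICKETT_CONTENT_WEIGHT[[base]]
  }
  score
}

#' Fickett TESTCODE statistic
#'
#' For each base, the position parameter (maximum over the three codon
#' positions of the base's count, divided by the minimum plus one) and the
#' content parameter (the base's overall frequency) are converted to
#' probabilities through the published lookup tables; the statistic is the
#' published weighted sum of the eight converted values. N bases are
#' excluded from both counts. Deterministic and composition-based, so a
#' sequence and its concatenation with itself share content parameters.
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @return Tibble with columns `transcript_id` and `fickett_score`.
#' @export
fickett_score <- function(seqs) {
  check_sequences(seqs)
  tibble(
    transcript_id = seqs$transcript_id,
    fickett_score = vapply(seqs$sequence, fickett_one, numeric(1),
                           USE.NAMES = FALSE)
  )
}
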