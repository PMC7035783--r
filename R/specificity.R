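shannon_entropy_bits <- function(p) {
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Jensen-Shannon divergence of two probability vectors
#'
#' `H((p+q)/2) - (H(p) + H(q))/2` with Shannon entropy in bits and the
#' convention `0 * log 0 = 0`; symmetric in its arguments and bounded in
#' `[0, 1]`.
#'
#' @param p,q Non-negative numeric vectors of equal length (>= 2), each
#'   summing to 1 (tolerance 1e-9).
#' @return The divergence, a number in `[0, 1]`.
#' @export
js_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  if (length(p) < 2) abort("probability vectors need length >= 2")
  if (any(p < 0) || any(q < 0)) abort("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("probability vectors must sum to 1")
  }
  shannon_entropy_bits((p + q) / 2) -
    (shannon_entropy_bits(p) + shannon_entropy_bits(q)) / 2
}

# Specificity of one normalized expression pattern: 1 - sqrt(JS divergence
# to the unit vector at each condition), maximized over conditions.
js_specificity_one <- function(e) {
  total <- sum(e)
  if (total <= 0) return(list(score = NA_real_, argmax = NA_integer_))
  p <- e / total
  n <- length(p)
  scores <- vapply(seq_len(n), function(t) {
    unit <- rep(0, n)
    unit[t] <- 1
    1 - sqrt(js_divergence(p, unit))
  }, numeric(1))
  list(score = max(scores), argmax = which.max(scores))
}

#' Jensen-Shannon tissue-specificity scores
#'
#' For each transcript, the expression vector across conditions is
#' normalized to a probability pattern and scored as one minus the square
#' root of the Jensen-Shannon divergence to the extremal single-condition
#' pattern, maximized over conditions (log base 2). A transcript expressed
#' in exactly one condition scores 1; the score is invariant to positive
#' rescaling. All-zero rows are flagged unscored rather than dropped. An
#' optional expression floor zeroes FPKM values below `min_fpkm` before
#' scoring, guarding against spuriously specific near-zero noise vectors.
#'
#' @param expr Expression tibble (`transcript_id` plus one numeric column
#'   per condition).
#' @param min_fpkm Expression floor; values strictly below it are treated
#'   as 0. Default 0 (no floor).
#' @return Tibble with columns `transcript_id`, `js_score`,
#'   `argmax_condition`, `scorable`.
#' @export
specificity_scores <- function(expr, min_fpkm = 0) {
  conds <- expression_conditions(expr)
  if (length(conds) < 2) abort("need at least two conditions")
  mat <- as.matrix(expr[conds])
  if (any(mat < 0)) abort("negative expression values")
  mat[mat < min_fpkm] <- 0
  res <- apply(mat, 1, js_specificity_one)
  tibble(
    transcript_id = expr$transcript_id,
    js_score = purrr::map_dbl(res, "score"),
    argmax_condition = conds[purrr::map_int(res, function(r) {
      if (is.na(r$argmax)) NA_integer_ else r$argmax
    })],
    scorable = !is.na(purrr::map_dbl(res, "score"))
  )
}

#' Call tissue-specific transcripts at a score cutoff
#'
#' A transcript is specific when its score is strictly greater than the
#' cutoff (a score exactly at the cutoff is non-specific).
#'
#' @param scores Tibble from [specificity_scores()].
#' @param cutoff JS score cutoff, default 0.5.
#' @return `scores` with an added logical `is_specific` column (NA for
#'   unscorable rows).
#' @export
call_specific <- function(scores, cutoff = 0.5) {
  mutate(scores, is_specific = .data$js_score > cutoff)
}

#' Summarize a specificity calling
#'
#' @param called Tibble from [call_specific()].
#' @return One-row tibble: `n_scored`, `n_specific`, `frac_specific`,
#'   `frac_js1` (fraction of scored transcripts with a score of exactly 1,
#'   at tolerance 1e-9).
#' @export
specificity_summary <- function(called) {
  scored <- filter(called, .data$scorable)
  tibble(
    n_scored = nrow(scored),
    n_specific = sum(scored$is_specific),
    frac_specific = if (nrow(scored) > 0) mean(scored$is_specific) else NA_real_,
    frac_js1 = if (nrow(scored) > 0) {
      mean(abs(scored$js_score - 1) < 1e-9)
    } else NA_real_
  )
}

#' Histogram table of specificity scores
#'
#' @param scores Tibble from [specificity_scores()].
#' @param breaks Bin breaks over `[0, 1]`.
#' @return Tibble with columns `bin` and `n`.
#' @export
specificity_histogram <- function(scores, breaks = seq(0, 1, by = 0.1)) {
  scored <- filter(scores, .data$scorable)
  bins <- cut(scored$js_score, breaks = breaks, include.lowest = TRUE)
  out <- as_tibble(table(bin = bins))
  names(out) <- c("bin", "n")
  out
}
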