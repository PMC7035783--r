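#' Extract coding-potential features for each transcript
#'
#' The four alignment-free features of the logistic coding-potential model:
#' maximal-ORF length in nucleotides, ORF coverage (fraction of the
#' transcript covered by the maximal ORF), the Fickett TESTCODE statistic
#' of the full transcript, and the hexamer usage bias of the maximal ORF.
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @param hexamer_table A `hexamer_table` from [train_hexamer_table()].
#' @return Tibble with columns `transcript_id`, `orf_nt_length`,
#'   `orf_coverage`, `fickett_score`, `hexamer_score`, `aa_length`.
#' @export
coding_features <- function(seqs, hexamer_table) {
  check_sequences(seqs)
  orfs <- find_max_orf(seqs)
  fick <- fickett_score(seqs)
  hexa <- hexamer_score(
    tibble(transcript_id = orfs$transcript_id, sequence = orfs$orf_seq),
    hexamer_table
  )
  tibble(
    transcript_id = seqs$transcript_id,
    orf_nt_length = orfs$nt_length,
    orf_coverage = if_else(nchar(seqs$sequence) > 0,
                           orfs$nt_length / nchar(seqs$sequence), 0),
    aa_length = orfs$aa_length
  ) |>
    left_join(fick, by = "transcript_id") |>
    left_join(hexa, by = "transcript_id")
}

CODING_FEATURE_NAMES <- c("orf_nt_length", "orf_coverage", "fickett_score",
                          "hexamer_score")

logistic_prob <- function(features, coef) {
  x <- as.matrix(features[, CODING_FEATURE_NAMES])
  eta <- coef[["(Intercept)"]] + drop(x %*% coef[CODING_FEATURE_NAMES])
  stats::plogis(eta)
}

#' Fit the logistic coding-potential model
#'
#' Extracts the four coding features for labeled training sequences, fits
#' a logistic regression (coding = 1) on a training split, and selects the
#' probability cutoff maximizing held-out sensitivity plus specificity
#' (the two-graph ROC rule). The held-out split is drawn with the current
#' RNG state, so set a seed for reproducibility.
#'
#' @param coding_seqs,noncoding_seqs Tibbles (`transcript_id`, `sequence`)
#'   of labeled training sequences; at least 50 per class.
#' @param held_out_fraction Fraction of each class held out for cutoff
#'   selection and performance estimation.
#' @param hexamer_table Optional pre-trained `hexamer_table`; by default
#'   one is trained on the same inputs.
#' @return An object of class `coding_model`: coefficients, `cutoff`, the
#'   hexamer table, and held-out performance.
#' @export
fit_coding_model <- function(coding_seqs, noncoding_seqs,
                             held_out_fraction = 0.25,
                             hexamer_table = NULL) {
  check_sequences(coding_seqs)
  check_sequences(noncoding_seqs)
  if (nrow(coding_seqs) < 50 || nrow(noncoding_seqs) < 50) {
    abort("each training class needs at least 50 sequences")
  }
  if (nrow(coding_seqs) == 0 || nrow(noncoding_seqs) == 0) {
    abort("degenerate single-class training input")
  }
  hexamer_table <- hexamer_table %val%
    train_hexamer_table(coding_seqs, noncoding_seqs)
  feats <- bind_rows(
    mutate(coding_features(coding_seqs, hexamer_table), label = 1L),
    mutate(coding_features(noncoding_seqs, hexamer_table), label = 0L)
  )
  hold <- unlist(lapply(split(seq_len(nrow(feats)), feats$label), function(i) {
    sample(i, size = max(1L, round(length(i) * held_out_fraction)))
  }), use.names = FALSE)
  train <- feats[-hold, ]
  test <- feats[hold, ]
  fml <- stats::as.formula(paste("label ~", paste(CODING_FEATURE_NAMES,
                                                  collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = train))
  coef <- stats::coef(fit)
  coef[is.na(coef)] <- 0
  p_test <- logistic_prob(test, coef)
  cutoff <- select_cutoff(p_test, test$label)
  sens <- mean(p_test[test$label == 1] >= cutoff)
  spec <- mean(p_test[test$label == 0] < cutoff)
  structure(
    list(coefficients = coef, cutoff = cutoff, hexamer_table = hexamer_table,
         heldout = tibble(sensitivity = sens, specificity = spec,
                          accuracy = mean((p_test >= cutoff) == (test$label == 1)),
                          n_heldout = length(p_test)),
         n_coding = nrow(coding_seqs), n_noncoding = nrow(noncoding_seqs)),
    class = "coding_model"
  )
}

# Two-graph ROC: probability cutoff maximizing sensitivity + specificity.
select_cutoff <- function(prob, label) {
  cands <- sort(unique(prob))
  youden <- vapply(cands, function(ct) {
    mean(prob[label == 1] >= ct) + mean(prob[label == 0] < ct)
  }, numeric(1))
  ct <- cands[which.max(youden)]
  min(max(ct, 1e-6), 1 - 1e-6)
}

#' @export
print.coding_model <- function(x, ...) {
  cat("<coding_model> logistic over", length(CODING_FEATURE_NAMES),
      "features; cutoff =", signif(x$cutoff, 4), "\n")
  cat("held-out sensitivity", signif(x$heldout$sensitivity, 3),
      "specificity", signif(x$heldout$specificity, 3), "\n")
  invisible(x)
}

#' @rdname fit_coding_model
#' @param x A `coding_model`.
#' @param ... Unused.
#' @method tidy coding_model
#' @export
tidy.coding_model <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' @rdname fit_coding_model
#' @method glance coding_model
#' @export
glance.coding_model <- function(x, ...) {
  bind_cols(
    tibble(cutoff = x$cutoff, n_coding = x$n_coding,
           n_noncoding = x$n_noncoding),
    x$heldout
  )
}

#' Score transcripts with a fitted coding-potential model
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @param model A `coding_model`.
#' @return [coding_features()] output plus a `coding_prob` column (the
#'   logistic probability that the transcript is protein-coding).
#' @export
predict_coding <- function(seqs, model) {
  feats <- coding_features(seqs, model$hexamer_table)
  mutate(feats, coding_prob = logistic_prob(feats, model$coefficients))
}

#' Apply the non-coding filter cascade
#'
#' Applies the four decision rules that call a transcript non-coding:
#' logistic coding probability below the model cutoff; negative
#' conservation coding score (vacuously true when no score table is
#' given); no protein-domain hit (vacuously true when no hit table is
#' given); and maximal ORF of at most `max_orf_aa` amino acids. The final
#' call is the conjunction of the four flags, so the rules may be applied
#' in any order.
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @param model A `coding_model`.
#' @param conservation Optional tibble (`transcript_id`, `score`) of
#'   precomputed conservation coding scores; transcripts with a
#'   non-negative score fail the conservation filter. Transcripts absent
#'   from the table pass vacuously.
#' @param domains Optional tibble (`transcript_id`, ...) of protein-domain
#'   hits; any recorded hit fails the domain filter.
#' @param max_orf_aa Maximal-ORF threshold in amino acids; longer ORFs are
#'   excluded.
#' @return Tibble with the features, `coding_prob`, `conservation_score`,
#'   `domain_hit`, the four `passes_*` flags and `is_noncoding`.
#' @export
apply_noncoding_filters <- function(seqs, model, conservation = NULL,
                                    domains = NULL, max_orf_aa = 100L) {
  scored <- predict_coding(seqs, model)
  cons <- if (is.null(conservation)) {
    tibble(transcript_id = scored$transcript_id,
           conservation_score = NA_real_)
  } else {
    tibble(transcript_id = scored$transcript_id) |>
      left_join(select(conservation, "transcript_id",
                       conservation_score = "score"),
                by = "transcript_id")
  }
  hit_ids <- if (is.null(domains)) character(0) else unique(domains$transcript_id)
  scored |>
    left_join(cons, by = "transcript_id") |>
    mutate(
      domain_hit = if (is.null(domains)) NA else
        .data$transcript_id %in% hit_ids,
      passes_cpat = .data$coding_prob < model$cutoff,
      passes_conservation = is.na(.data$conservation_score) |
        .data$conservation_score < 0,
      passes_domain = is.na(.data$domain_hit) | !.data$domain_hit,
      passes_maxorf = .data$aa_length <= max_orf_aa,
      is_noncoding = .data$passes_cpat & .data$passes_conservation &
        .data$passes_domain & .data$passes_maxorf
    )
}

#' Serialize a coding model to JSON
#'
#' Writes coefficients, cutoff, held-out performance and the hexamer table
#' to a documented JSON file readable by [read_coding_model()].
#'
#' @param model A `coding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coding_model <- function(model, path) {
  obj <- list(
    coefficients = as.list(model$coefficients),
    cutoff = model$cutoff,
    heldout = as.list(model$heldout),
    n_coding = model$n_coding,
    n_noncoding = model$n_noncoding,
    hexamer_table = list(hexamer = model$hexamer_table$hexamer,
                         f_coding = model$hexamer_table$f_coding,
                         f_noncoding = model$hexamer_table$f_noncoding)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized coding model
#'
#' @param path JSON file written by [write_coding_model()].
#' @return A `coding_model`.
#' @export
read_coding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble(hexamer = obj$hexamer_table$hexamer,
                f_coding = obj$hexamer_table$f_coding,
                f_noncoding = obj$hexamer_table$f_noncoding)
  class(tab) <- c("hexamer_table", class(tab))
  structure(
    list(coefficients = unlist(obj$coefficients), cutoff = obj$cutoff,
         hexamer_table = tab, heldout = as_tibble(obj$heldout),
         n_coding = obj$n_coding, n_noncoding = obj$n_noncoding),
    class = "coding_model"
  )
}
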