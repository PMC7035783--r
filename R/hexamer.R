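ALL_HEXAMERS <- local({
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                   b5 = bases, b6 = bases, stringsAsFactors = FALSE)
  sort(do.call(paste0, g[6:1]))
})

# Hexamer counts over a set of sequences; step 3 gives in-frame hexamers
# read from position 0, step 1 gives all sliding hexamers. Hexamers
# containing N are never counted.
hexamer_counts <- function(sequences, step) {
  ok <- sequences[nchar(sequences) >= 6]
  if (length(ok) == 0) return(setNames(numeric(4096), ALL_HEXAMERS))
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(ok), width = 6, step = step
  ))
  counts[ALL_HEXAMERS]
}

#' Train a coding/noncoding hexamer frequency table
#'
#' In-frame hexamer frequencies (step 3 from the annotated frame) are
#' tallied over the coding training sequences and sliding hexamer
#' frequencies (step 1) over the noncoding training sequences; both are
#' add-one pseudocounted and normalized to sum to one over the 4096
#' hexamers.
#'
#' @param coding Tibble (`transcript_id`, `sequence`) of in-frame CDS
#'   training sequences, or a character vector of sequences.
#' @param noncoding Noncoding training sequences, same forms accepted.
#' @return A tibble of class `hexamer_table` with columns `hexamer`,
#'   `f_coding`, `f_noncoding`.
#' @export
train_hexamer_table <- function(coding, noncoding) {
  as_seqvec <- function(x) {
    if (is.data.frame(x)) x$sequence else as.character(x)
  }
  coding <- as_seqvec(coding)
  noncoding <- as_seqvec(noncoding)
  if (length(coding) == 0 || length(noncoding) == 0) {
    abort("both training sets must be non-empty")
  }
  fc <- hexamer_counts(coding, step = 3L) + 1
  fn <- hexamer_counts(noncoding, step = 1L) + 1
  out <- tibble(hexamer = ALL_HEXAMERS,
                f_coding = as.numeric(fc / sum(fc)),
                f_noncoding = as.numeric(fn / sum(fn)))
  class(out) <- c("hexamer_table", class(out))
  out
}

#' Hexamer usage bias score of ORF sequences
#'
#' The mean, over the in-frame hexamers of each ORF sequence, of
#' `log(f_coding / f_noncoding)` (natural log). Hexamers containing N are
#' skipped; a sequence with no scorable hexamer scores 0.
#'
#' @param orf_seqs Tibble with columns `transcript_id` and `sequence`
#'   (ORF nucleotide sequences read from their start codon), or a character
#'   vector.
#' @param table A `hexamer_table` from [train_hexamer_table()].
#' @return Tibble with columns `transcript_id` and `hexamer_score`.
#' @export
hexamer_score <- function(orf_seqs, table) {
  if (!is.data.frame(orf_seqs)) {
    orf_seqs <- tibble(transcript_id = as.character(seq_along(orf_seqs)),
                       sequence = as.character(orf_seqs))
  }
  log_ratio <- setNames(log(table$f_coding / table$f_noncoding),
                        table$hexamer)
  score1 <- function(sq) {
    if (is.na(sq) || nchar(sq) < 6) return(0)
    m <- (nchar(sq) - 6L) %/% 3L + 1L
    hex <- substring(sq, 3L * (seq_len(m) - 1L) + 1L,
                     3L * (seq_len(m) - 1L) + 6L)
    vals <- log_ratio[hex]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(0)
    mean(vals)
  }
  tibble(
    transcript_id = orf_seqs$transcript_id,
    hexamer_score = vapply(orf_seqs$sequence, score1, numeric(1),
                           USE.NAMES = FALSE)
  )
}
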