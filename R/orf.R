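STOP_CODONS <- c("TAA", "TAG", "TGA")

# Longest ORF in one frame of one sequence. Returns NULL when the frame
# holds no ATG. Codons containing N never match ATG or a stop.
max_orf_in_frame <- function(seq, frame, require_stop = FALSE) {
  n <- nchar(seq)
  m <- (n - frame) %/% 3L
  if (m < 1) return(NULL)
  codons <- substring(seq, frame + 3L * (seq_len(m) - 1L) + 1L,
                      frame + 3L * seq_len(m))
  starts <- which(codons == "ATG")
  if (length(starts) == 0) return(NULL)
  stops <- which(codons %in% STOP_CODONS)
  # index (into `stops`) of the first stop codon after each start
  k <- findInterval(starts, stops) + 1L
  stop_at <- ifelse(k <= length(stops), stops[k], NA_integer_)
  if (require_stop) {
    keep <- !is.na(stop_at)
    if (!any(keep)) return(NULL)
    starts <- starts[keep]
    stop_at <- stop_at[keep]
  }
  n_codons <- ifelse(is.na(stop_at), m - starts + 1L, stop_at - starts + 1L)
  best <- which.max(n_codons)
  s <- starts[best]
  has_stop <- !is.na(stop_at[best])
  nt <- 3L * n_codons[best]
  list(
    frame = frame,
    start = frame + 3L * (s - 1L),
    end = frame + 3L * (s - 1L) + nt,
    nt_length = nt,
    aa_length = if (has_stop) nt %/% 3L - 1L else nt %/% 3L,
    has_stop = has_stop
  )
}

#' Find the maximal open reading frame of each transcript
#'
#' Scans the three forward frames of each sequence for the longest
#' ATG-initiated open reading frame ending at the first in-frame stop codon
#' (TAA/TAG/TGA); an ORF with no downstream in-frame stop extends to the
#' last complete codon. Codons containing N never match ATG or a stop. The
#' reported `nt_length` includes the stop codon when present; `aa_length`
#' excludes it.
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @param require_stop When `TRUE`, only stop-terminated ORFs are
#'   considered (default `FALSE`, accommodating truncated transcripts).
#' @return Tibble with one row per transcript: `transcript_id`, `frame`
#'   (0/1/2, NA when no ORF), `orf_start`, `orf_end` (0-based half-open
#'   offsets in the transcript), `nt_length`, `aa_length`, `has_stop`,
#'   `orf_seq`.
#' @export
find_max_orf <- function(seqs, require_stop = FALSE) {
  check_sequences(seqs)
  rows <- purrr::map2(seqs$transcript_id, seqs$sequence, function(id, sq) {
    cands <- purrr::compact(lapply(0:2, function(f) {
      max_orf_in_frame(sq, f, require_stop = require_stop)
    }))
    if (length(cands) == 0) {
      return(tibble(transcript_id = id, frame = NA_integer_,
                    orf_start = 0L, orf_end = 0L, nt_length = 0L,
                    aa_length = 0L, has_stop = FALSE, orf_seq = ""))
    }
    best <- cands[[which.max(purrr::map_int(cands, "nt_length"))]]
    tibble(transcript_id = id, frame = best$frame,
           orf_start = best$start, orf_end = best$end,
           nt_length = best$nt_length, aa_length = best$aa_length,
           has_stop = best$has_stop,
           orf_seq = substr(sq, best$start + 1L, best$end))
  })
  bind_rows(rows)
}

#' Translate each transcript in the three forward frames
#'
#' Standard genetic code; stop codons are rendered as `*` and codons
#' containing N as `X`. Used to export peptides for external protein-domain
#' scanning.
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @return Tibble with columns `transcript_id`, `frame` (0/1/2), `peptide`.
#' @export
translate_three_frames <- function(seqs) {
  check_sequences(seqs)
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(sq, frame) {
    n <- nchar(sq)
    m <- (n - frame) %/% 3L
    if (m < 1) return("")
    codons <- substring(sq, frame + 3L * (seq_len(m) - 1L) + 1L,
                        frame + 3L * seq_len(m))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }
  tidyr::expand_grid(transcript_id = seqs$transcript_id, frame = 0:2) |>
    left_join(seqs, by = "transcript_id") |>
    mutate(peptide = purrr::map2_chr(.data$sequence, .data$frame, translate1)) |>
    select("transcript_id", "frame", "peptide")
}

#' Write three-frame peptides to FASTA
#'
#' Record ids are suffixed with `.f0`/`.f1`/`.f2` by frame.
#'
#' @param peptides Tibble from [translate_three_frames()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path) {
  set <- Biostrings::BStringSet(setNames(
    peptides$peptide,
    paste0(peptides$transcript_id, ".f", peptides$frame)
  ))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
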