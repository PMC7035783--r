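# Internal validation helpers shared across modules.

# A genomic interval is 0-based half-open: 0 <= start < end.
check_intervals <- function(df, what = "interval") {
  stopifnot(is.data.frame(df))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0(what, " table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$start >= df$end)) {
    abort(paste0(what, " table violates 0 <= start < end"))
  }
  invisible(df)
}

check_strand <- function(strand) {
  bad <- setdiff(unique(strand), c("+", "-", "*"))
  if (length(bad) > 0) {
    abort(paste0("invalid strand value(s): ", paste(bad, collapse = ", ")))
  }
  invisible(strand)
}

# Length of the overlap between [s1, e1) and [s2, e2); 0 when disjoint.
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# Edge-to-edge distance between two half-open intervals; 0 when they overlap
# or touch.
interval_distance <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s2 - e1, s1 - e2))
}

check_sequences <- function(seqs) {
  stopifnot(is.data.frame(seqs))
  miss <- setdiff(c("transcript_id", "sequence"), names(seqs))
  if (length(miss) > 0) {
    abort(paste0("sequence table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(seqs$transcript_id) > 0) {
    abort("duplicate transcript_id in sequence table")
  }
  invisible(seqs)
}

`%val%` <- function(x, default) if (is.null(x)) default else x
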