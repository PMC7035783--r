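CLASS_CODES <- c("=", "c", "j", "e", "i", "o", "p", "u", "x", "s")

# Precedence when several references yield different codes for one
# transcript: most specific first.
CLASS_PRECEDENCE <- c("=", "c", "j", "e", "o", "i", "x", "s", "p", "u")

#' Build an overlap-queryable index over reference transcripts
#'
#' Wraps the reference annotation in per-chromosome interval trees
#' (IRanges) over transcript spans, together with the exon and intron
#' structures needed for class-code assignment.
#'
#' @param ref_exons Exon tibble of the reference annotation (all reference
#'   sets combined: protein-coding, known non-coding, small RNAs).
#' @return An object of class `reference_index`.
#' @export
build_interval_index <- function(ref_exons) {
  spans <- transcript_spans(ref_exons)
  exon_list <- split(ref_exons[c("start", "end")], ref_exons$transcript_id)
  introns <- transcript_introns(ref_exons)
  intron_list <- split(introns[c("start", "end")], introns$transcript_id)
  trees <- lapply(split(seq_len(nrow(spans)), spans$chrom), function(rows) {
    list(rows = rows,
         ranges = IRanges::IRanges(start = spans$start[rows] + 1L,
                                   end = spans$end[rows]))
  })
  structure(
    list(spans = spans, exons = exon_list, introns = intron_list,
         trees = trees),
    class = "reference_index"
  )
}

#' @export
print.reference_index <- function(x, ...) {
  cat("<reference_index>", nrow(x$spans), "transcripts on",
      length(x$trees), "chromosome(s)\n")
  invisible(x)
}

#' Query an interval index for span-overlapping references
#'
#' @param index A `reference_index`.
#' @param chrom Chromosome name.
#' @param start,end Query interval, 0-based half-open.
#' @return The subset of the reference span table whose spans intersect the
#'   query (identical to a linear scan).
#' @export
query_index <- function(index, chrom, start, end) {
  tree <- index$trees[[chrom]]
  if (is.null(tree)) return(index$spans[0, ])
  q <- IRanges::IRanges(start = start + 1L, end = end)
  hits <- IRanges::findOverlaps(q, tree$ranges)
  index$spans[tree$rows[S4Vectors::subjectHits(hits)], ]
}

# Total exonic overlap in bp between two exon tables (start/end columns).
exonic_overlap_total <- function(qe, re) {
  tot <- 0L
  for (i in seq_len(nrow(qe))) {
    tot <- tot + sum(overlap_bp(qe$start[i], qe$end[i], re$start, re$end))
  }
  tot
}

# Classify one query transcript against one reference transcript.
# Returns NA_character_ when no relation holds.
code_against_reference <- function(q_span, q_exons, q_introns,
                                   r_span, r_exons, r_introns,
                                   run_on_distance) {
  strand_known <- q_span$strand != "*"
  same_strand <- !strand_known || q_span$strand == r_span$strand
  ov <- exonic_overlap_total(q_exons, r_exons)
  nq <- nrow(q_exons)
  nr <- nrow(r_exons)
  contained_in_intron <- any(
    q_span$start >= r_introns$start & q_span$end <= r_introns$end
  )
  if (same_strand) {
    if (strand_known && nq >= 2 && nr >= 2 &&
        nrow(q_introns) == nrow(r_introns) &&
        all(q_introns$start == r_introns$start) &&
        all(q_introns$end == r_introns$end)) {
      return(list(code = "=", overlap = ov))
    }
    if (strand_known && nq == 1 && nr == 1 && ov > 0) {
      return(list(code = "=", overlap = ov))
    }
    exons_contained <- all(vapply(seq_len(nq), function(i) {
      any(q_exons$start[i] >= r_exons$start & q_exons$end[i] <= r_exons$end)
    }, logical(1)))
    introns_match <- nrow(q_introns) == 0 ||
      all(vapply(seq_len(nrow(q_introns)), function(i) {
        any(q_introns$start[i] == r_introns$start &
              q_introns$end[i] == r_introns$end)
      }, logical(1)))
    if (ov > 0 && exons_contained && introns_match && nq < nr) {
      return(list(code = "c", overlap = ov))
    }
    if (strand_known && nq >= 2 && nr >= 2 && nrow(q_introns) > 0 &&
        nrow(r_introns) > 0) {
      # exact junction sharing; identical chains were caught by "=" above
      shared <- any(paste(q_introns$start, q_introns$end) %in%
                      paste(r_introns$start, r_introns$end))
      if (shared) return(list(code = "j", overlap = ov))
    }
    if (nq == 1 && ov > 0 && nrow(r_introns) > 0) {
      into_intron <- max(overlap_bp(q_exons$start[1], q_exons$end[1],
                                    r_introns$start, r_introns$end), 0L)
      if (into_intron >= 10L) return(list(code = "e", overlap = ov))
    }
    if (ov > 0) return(list(code = "o", overlap = ov))
    if (contained_in_intron) return(list(code = "i", overlap = 0L))
    downstream <- if (r_span$strand == "+") {
      q_span$start >= r_span$end && q_span$start - r_span$end <= run_on_distance
    } else {
      q_span$end <= r_span$start && r_span$start - q_span$end <= run_on_distance
    }
    if (downstream) return(list(code = "p", overlap = 0L))
    return(NULL)
  }
  # opposite strand
  if (ov > 0) return(list(code = "x", overlap = ov))
  if (contained_in_intron) return(list(code = "s", overlap = 0L))
  NULL
}

#' Assign a Cuffcompare-style class code to one transcript
#'
#' Evaluates the query against every reference whose span lies within the
#' run-on distance, computes a per-reference code, and keeps the most
#' specific one in the precedence order `=`, `c`, `j`, `e`, `o`, `i`, `x`,
#' `s`, `p`; a transcript matching nothing is `u` (unknown, intergenic).
#' Ties across references are broken by largest exonic overlap, then
#' lexicographically smallest reference id. Strand-unknown queries are
#' compared against both strands but are never eligible for `=` or `j`.
#'
#' @param t_exons Exon tibble of a single transcript.
#' @param index A `reference_index` from [build_interval_index()].
#' @param run_on_distance Maximum distance (bp) downstream of a same-strand
#'   reference 3' end for the polymerase run-on code `p`.
#' @return One-row tibble: `transcript_id`, `class_code`, `best_reference`
#'   (empty string for `u`), `n_exons`.
#' @export
assign_class_code <- function(t_exons, index, run_on_distance = 2000L) {
  q_span <- transcript_spans(t_exons)
  if (nrow(q_span) != 1) abort("assign_class_code expects exactly one transcript")
  q_exons <- arrange(t_exons[c("start", "end")], .data$start)
  q_introns <- transcript_introns(t_exons)[c("start", "end")]
  cands <- query_index(index, q_span$chrom,
                       max(0L, q_span$start - run_on_distance),
                       q_span$end + run_on_distance)
  best_code <- "u"
  best_ref <- ""
  best_ov <- -1L
  empty_introns <- tibble(start = integer(), end = integer())
  for (i in seq_len(nrow(cands))) {
    rid <- cands$transcript_id[i]
    res <- code_against_reference(
      q_span, q_exons, q_introns,
      cands[i, ], index$exons[[rid]],
      index$introns[[rid]] %val% empty_introns,
      run_on_distance
    )
    if (is.null(res)) next
    rank_new <- match(res$code, CLASS_PRECEDENCE)
    rank_old <- match(best_code, CLASS_PRECEDENCE)
    better <- rank_new < rank_old ||
      (rank_new == rank_old &&
         (res$overlap > best_ov ||
            (res$overlap == best_ov && rid < best_ref)))
    if (better) {
      best_code <- res$code
      best_ref <- rid
      best_ov <- res$overlap
    }
  }
  tibble(transcript_id = q_span$transcript_id, class_code = best_code,
         best_reference = if (best_code == "u") "" else best_ref,
         n_exons = q_span$n_exons)
}

#' Classify every assembled transcript against the reference
#'
#' @param exons Exon tibble of assembled transcripts.
#' @param index A `reference_index` over all reference sets.
#' @param run_on_distance See [assign_class_code()].
#' @param strand_unknown `"both"` (default) compares strand-unknown
#'   transcripts against both strands; `"drop"` removes them from the
#'   output instead.
#' @return Tibble with one row per transcript: `transcript_id`,
#'   `class_code`, `best_reference`, `n_exons`.
#' @export
classify_transcripts <- function(exons, index, run_on_distance = 2000L,
                                 strand_unknown = c("both", "drop")) {
  strand_unknown <- match.arg(strand_unknown)
  if (strand_unknown == "drop") {
    exons <- filter(exons, .data$strand != "*")
  }
  if (nrow(exons) == 0) {
    return(tibble(transcript_id = character(), class_code = character(),
                  best_reference = character(), n_exons = integer()))
  }
  exons |>
    split(exons$transcript_id) |>
    purrr::map(assign_class_code, index = index,
               run_on_distance = run_on_distance) |>
    bind_rows() |>
    arrange(.data$transcript_id)
}

#' Select candidate intergenic transcripts
#'
#' Keeps exactly the transcripts with class code `u` and at least two
#' exons — the multi-exon unknown intergenic candidates carried into the
#' coding-potential filters.
#'
#' @param coded Class-code tibble from [classify_transcripts()].
#' @return The filtered rows of `coded`.
#' @export
select_candidates <- function(coded) {
  filter(coded, .data$class_code == "u", .data$n_exons >= 2L)
}

#' Tabulate class-code counts
#'
#' @param coded Class-code tibble from [classify_transcripts()].
#' @return Tibble with one row per code (all ten codes, zero-filled) and a
#'   count column `n`; counts sum to the number of input transcripts.
#' @export
summarize_classes <- function(coded) {
  counts <- count(coded, .data$class_code)
  tibble(class_code = CLASS_CODES) |>
    left_join(counts, by = "class_code") |>
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)))
}
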