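#' Per-transcript spans and summary columns
#'
#' Collapses a tidy exon table to one row per transcript, with the genomic
#' span (first exon start to last exon end), exon count and spliced length
#' (sum of exon lengths, the length statistic used for lincRNA summaries).
#'
#' @param exons Exon tibble as returned by [read_gtf()].
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `n_exons`, `spliced_length`, `biotype`.
#' @export
transcript_spans <- function(exons) {
  check_intervals(exons, "exon")
  if (nrow(exons) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  start = integer(), end = integer(), n_exons = integer(),
                  spliced_length = integer(), biotype = character()))
  }
  exons |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      # spliced length first: summarise masks start/end once redefined
      spliced_length = sum(.data$end - .data$start),
      n_exons = n(),
      start = min(.data$start),
      end = max(.data$end),
      biotype = first(.data$biotype),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "n_exons", "spliced_length", "biotype")
}

#' Per-gene spans
#'
#' The span of a gene is the union (min start, max end) of its transcripts'
#' spans on its chromosome.
#'
#' @param exons Exon tibble.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_spans <- function(exons) {
  transcript_spans(exons) |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )
}

#' Intron intervals of each transcript
#'
#' @param exons Exon tibble.
#' @return Tibble with one row per intron: `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @keywords internal
transcript_introns <- function(exons) {
  exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(intron_start = .data$end, intron_end = dplyr::lead(.data$start)) |>
    filter(!is.na(.data$intron_end)) |>
    ungroup() |>
    select(transcript_id = "transcript_id", chrom = "chrom",
           strand = "strand", start = "intron_start", end = "intron_end")
}

#' Group transcripts into loci by span overlap
#'
#' Assigns a locus id to each transcript by single-linkage clustering of
#' span-overlapping transcripts on the same chromosome and strand
#' (strand-unknown transcripts link with either strand). This is the rule
#' used to report distinct non-coding loci for a lincRNA set.
#'
#' @param spans Transcript span tibble from [transcript_spans()].
#' @return `spans` with an added `locus_id` column (`locus_1`, ...).
#' @export
assign_loci <- function(spans) {
  check_intervals(spans, "span")
  if (nrow(spans) == 0) return(mutate(spans, locus_id = character(0)))
  spans <- arrange(spans, .data$chrom, .data$start, .data$end)
  strand_key <- function(s) if (s == "*") c("+", "-") else s
  # single linkage: sweep each chrom+strand lane, chaining overlaps
  n <- nrow(spans)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
    invisible(NULL)
  }
  for (lane_strand in c("+", "-")) {
    idx <- which(spans$strand %in% c(lane_strand, "*"))
    if (length(idx) < 2) next
    by_chrom <- split(idx, spans$chrom[idx])
    for (ids in by_chrom) {
      if (length(ids) < 2) next
      max_end <- spans$end[ids[1]]
      open <- ids[1]
      for (i in ids[-1]) {
        if (spans$start[i] < max_end) union_(open, i) else open <- i
        max_end <- max(max_end, spans$end[i])
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  locus <- match(roots, unique(roots))
  mutate(spans, locus_id = paste0("locus_", locus))
}
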