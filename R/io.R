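#' Read exon models from a GTF file
#'
#' Parses the `exon` features of a GTF file (Ensembl/UCSC dialect, 1-based
#' inclusive coordinates, `transcript_id` and `gene_id` attributes) into a
#' tidy exon table using 0-based half-open coordinates. Exons are grouped by
#' transcript and sorted by start; a transcript whose lines disagree on
#' strand or chromosome, or whose exons overlap one another, is rejected.
#'
#' @param path Path to a GTF file.
#' @param biotype Biotype label attached to every transcript read from this
#'   file, one of `"protein_coding"`, `"known_noncoding"`, `"small_rna"`,
#'   `"assembled_unknown"`.
#' @return A tibble with one row per exon and columns `chrom`, `start`,
#'   `end`, `strand` (`"+"`, `"-"`, or `"*"` for unknown), `transcript_id`,
#'   `gene_id`, `biotype`.
#' @export
read_gtf <- function(path, biotype = c("assembled_unknown", "protein_coding",
                                       "known_noncoding", "small_rna")) {
  biotype <- match.arg(biotype)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) return(empty_exon_table())
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    abort(paste0("GTF parse error at line ", idx[which(nf < 9)[1]],
                 ": expected 9 tab-separated fields"))
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1 | end1 < start1)
  if (length(bad) > 0) {
    abort(paste0("GTF parse error at line ", idx[bad[1]],
                 ": invalid coordinates"))
  }
  tid <- stringr::str_match(m[, 9], 'transcript_id\\s+"([^"]+)"')[, 2]
  gid <- stringr::str_match(m[, 9], 'gene_id\\s+"([^"]+)"')[, 2]
  is_exon <- m[, 3] == "exon"
  if (any(is_exon & is.na(tid))) {
    abort(paste0("GTF parse error at line ", idx[which(is_exon & is.na(tid))[1]],
                 ": exon feature lacks transcript_id attribute"))
  }
  exons <- tibble(
    chrom = m[is_exon, 1],
    start = start1[is_exon] - 1L,
    end = end1[is_exon],
    strand = if_else(m[is_exon, 7] %in% c("+", "-"), m[is_exon, 7], "*"),
    transcript_id = tid[is_exon],
    gene_id = if_else(is.na(gid[is_exon]), tid[is_exon], gid[is_exon]),
    biotype = biotype
  )
  if (nrow(exons) == 0) return(empty_exon_table())
  validate_exons(exons)
}

empty_exon_table <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), transcript_id = character(),
         gene_id = character(), biotype = character())
}

#' Validate a tidy exon table
#'
#' Checks the transcript-model invariants: valid half-open intervals, one
#' chromosome and strand per transcript, and non-overlapping exons with
#' intron gaps of at least 1 bp. Returns the table sorted by transcript and
#' exon start.
#'
#' @param exons Exon tibble as returned by [read_gtf()].
#' @return The validated, sorted exon tibble.
#' @export
validate_exons <- function(exons) {
  check_intervals(exons, "exon")
  check_strand(exons$strand)
  exons <- arrange(exons, .data$transcript_id, .data$start)
  per_tx <- group_by(exons, .data$transcript_id)
  conflict <- summarise(per_tx,
                        n_chrom = dplyr::n_distinct(.data$chrom),
                        n_strand = dplyr::n_distinct(.data$strand))
  bad <- filter(conflict, .data$n_chrom > 1 | .data$n_strand > 1)
  if (nrow(bad) > 0) {
    abort(paste0("transcript(s) with conflicting chromosome or strand: ",
                 paste(head(bad$transcript_id, 5), collapse = ", ")))
  }
  ovl <- summarise(per_tx,
                   bad = any(.data$start <= dplyr::lag(.data$end, default = -1L)))
  bad <- filter(ovl, .data$bad)
  if (nrow(bad) > 0) {
    abort(paste0("transcript(s) with overlapping or abutting exons: ",
                 paste(head(bad$transcript_id, 5), collapse = ", ")))
  }
  ungroup(exons)
}

#' Write exon models to a GTF file
#'
#' Inverse of [read_gtf()]: emits one `exon` line per row, converting
#' internal 0-based half-open coordinates back to 1-based inclusive.
#'
#' @param exons Exon tibble.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, source = "lincfinder") {
  check_intervals(exons, "exon")
  lines <- character(0)
  if (nrow(exons) > 0) {
    exons <- arrange(exons, .data$transcript_id, .data$start)
    strand <- if_else(exons$strand %in% c("+", "-"), exons$strand, ".")
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     exons$gene_id, exons$transcript_id)
    lines <- paste(exons$chrom, source, "exon", exons$start + 1L, exons$end,
                   ".", strand, ".", attrs, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read nucleotide sequences from a FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header;
#' sequences are upper-cased and restricted to the alphabet A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `transcript_id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids) > 0) {
    abort(paste0("duplicate sequence id in FASTA: ",
                 ids[which(duplicated(ids))[1]]))
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-nucleotide character in FASTA record: ",
                 ids[which(bad)[1]]))
  }
  tibble(transcript_id = unname(ids), sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `transcript_id` and `sequence`.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  check_sequences(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$transcript_id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a transcripts-by-conditions FPKM table
#'
#' Expects a tab-separated file whose header row names the conditions and
#' whose first column holds transcript ids. Missing, non-numeric and
#' negative values are rejected.
#'
#' @param path Path to the TSV file.
#' @return A tibble with column `transcript_id` followed by one numeric
#'   column per condition.
#' @export
read_expression_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(readr::problems(raw)) > 0) {
    abort(paste0("malformed expression table (ragged rows?): ", path))
  }
  names(raw)[1] <- "transcript_id"
  if (ncol(raw) < 2) abort("expression table needs at least one condition column")
  vals <- purrr::map(raw[-1], function(x) suppressWarnings(as.numeric(x)))
  if (any(purrr::map_lgl(vals, function(x) any(is.na(x))))) {
    abort("expression table contains missing or non-numeric values")
  }
  if (any(purrr::map_lgl(vals, function(x) any(x < 0)))) {
    abort("expression table contains negative FPKM values")
  }
  bind_cols(raw["transcript_id"], as_tibble(vals))
}

#' Write an expression table to TSV
#'
#' @param expr Expression tibble (`transcript_id` plus condition columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Condition names of an expression table
#' @param expr Expression tibble.
#' @return Character vector of condition column names.
#' @export
expression_conditions <- function(expr) {
  setdiff(names(expr), "transcript_id")
}

#' Write named loci to a BED6 file
#'
#' @param loci Tibble with columns `chrom`, `start`, `end`, `name` and
#'   optionally `strand` (unknown strand is written as `"."`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  check_intervals(loci, "locus")
  lines <- character(0)
  if (nrow(loci) > 0) {
    strand <- loci$strand %val% rep("*", nrow(loci))
    strand <- if_else(strand %in% c("+", "-"), strand, ".")
    lines <- paste(loci$chrom, loci$start, loci$end, loci$name, 0L, strand,
                   sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into a locus table
#'
#' Accepts BED4 or wider; only the first six columns are used.
#'
#' @param path Path to a BED file.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4)) abort("BED line with fewer than 4 fields")
  get <- function(i, default = NA_character_) {
    purrr::map_chr(fields, function(f) if (length(f) >= i) f[i] else default)
  }
  out <- tibble(
    chrom = get(1),
    start = as.integer(get(2)),
    end = as.integer(get(3)),
    name = get(4),
    strand = get(6, ".")
  )
  out$strand <- if_else(out$strand %in% c("+", "-"), out$strand, "*")
  check_intervals(out, "BED locus")
  out
}

#' Read a per-transcript score table (e.g. conservation coding scores)
#'
#' @param path TSV with columns `transcript_id` and `score`.
#' @return Tibble with those two columns.
#' @export
read_score_table <- function(path) {
  out <- readr::read_tsv(path, col_types = "cd", progress = FALSE)
  names(out)[1:2] <- c("transcript_id", "score")
  if (any(is.na(out$score))) abort("score table contains missing scores")
  out
}

#' Read a per-transcript protein-domain hit table
#'
#' @param path TSV with columns `transcript_id`, `domain_accession`,
#'   `e_value`.
#' @return Tibble with those columns.
#' @export
read_domain_table <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  names(out)[1:3] <- c("transcript_id", "domain_accession", "e_value")
  out
}

#' Read a gene-to-GO-term map
#'
#' @param path Two-column TSV (`gene_id`, `term_id`).
#' @return Tibble with columns `gene_id` and `term_id`.
#' @export
read_go_map <- function(path) {
  out <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(out)[1:2] <- c("gene_id", "term_id")
  distinct(out)
}

#' Read GO term metadata
#'
#' @param path TSV with columns `term_id`, `category` (BP/MF/CC), `name`.
#' @return Tibble with those columns.
#' @export
read_go_terms <- function(path) {
  out <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  names(out)[1:3] <- c("term_id", "category", "name")
  out
}
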