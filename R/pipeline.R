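#' Assemble and validate a pipeline run configuration
#'
#' Collects the input paths and thresholds of a full run. Unknown
#' arguments are rejected; thresholds are range-checked.
#'
#' @param reference_gtfs Named list of reference GTF paths; names give the
#'   biotype of each file (`protein_coding`, `small_rna`,
#'   `known_noncoding`).
#' @param assembled_gtf Path to the assembled-transcript GTF.
#' @param transcripts_fasta FASTA of assembled transcript sequences.
#' @param training_coding_fasta,training_noncoding_fasta Labeled training
#'   FASTAs for the coding-potential model (ignored when `model_json` is
#'   given).
#' @param model_json Optional path to a saved coding model.
#' @param conservation_tsv,domain_tsv Optional precomputed score/hit
#'   tables.
#' @param linc_expression_tsv,gene_expression_tsv Expression tables for
#'   characterization.
#' @param catalogues Named list of BED paths of external lncRNA
#'   catalogues (may be empty).
#' @param go_map_tsv,go_terms_tsv GO annotation tables.
#' @param out_dir Output directory.
#' @param max_orf_aa,cpat_cutoff,js_cutoff,neighbor_window,pcc_threshold,run_on_distance,min_overlap_bp,fdr
#'   Thresholds; `cpat_cutoff = NULL` derives the cutoff from held-out
#'   training data (two-graph ROC). A fixed value such as the 0.348 used
#'   for bovine-trained models may be supplied instead.
#' @param seed Integer seed for the model training split.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(reference_gtfs, assembled_gtf, transcripts_fasta,
                       training_coding_fasta = NULL,
                       training_noncoding_fasta = NULL,
                       model_json = NULL,
                       conservation_tsv = NULL, domain_tsv = NULL,
                       linc_expression_tsv = NULL,
                       gene_expression_tsv = NULL,
                       catalogues = list(),
                       go_map_tsv = NULL, go_terms_tsv = NULL,
                       out_dir = tempfile("linc_run_"),
                       max_orf_aa = 100L, cpat_cutoff = NULL,
                       js_cutoff = 0.5, neighbor_window = 50000L,
                       pcc_threshold = 0.9, run_on_distance = 2000L,
                       min_overlap_bp = 1L, fdr = 0.05, seed = 1L) {
  stopifnot(js_cutoff > 0, js_cutoff < 1, max_orf_aa > 0,
            neighbor_window >= 0, pcc_threshold >= 0, pcc_threshold <= 1,
            run_on_distance >= 0, min_overlap_bp >= 1, fdr > 0, fdr <= 1)
  if (!is.null(cpat_cutoff)) {
    stopifnot(cpat_cutoff > 0, cpat_cutoff < 1)
  }
  structure(as.list(environment()), class = "run_config")
}

read_references <- function(reference_gtfs) {
  allowed <- c("protein_coding", "small_rna", "known_noncoding")
  bad <- setdiff(names(reference_gtfs), allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown reference biotype(s): ", paste(bad, collapse = ", ")))
  }
  bind_rows(purrr::imap(reference_gtfs, function(path, bt) {
    read_gtf(path, biotype = bt)
  }))
}

#' Identify lincRNAs from assembled transcripts
#'
#' Runs the identification cascade: class-code assignment against the
#' reference annotation, selection of multi-exon intergenic (`u`)
#' candidates, coding-potential scoring with the logistic model, and the
#' conservation / protein-domain / maximal-ORF decision rules. Writes the
#' final lincRNA GTF, per-stage tables and a BED of distinct loci to the
#' output directory.
#'
#' @param config A `run_config`.
#' @return A list of class `linc_run`: `report` (stage counts and summary
#'   statistics), `class_codes`, `filters`, `lincrnas` (final spans with
#'   locus ids), `model`, and `files`.
#' @export
run_identify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  needed <- c(unlist(config$reference_gtfs), config$assembled_gtf,
              config$transcripts_fasta)
  missing_in <- needed[!file.exists(needed)]
  if (length(missing_in) > 0) {
    abort(paste0("missing input file(s): ", paste(missing_in, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)

  refs <- read_references(config$reference_gtfs)
  index <- build_interval_index(refs)
  assembled <- read_gtf(config$assembled_gtf)
  coded <- classify_transcripts(assembled, index,
                                run_on_distance = config$run_on_distance)
  class_summary <- summarize_classes(coded)
  candidates <- select_candidates(coded)

  seqs <- read_fasta(config$transcripts_fasta)
  model <- if (!is.null(config$model_json)) {
    read_coding_model(config$model_json)
  } else {
    set.seed(config$seed)
    m <- fit_coding_model(read_fasta(config$training_coding_fasta),
                          read_fasta(config$training_noncoding_fasta))
    if (!is.null(config$cpat_cutoff)) m$cutoff <- config$cpat_cutoff
    m
  }
  cand_seqs <- semi_join(seqs, candidates, by = "transcript_id")
  conservation <- if (is.null(config$conservation_tsv)) NULL else
    read_score_table(config$conservation_tsv)
  domains <- if (is.null(config$domain_tsv)) NULL else
    read_domain_table(config$domain_tsv)
  filters <- apply_noncoding_filters(cand_seqs, model,
                                     conservation = conservation,
                                     domains = domains,
                                     max_orf_aa = config$max_orf_aa)
  final_ids <- filters$transcript_id[filters$is_noncoding]
  linc_exons <- filter(assembled, .data$transcript_id %in% final_ids)
  linc_spans <- assign_loci(transcript_spans(linc_exons))
  stats <- summarize_lincrnas(linc_exons)
  chrom_tab <- chromosome_counts(linc_exons)

  write_gtf(linc_exons, out("lincrna.gtf"))
  readr::write_tsv(select(coded, -"n_exons"), out("class_codes.tsv"),
                   progress = FALSE)
  readr::write_tsv(class_summary, out("class_summary.tsv"), progress = FALSE)
  readr::write_tsv(filters, out("coding_filters.tsv"), progress = FALSE)
  write_bed(mutate(linc_spans, name = .data$transcript_id), out("lincrna.bed"))
  loci_bed <- linc_spans |>
    group_by(.data$locus_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop") |>
    rename(name = "locus_id")
  write_bed(loci_bed, out("lincrna_loci.bed"))
  write_coding_model(model, out("coding_model.json"))

  report <- list(
    n_assembled = dplyr::n_distinct(assembled$transcript_id),
    class_summary = class_summary,
    n_candidates = nrow(candidates),
    n_noncoding = sum(filters$is_noncoding),
    n_lincrnas = length(final_ids),
    n_loci = dplyr::n_distinct(linc_spans$locus_id),
    skipped = c(
      if (is.null(conservation)) "conservation filter (no score table)",
      if (is.null(domains)) "domain filter (no hit table)"
    ),
    stats = stats,
    chromosome_counts = chrom_tab,
    config = config[setdiff(names(config), "catalogues")]
  )
  jsonlite::write_json(
    report[c("n_assembled", "n_candidates", "n_noncoding", "n_lincrnas",
             "n_loci")],
    out("identify_report.json"), auto_unbox = TRUE, digits = NA
  )
  structure(
    list(report = report, class_codes = coded, filters = filters,
         lincrnas = linc_spans, model = model,
         files = list(lincrna_gtf = out("lincrna.gtf"),
                      lincrna_bed = out("lincrna.bed"),
                      loci_bed = out("lincrna_loci.bed"))),
    class = "linc_run"
  )
}

#' @export
print.linc_run <- function(x, ...) {
  r <- x$report
  cat("<linc_run>", r$n_assembled, "assembled ->", r$n_candidates,
      "multi-exon intergenic candidates ->", r$n_lincrnas, "lincRNAs (",
      r$n_loci, "loci )\n")
  invisible(x)
}

#' Characterize an identified lincRNA set
#'
#' Runs the downstream stages on the output of [run_identify()]: the
#' Jensen-Shannon specificity scores with the cutoff calling, the
#' locus-overlap comparison against any external catalogues, and the
#' cis-neighbor analysis (JS-selected lincRNAs, window search, Pearson
#' correlation, hypergeometric GO enrichment). Optional stages without
#' inputs are skipped and listed in the report.
#'
#' @param config A `run_config`.
#' @param identified A `linc_run` from [run_identify()].
#' @return A list of class `linc_characterization` with `specificity`,
#'   `specificity_summary`, `catalogue_membership`, `neighbors`,
#'   `enrichment` and `report`.
#' @export
run_characterize <- function(config, identified) {
  stopifnot(inherits(config, "run_config"), inherits(identified, "linc_run"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  skipped <- character(0)
  lincs <- identified$lincrnas

  if (is.null(config$linc_expression_tsv)) {
    abort("characterization requires linc_expression_tsv")
  }
  expr <- read_expression_table(config$linc_expression_tsv)
  missing_expr <- setdiff(lincs$transcript_id, expr$transcript_id)
  if (length(missing_expr) > 0) {
    message(length(missing_expr),
            " lincRNA(s) without expression rows were excluded")
  }
  expr <- filter(expr, .data$transcript_id %in% lincs$transcript_id)
  scores <- call_specific(specificity_scores(expr), cutoff = config$js_cutoff)
  spec_summary <- specificity_summary(scores)
  readr::write_tsv(scores, out("specificity.tsv"), progress = FALSE)

  membership <- NULL
  if (length(config$catalogues) > 0) {
    primary <- lincs |>
      select("chrom", "start", "end", name = "transcript_id", "strand")
    others <- purrr::map(config$catalogues, read_bed)
    membership <- multi_set_membership(primary, others,
                                       min_overlap_bp = config$min_overlap_bp)
    readr::write_tsv(membership, out("catalogue_membership.tsv"),
                     progress = FALSE)
  } else {
    skipped <- c(skipped, "catalogue comparison (no external catalogues)")
  }

  neighbors <- NULL
  enrichment <- NULL
  if (!is.null(config$gene_expression_tsv)) {
    specific_ids <- scores$transcript_id[!is.na(scores$is_specific) &
                                           scores$is_specific]
    sel <- filter(lincs, .data$transcript_id %in% specific_ids)
    gene_expr <- read_expression_table(config$gene_expression_tsv)
    genes <- gene_spans(read_references(config$reference_gtfs)) |>
      filter(.data$gene_id %in% gene_expr$transcript_id)
    sel_bed <- select(sel, "chrom", "start", "end",
                      name = "transcript_id", "strand")
    pairs <- find_neighbors(sel_bed, genes, window = config$neighbor_window)
    neighbors <- correlate_neighbors(pairs, expr, gene_expr,
                                     threshold = config$pcc_threshold)
    readr::write_tsv(neighbors, out("neighbor_links.tsv"), progress = FALSE)
    if (!is.null(config$go_map_tsv)) {
      foreground <- unique(neighbors$gene_id[neighbors$strong])
      go_map <- read_go_map(config$go_map_tsv)
      go_terms <- if (is.null(config$go_terms_tsv)) NULL else
        read_go_terms(config$go_terms_tsv)
      if (length(foreground) > 0) {
        enrichment <- go_enrichment(foreground, genes$gene_id, go_map,
                                    go_terms = go_terms, fdr = config$fdr)
        readr::write_tsv(enrichment, out("go_enrichment.tsv"),
                         progress = FALSE)
      } else {
        skipped <- c(skipped, "GO enrichment (no strongly correlated genes)")
      }
    } else {
      skipped <- c(skipped, "GO enrichment (no GO map)")
    }
  } else {
    skipped <- c(skipped, "cis-neighbor analysis (no gene expression)")
  }

  structure(
    list(specificity = scores, specificity_summary = spec_summary,
         catalogue_membership = membership, neighbors = neighbors,
         enrichment = enrichment,
         report = list(skipped = skipped,
                       n_specific = spec_summary$n_specific,
                       frac_specific = spec_summary$frac_specific,
                       frac_js1 = spec_summary$frac_js1)),
    class = "linc_characterization"
  )
}

#' Summary statistics of a lincRNA set
#'
#' Transcript length is the spliced (exonic) length, not the genomic
#' span; dispersions are sample standard deviations.
#'
#' @param exons Exon tibble of the final lincRNA set.
#' @return One-row tibble: `n_transcripts`, `mean_length`, `sd_length`,
#'   `mean_exons`, `sd_exons` (zeros and NAs for an empty set).
#' @export
summarize_lincrnas <- function(exons) {
  spans <- transcript_spans(exons)
  if (nrow(spans) == 0) {
    return(tibble(n_transcripts = 0L, mean_length = NA_real_,
                  sd_length = NA_real_, mean_exons = NA_real_,
                  sd_exons = NA_real_))
  }
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  tibble(
    n_transcripts = nrow(spans),
    mean_length = mean(spans$spliced_length),
    sd_length = sd0(spans$spliced_length),
    mean_exons = mean(spans$n_exons),
    sd_exons = sd0(spans$n_exons)
  )
}

#' Per-chromosome transcript counts
#'
#' @param exons Exon tibble.
#' @return Tibble with columns `chrom` and `n`; counts sum to the number
#'   of transcripts.
#' @export
chromosome_counts <- function(exons) {
  transcript_spans(exons) |>
    count(.data$chrom, name = "n") |>
    arrange(dplyr::desc(.data$n))
}

#' Sequencing/alignment summary percentages
#'
#' Given ordered read-processing counts (e.g. raw reads, clean reads,
#' mapped reads, concordant pair alignments), computes each stage's
#' percentage relative to the preceding stage — the arithmetic behind a
#' sequencing summary table, e.g. concordant pairs as a percentage of
#' mapped reads.
#'
#' @param counts Tibble with columns `category` and `reads`, ordered from
#'   rawest to most derived.
#' @return `counts` with an added `pct_of_previous` column (NA for the
#'   first row).
#' @export
alignment_concordance <- function(counts) {
  stopifnot(all(c("category", "reads") %in% names(counts)))
  mutate(counts,
         pct_of_previous = 100 * .data$reads / dplyr::lag(.data$reads))
}
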