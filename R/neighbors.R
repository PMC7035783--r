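#' Find protein-coding neighbors of lincRNA loci
#'
#' A gene is a neighbor of a lincRNA when its span overlaps the lincRNA
#' span extended by `window` bp on both sides — i.e. the closest edges are
#' at most `window` bp apart (the window boundary is inclusive). Both
#' strands are eligible; distance is edge-to-edge bp, 0 when the spans
#' overlap.
#'
#' @param lincs Locus tibble of lincRNAs (`chrom`, `start`, `end`,
#'   `name`); upstream selection (e.g. JS score > 0.5) is the caller's
#'   responsibility.
#' @param genes Gene span tibble (`gene_id`, `chrom`, `start`, `end`) as
#'   from [gene_spans()].
#' @param window Flanking window in bp on either side (default 50 kb).
#' @return Tibble with columns `lincrna_id`, `gene_id`, `distance`.
#' @export
find_neighbors <- function(lincs, genes, window = 50000L) {
  check_intervals(lincs, "lincRNA locus")
  check_intervals(genes, "gene span")
  rows <- purrr::map(seq_len(nrow(lincs)), function(i) {
    same <- which(genes$chrom == lincs$chrom[i])
    if (length(same) == 0) return(NULL)
    d <- interval_distance(lincs$start[i], lincs$end[i],
                           genes$start[same], genes$end[same])
    keep <- d <= window
    if (!any(keep)) return(NULL)
    tibble(lincrna_id = lincs$name[i],
           gene_id = genes$gene_id[same][keep],
           distance = as.integer(d[keep]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(lincrna_id = character(), gene_id = character(),
                  distance = integer()))
  }
  arrange(out, .data$lincrna_id, .data$gene_id)
}

#' Correlate lincRNA-neighbor expression profiles
#'
#' Computes the product-moment correlation between each paired lincRNA and
#' gene across the shared, identically ordered condition set; pairs where
#' either profile has zero variance are dropped (their correlation is
#' undefined) and reported via a message.
#'
#' @param pairs Tibble from [find_neighbors()].
#' @param linc_expr,gene_expr Expression tibbles for lincRNAs and genes
#'   over the same ordered conditions.
#' @param threshold Absolute-correlation threshold for the `strong` flag.
#' @param method `"pearson"` (normative) or `"spearman"`.
#' @return Tibble of neighbor links: `lincrna_id`, `gene_id`, `distance`,
#'   `pcc`, `strong`.
#' @export
correlate_neighbors <- function(pairs, linc_expr, gene_expr,
                                threshold = 0.9,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  conds <- expression_conditions(linc_expr)
  if (!identical(conds, expression_conditions(gene_expr))) {
    abort("lincRNA and gene expression tables must share the same ordered conditions")
  }
  lmat <- as.matrix(linc_expr[conds])
  rownames(lmat) <- linc_expr$transcript_id
  gmat <- as.matrix(gene_expr[conds])
  rownames(gmat) <- gene_expr$transcript_id
  pairs <- filter(pairs, .data$lincrna_id %in% rownames(lmat),
                  .data$gene_id %in% rownames(gmat))
  pcc <- purrr::map2_dbl(pairs$lincrna_id, pairs$gene_id, function(l, g) {
    x <- lmat[l, ]
    y <- gmat[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  })
  dropped <- sum(is.na(pcc))
  if (dropped > 0) {
    message(dropped, " pair(s) dropped: zero variance in a profile")
  }
  pairs |>
    mutate(pcc = pcc, strong = abs(pcc) >= threshold) |>
    filter(!is.na(.data$pcc))
}

#' Hypergeometric GO-term enrichment
#'
#' For each term annotated to at least one foreground gene, computes the
#' upper-tail hypergeometric probability of drawing at least `k` genes
#' with the term in a sample of `n` from a background of `N` containing
#' `K` term-carrying genes, then adjusts with Benjamini-Hochberg within
#' each GO category.
#'
#' @param foreground Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param background Character vector of background genes.
#' @param go_map Tibble (`gene_id`, `term_id`).
#' @param go_terms Optional term metadata tibble (`term_id`, `category`,
#'   `name`); when absent all terms share one category.
#' @param fdr Adjusted-p threshold recorded in the `significant` column.
#' @return Tibble sorted by `adjusted_p`: `term_id`, `category`, `name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`, `significant`.
#' @export
go_enrichment <- function(foreground, background, go_map, go_terms = NULL,
                          fdr = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (length(foreground) == 0) abort("empty foreground gene set")
  if (!all(foreground %in% background)) {
    abort("foreground must be a subset of the background")
  }
  go_map <- filter(go_map, .data$gene_id %in% background)
  n <- length(foreground)
  N <- length(background)
  per_term <- go_map |>
    group_by(.data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(.data$gene_id[
                .data$gene_id %in% foreground]),
              .groups = "drop") |>
    filter(.data$k > 0)
  if (nrow(per_term) == 0) {
    return(tibble(term_id = character(), category = character(),
                  name = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), p_value = numeric(),
                  adjusted_p = numeric(), significant = logical()))
  }
  out <- per_term |>
    mutate(
      n = n, N = N,
      p_value = phyper(.data$k - 1L, .data$K, N - .data$K, n,
                       lower.tail = FALSE)
    )
  if (!is.null(go_terms)) {
    out <- left_join(out, go_terms, by = "term_id")
    if (!"category" %in% names(out)) out$category <- "all"
    if (!"name" %in% names(out)) out$name <- NA_character_
  } else {
    out$category <- "all"
    out$name <- NA_character_
  }
  out$category[is.na(out$category)] <- "all"
  out <- out |>
    group_by(.data$category) |>
    mutate(adjusted_p = p.adjust(.data$p_value, method = "BH")) |>
    ungroup() |>
    mutate(significant = .data$adjusted_p <= fdr) |>
    select("term_id", "category", "name", "k", "K", "n", "N",
           "p_value", "adjusted_p", "significant") |>
    arrange(.data$adjusted_p, .data$term_id)
  out
}
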