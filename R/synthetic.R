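#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module with desk-scale
#' defaults: a toy two-chromosome genome, a reference annotation of
#' multi-exon coding genes and single-exon small RNAs, assembled
#' transcripts planted to satisfy each class-code definition, sequence
#' regimes with distinct first-order composition for coding and noncoding
#' labels, a transcripts-by-conditions FPKM matrix with planted
#' specificity patterns, latent-factor correlated lincRNA-gene pairs, and
#' a GO map with one planted enriched term.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_chroms,chrom_length Toy genome shape.
#' @param n_coding_genes,n_small_rnas Reference annotation sizes.
#' @param n_assembled Named integer vector of transcripts to plant per
#'   class code.
#' @param n_single_exon_u Extra single-exon intergenic transcripts (true
#'   class `u` but never candidates), exercising the multi-exon filter.
#' @param u_coding_fraction Fraction of multi-exon `u` transcripts given a
#'   protein-coding sequence regime (to be removed by the coding filters).
#' @param coding_orf_range ORF length range (nt, including start and stop
#'   codons) for coding-labeled sequences and CDS training sequences.
#' @param noncoding_max_orf_aa Maximal-ORF cap (aa) enforced by rejection
#'   sampling on noncoding-labeled sequences; kept well under the
#'   100-aa filter threshold so planted labels are unambiguous.
#' @param coding_gc_bias Strength of the GC-rich codon bias of the coding
#'   regime (log-weight per G/C in a codon).
#' @param training_n Training sequences per class.
#' @param training_length_range Length range (nt) of noncoding training
#'   sequences.
#' @param n_conditions Number of expression conditions (tissues; the first
#'   is the oocyte-like focal condition).
#' @param specificity_mix Fractions of single-condition, few-condition and
#'   ubiquitous expression patterns among lincRNAs (must sum to 1).
#' @param correlated_fraction Fraction of lincRNA-gene neighbor pairs
#'   sharing a latent expression factor.
#' @param noise_sd Standard deviation of the multiplicative noise on
#'   correlated profiles (0 gives exactly linear pairs).
#' @param n_go_terms,go_background_prob,go_planted_fold GO map shape: term
#'   count, per-gene background annotation probability, and the planted
#'   term's fold enrichment over background in the foreground set.
#' @param run_on_distance Run-on distance used when placing `p` and `u`
#'   transcripts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L, chrom_length = 2000000L,
                             n_coding_genes = 40L, n_small_rnas = 10L,
                             n_assembled = c("=" = 20L, "c" = 20L, "j" = 20L,
                                             "e" = 20L, "i" = 20L, "o" = 20L,
                                             "p" = 20L, "u" = 40L, "x" = 20L,
                                             "s" = 20L),
                             n_single_exon_u = 10L,
                             u_coding_fraction = 0.3,
                             coding_orf_range = c(360L, 900L),
                             noncoding_max_orf_aa = 60L,
                             coding_gc_bias = 0.5,
                             training_n = 500L,
                             training_length_range = c(400L, 1200L),
                             n_conditions = 10L,
                             specificity_mix = c(single = 0.4, few = 0.3,
                                                 ubiquitous = 0.3),
                             correlated_fraction = 0.5,
                             noise_sd = 0.05,
                             n_go_terms = 50L,
                             go_background_prob = 0.05,
                             go_planted_fold = 10,
                             run_on_distance = 2000L) {
  if (abs(sum(specificity_mix) - 1) > 1e-9) {
    abort("specificity_mix must sum to 1")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

# First-order Markov sequence of length n over A/C/G/T.
rmarkov <- function(n, trans, init = rep(0.25, 4)) {
  bases <- c("A", "C", "G", "T")
  out <- integer(n)
  out[1] <- sample.int(4, 1, prob = init)
  for (i in seq_len(n - 1)) {
    out[i + 1] <- sample.int(4, 1, prob = trans[out[i], ])
  }
  paste(bases[out], collapse = "")
}

# Noncoding/background composition: mildly AT-rich with first-order
# dependence (A/T runs), which keeps random ORFs short.
NONCODING_TRANS <- matrix(c(
  0.35, 0.15, 0.15, 0.35,
  0.25, 0.25, 0.25, 0.25,
  0.25, 0.25, 0.25, 0.25,
  0.35, 0.15, 0.15, 0.35
), nrow = 4, byrow = TRUE)

# Codon table without stop codons, weighted toward G/C-rich codons.
coding_codon_pool <- function(gc_bias) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(bases, bases, paste0)), bases,
                            paste0))
  codons <- setdiff(codons, STOP_CODONS)
  gc <- vapply(strsplit(codons, ""), function(ch) sum(ch %in% c("C", "G")),
               numeric(1))
  list(codons = codons, weights = exp(gc_bias * gc))
}

# An in-frame CDS: ATG, stop-free biased codons, then a stop codon.
r_cds <- function(nt_length, pool) {
  n_codons <- nt_length %/% 3L
  body <- sample(pool$codons, n_codons - 2L, replace = TRUE,
                 prob = pool$weights)
  paste(c("ATG", body, sample(STOP_CODONS, 1)), collapse = "")
}

# Background sequence rejection-sampled to keep its maximal ORF short.
r_noncoding <- function(nt_length, max_aa, retries = 100L) {
  for (i in seq_len(retries)) {
    sq <- rmarkov(nt_length, NONCODING_TRANS)
    aa <- max(0L,
              purrr::map_int(purrr::compact(lapply(0:2, max_orf_in_frame,
                                                   seq = sq)),
                             "aa_length"))
    if (aa <= max_aa) return(sq)
  }
  abort("rejection sampling budget exceeded while drawing a noncoding sequence")
}

#' Generate a toy reference annotation
#'
#' Places non-overlapping multi-exon protein-coding genes and single-exon
#' small-RNA genes along the toy chromosomes with wide intergenic gaps,
#' leaving room for planted intergenic transcripts. Deterministic under
#' the config seed.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `exons` (reference exon tibble) and `gaps`
#'   (intergenic intervals wide enough for planting).
#' @export
generate_annotation <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  cursor <- setNames(rep(1000L, cfg$n_chroms), chroms)
  rows <- list()
  place_gene <- function(gene_id, tx_id, chrom, n_ex, exon_range,
                         intron_range, biotype) {
    gap <- sample(20000:40000, 1)
    start <- cursor[[chrom]] + gap
    exon_lens <- sample(exon_range[1]:exon_range[2], n_ex, replace = TRUE)
    intron_lens <- if (n_ex > 1) {
      sample(intron_range[1]:intron_range[2], n_ex - 1, replace = TRUE)
    } else integer(0)
    starts <- start + cumsum(c(0L, head(exon_lens, -1) + intron_lens))
    ends <- starts + exon_lens
    if (max(ends) > cfg$chrom_length) {
      abort("chromosome too short for the requested gene count")
    }
    cursor[[chrom]] <<- max(ends)
    tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
           strand = sample(c("+", "-"), 1), transcript_id = tx_id,
           gene_id = gene_id, biotype = biotype)
  }
  for (i in seq_len(cfg$n_coding_genes)) {
    chrom <- chroms[(i - 1) %% cfg$n_chroms + 1]
    rows[[length(rows) + 1]] <- place_gene(
      sprintf("ref_gene_%03d", i), sprintf("ref_tx_%03d", i), chrom,
      n_ex = sample(3:8, 1), exon_range = c(100L, 300L),
      intron_range = c(300L, 2000L), biotype = "protein_coding"
    )
  }
  for (i in seq_len(cfg$n_small_rnas)) {
    chrom <- chroms[(i - 1) %% cfg$n_chroms + 1]
    rows[[length(rows) + 1]] <- place_gene(
      sprintf("srna_gene_%03d", i), sprintf("srna_tx_%03d", i), chrom,
      n_ex = 1L, exon_range = c(70L, 150L), intron_range = c(0L, 0L),
      biotype = "small_rna"
    )
  }
  exons <- validate_exons(bind_rows(rows))
  spans <- transcript_spans(exons)
  gaps <- spans |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(gap_start = list(c(.data$end[-n()])),
              gap_end = list(c(.data$start[-1])), .groups = "drop") |>
    tidyr::unnest(c("gap_start", "gap_end")) |>
    rename(start = "gap_start", end = "gap_end") |>
    filter(.data$end - .data$start >= 15000L)
  list(exons = exons, gaps = gaps)
}

# Build an exon tibble for one planted transcript.
planted_tx <- function(tx_id, chrom, strand, starts, ends, true_class) {
  tibble(chrom = chrom, start = as.integer(starts), end = as.integer(ends),
         strand = strand, transcript_id = tx_id, gene_id = tx_id,
         biotype = "assembled_unknown")
}

#' Generate assembled transcripts with planted class codes
#'
#' For each requested class code, constructs transcripts whose geometry
#' satisfies that class's definition against the generated reference
#' (copying intron chains for `=`, merging terminal exons for `j`, placing
#' inside introns for `i`/`s`, beyond the run-on distance from everything
#' for `u`, and so on). Ground-truth codes are recorded for every
#' transcript.
#'
#' @param cfg A `synthetic_config`.
#' @param annotation Output of [generate_annotation()].
#' @return List with `exons` (assembled exon tibble) and `truth` (tibble
#'   `transcript_id`, `true_class`, `multi_exon`).
#' @export
generate_assembled <- function(cfg, annotation) {
  set.seed(cfg$seed + 1L)
  ref <- filter(annotation$exons, .data$biotype == "protein_coding")
  ref_spans <- transcript_spans(ref)
  ref_exons <- split(ref, ref$transcript_id)
  multi3 <- ref_spans$transcript_id[ref_spans$n_exons >= 3]
  if (length(multi3) == 0) abort("need references with >= 3 exons")
  rows <- list()
  truth <- list()
  counter <- 0L
  emit <- function(code, chrom, strand, starts, ends) {
    counter <<- counter + 1L
    tid <- sprintf("asm_%04d", counter)
    rows[[length(rows) + 1]] <<- planted_tx(tid, chrom, strand, starts, ends)
    truth[[length(truth) + 1]] <<- tibble(
      transcript_id = tid, true_class = code,
      multi_exon = length(starts) > 1
    )
  }
  pick_ref <- function(min_exons = 2) {
    ok <- ref_spans$transcript_id[ref_spans$n_exons >= min_exons]
    ref_exons[[sample(ok, 1)]] |> arrange(.data$start)
  }
  n_req <- function(code) {
    n <- cfg$n_assembled[[code]]
    if (is.null(n) || is.na(n)) 0L else as.integer(n)
  }
  for (k in seq_len(n_req("="))) {
    re <- pick_ref(2)
    emit("=", re$chrom[1], re$strand[1], re$start, re$end)
  }
  for (k in seq_len(n_req("c"))) {
    re <- pick_ref(3)
    n <- nrow(re)
    i0 <- sample(seq_len(n - 2), 1)   # consecutive exons i0..i0+1 (< n)
    keep <- re[i0:(i0 + 1), ]
    s <- keep$start
    e <- keep$end
    s[1] <- s[1] + sample(10:40, 1)   # trim terminal exons inward
    e[2] <- e[2] - sample(10:40, 1)
    emit("c", re$chrom[1], re$strand[1], s, e)
  }
  for (k in seq_len(n_req("j"))) {
    re <- pick_ref(3)
    n <- nrow(re)
    # keep junctions up to exon n-2, then one exon bridging the last intron
    s <- c(re$start[seq_len(n - 2)], re$start[n - 1])
    e <- c(re$end[seq_len(n - 2)], re$end[n])
    emit("j", re$chrom[1], re$strand[1], s, e)
  }
  for (k in seq_len(n_req("e"))) {
    re <- pick_ref(2)
    i <- sample(seq_len(nrow(re) - 1), 1)
    emit("e", re$chrom[1], re$strand[1],
         re$end[i] - sample(40:80, 1), re$end[i] + sample(30:60, 1))
  }
  for (k in seq_len(n_req("i"))) {
    re <- pick_ref(2)
    i <- sample(seq_len(nrow(re) - 1), 1)
    mid <- (re$end[i] + re$start[i + 1]) %/% 2
    emit("i", re$chrom[1], re$strand[1], mid - 50L, mid + 50L)
  }
  for (k in seq_len(n_req("o"))) {
    re <- pick_ref(2)
    emit("o", re$chrom[1], re$strand[1],
         re$start[1] - sample(100:200, 1), re$start[1] + sample(30:60, 1))
  }
  for (k in seq_len(n_req("p"))) {
    re <- pick_ref(2)
    span_end <- max(re$end)
    span_start <- min(re$start)
    off <- sample(300:(cfg$run_on_distance - 300), 1)
    if (re$strand[1] == "+") {
      emit("p", re$chrom[1], re$strand[1], span_end + off,
           span_end + off + 200L)
    } else {
      emit("p", re$chrom[1], re$strand[1], span_start - off - 200L,
           span_start - off)
    }
  }
  for (k in seq_len(n_req("x"))) {
    re <- pick_ref(2)
    flip <- if (re$strand[1] == "+") "-" else "+"
    emit("x", re$chrom[1], flip, re$start[1] + 10L, re$end[1] - 10L)
  }
  for (k in seq_len(n_req("s"))) {
    re <- pick_ref(2)
    flip <- if (re$strand[1] == "+") "-" else "+"
    i <- sample(seq_len(nrow(re) - 1), 1)
    mid <- (re$end[i] + re$start[i + 1]) %/% 2
    emit("s", re$chrom[1], flip, mid - 50L, mid + 50L)
  }
  # intergenic transcripts: centered in wide gaps, clear of the run-on zone
  gaps <- annotation$gaps
  margin <- cfg$run_on_distance + 500L
  n_u_multi <- n_req("u")
  n_u <- n_u_multi + cfg$n_single_exon_u
  for (k in seq_len(n_u)) {
    g <- gaps[sample(nrow(gaps), 1), ]
    lo <- g$start + margin
    hi <- g$end - margin
    multi <- k <= n_u_multi
    n_ex <- if (multi) sample(2:4, 1) else 1L
    exon_lens <- sample(200:300, n_ex, replace = TRUE)
    intron_lens <- if (n_ex > 1) sample(200:800, n_ex - 1) else integer(0)
    total <- sum(exon_lens) + sum(intron_lens)
    if (hi - lo <= total) next
    start <- lo + sample(hi - lo - total, 1)
    starts <- start + cumsum(c(0L, head(exon_lens, -1) + intron_lens))
    emit("u", g$chrom, sample(c("+", "-"), 1), starts, starts + exon_lens)
  }
  list(exons = validate_exons(bind_rows(rows)), truth = bind_rows(truth))
}

#' Generate transcript sequences and training sets
#'
#' Every assembled transcript receives a sequence of its spliced length.
#' Multi-exon intergenic (`u`) transcripts are labeled: a configured
#' fraction get a protein-coding regime (an embedded in-frame ORF longer
#' than 100 aa, GC-biased codon composition) and the rest a noncoding
#' regime (background composition, maximal ORF rejection-sampled under
#' the configured cap). Training sets for the coding-potential model are
#' drawn from the same two regimes.
#'
#' @param cfg A `synthetic_config`.
#' @param assembled Output of [generate_assembled()].
#' @return List with `seqs` (tibble `transcript_id`, `sequence`),
#'   `training_coding`, `training_noncoding` (same shape), and `truth`
#'   (tibble `transcript_id`, `true_coding`, NA for unlabeled classes).
#' @export
generate_sequences <- function(cfg, assembled) {
  set.seed(cfg$seed + 2L)
  spans <- transcript_spans(assembled$exons)
  info <- left_join(spans, assembled$truth, by = "transcript_id")
  pool <- coding_codon_pool(cfg$coding_gc_bias)
  draw_coding <- function(total_len) {
    lo <- cfg$coding_orf_range[1]
    hi <- min(cfg$coding_orf_range[2], total_len - 20L)
    orf_nt <- 3L * (sample(lo:max(lo, hi), 1) %/% 3L)
    cds <- r_cds(orf_nt, pool)
    lead_n <- sample.int(max(1L, total_len - orf_nt), 1) - 1L
    lead <- if (lead_n > 0) rmarkov(lead_n, NONCODING_TRANS) else ""
    tail_n <- total_len - orf_nt - lead_n
    trail <- if (tail_n > 0) rmarkov(tail_n, NONCODING_TRANS) else ""
    sq <- paste0(lead, cds, trail)
    # leading context can spawn a longer spurious frame; re-draw if the
    # planted ORF is not dominant
    if (find_max_orf(tibble(transcript_id = "x", sequence = sq))$aa_length >
          100L) sq else draw_coding(total_len)
  }
  truth_rows <- list()
  seqs <- purrr::pmap(
    list(info$transcript_id, info$spliced_length, info$true_class,
         info$multi_exon),
    function(tid, len, cls, multi) {
      label <- NA
      if (identical(cls, "u") && isTRUE(multi)) {
        label <- runif(1) < cfg$u_coding_fraction
      }
      sq <- if (isTRUE(label)) {
        draw_coding(len)
      } else if (identical(label, FALSE)) {
        r_noncoding(len, cfg$noncoding_max_orf_aa)
      } else {
        rmarkov(len, NONCODING_TRANS)
      }
      truth_rows[[length(truth_rows) + 1]] <<-
        tibble(transcript_id = tid, true_coding = label)
      tibble(transcript_id = tid, sequence = sq)
    }
  ) |> bind_rows()
  n_tr <- cfg$training_n
  training_coding <- tibble(
    transcript_id = sprintf("cds_train_%04d", seq_len(n_tr)),
    sequence = vapply(seq_len(n_tr), function(i) {
      nt <- 3L * (sample(cfg$coding_orf_range[1]:cfg$coding_orf_range[2],
                         1) %/% 3L)
      r_cds(nt, pool)
    }, character(1))
  )
  training_noncoding <- tibble(
    transcript_id = sprintf("nc_train_%04d", seq_len(n_tr)),
    sequence = vapply(seq_len(n_tr), function(i) {
      len <- sample(cfg$training_length_range[1]:cfg$training_length_range[2], 1)
      r_noncoding(len, cfg$noncoding_max_orf_aa)
    }, character(1))
  )
  list(seqs = seqs, training_coding = training_coding,
       training_noncoding = training_noncoding,
       truth = bind_rows(truth_rows))
}

#' Generate expression matrices with planted specificity and correlation
#'
#' LincRNAs are assigned expression patterns by the configured mix:
#' single-condition (positive FPKM in exactly one condition), few
#' (two or three conditions), or ubiquitous (near-uniform positive).
#' Genes get ubiquitous profiles; for each planted correlated pair the
#' lincRNA and gene profiles share a latent positive per-condition factor
#' scaled independently, with multiplicative noise of the configured sd.
#'
#' @param cfg A `synthetic_config`.
#' @param linc_ids Character vector of lincRNA ids.
#' @param gene_ids Character vector of gene ids.
#' @param pairs Optional tibble (`lincrna_id`, `gene_id`) of candidate
#'   neighbor pairs from which correlated pairs are drawn.
#' @return List with `linc_expr`, `gene_expr` (expression tibbles over the
#'   same conditions), `truth_specificity` (tibble `transcript_id`,
#'   `true_pattern`, `true_condition`), and `truth_pairs` (tibble
#'   `lincrna_id`, `gene_id`, `correlated`).
#' @export
generate_expression <- function(cfg, linc_ids, gene_ids, pairs = NULL) {
  set.seed(cfg$seed + 3L)
  n_cond <- cfg$n_conditions
  if (n_cond < 2) abort("need at least two conditions")
  conds <- c("oocyte", paste0("tissue_", seq_len(n_cond - 1)))
  n_linc <- length(linc_ids)
  pattern <- sample(names(cfg$specificity_mix), n_linc, replace = TRUE,
                    prob = cfg$specificity_mix)
  lmat <- matrix(0, nrow = n_linc, ncol = n_cond,
                 dimnames = list(linc_ids, conds))
  true_cond <- rep(NA_character_, n_linc)
  for (i in seq_len(n_linc)) {
    base <- stats::rlnorm(1, log(20), 0.5)
    if (pattern[i] == "single") {
      j <- sample.int(n_cond, 1)
      lmat[i, j] <- base
      true_cond[i] <- conds[j]
    } else if (pattern[i] == "few") {
      j <- sample.int(n_cond, sample(2:3, 1))
      lmat[i, j] <- base * stats::rlnorm(length(j), 0, 0.3)
    } else {
      lmat[i, ] <- base * exp(rnorm(n_cond, 0, 0.05))
    }
  }
  gmat <- matrix(stats::rlnorm(length(gene_ids) * n_cond, log(30), 0.4),
                 nrow = length(gene_ids),
                 dimnames = list(gene_ids, conds))
  truth_pairs <- tibble(lincrna_id = character(), gene_id = character(),
                        correlated = logical())
  if (!is.null(pairs) && nrow(pairs) > 0) {
    pairs <- distinct(pairs, .data$lincrna_id, .data$gene_id)
    corr <- runif(nrow(pairs)) < cfg$correlated_fraction
    # one linc profile can only follow one latent factor: keep the first
    # correlated pair per linc and per gene
    corr <- corr & !duplicated(pairs$lincrna_id) & !duplicated(pairs$gene_id)
    for (idx in which(corr)) {
      l <- pairs$lincrna_id[idx]
      g <- pairs$gene_id[idx]
      if (!(l %in% rownames(lmat)) || !(g %in% rownames(gmat))) {
        corr[idx] <- FALSE
        next
      }
      # latent factor dominated by one condition, so correlated lincRNAs
      # remain tissue-specific and survive the JS selection upstream of
      # the neighbor analysis
      dom <- sample.int(n_cond, 1)
      factor_profile <- stats::rlnorm(n_cond, log(1), 0.4)
      factor_profile[dom] <- stats::rlnorm(1, log(60), 0.3)
      noise <- function() exp(rnorm(n_cond, 0, cfg$noise_sd))
      lmat[l, ] <- factor_profile * stats::rlnorm(1, 0, 0.3) * noise()
      gmat[g, ] <- factor_profile * stats::rlnorm(1, 0, 0.3) * noise()
      # the factor profile supersedes the planted specificity pattern
      li <- match(l, linc_ids)
      pattern[li] <- "correlated"
      true_cond[li] <- conds[dom]
    }
    truth_pairs <- mutate(pairs, correlated = corr)
  }
  to_expr <- function(mat) {
    bind_cols(tibble(transcript_id = rownames(mat)),
              as_tibble(as.data.frame(mat)))
  }
  list(
    linc_expr = to_expr(lmat),
    gene_expr = to_expr(gmat),
    truth_specificity = tibble(transcript_id = linc_ids,
                               true_pattern = pattern,
                               true_condition = true_cond),
    truth_pairs = truth_pairs
  )
}

#' Generate a gene-to-GO-term map with one planted enriched term
#'
#' Background terms are assigned to genes independently at the background
#' probability; the planted term (`GO:PLANTED`) is assigned to the given
#' foreground genes at `go_planted_fold` times the background probability
#' (capped at 1) and to other genes at background probability.
#'
#' @param cfg A `synthetic_config`.
#' @param gene_ids All background genes.
#' @param enriched_genes Genes carrying the planted enrichment (e.g. the
#'   correlated-neighbor foreground).
#' @return List with `go_map` (tibble `gene_id`, `term_id`), `go_terms`
#'   (term metadata) and `planted_term`.
#' @export
generate_go <- function(cfg, gene_ids, enriched_genes = character(0)) {
  set.seed(cfg$seed + 4L)
  terms <- sprintf("GO:%07d", seq_len(cfg$n_go_terms))
  cats <- sample(c("BP", "MF", "CC"), cfg$n_go_terms, replace = TRUE)
  rows <- purrr::map(seq_along(terms), function(t) {
    hit <- runif(length(gene_ids)) < cfg$go_background_prob
    if (!any(hit)) return(NULL)
    tibble(gene_id = gene_ids[hit], term_id = terms[t])
  })
  planted <- "GO:PLANTED"
  p_fg <- min(1, cfg$go_planted_fold * cfg$go_background_prob)
  in_fg <- gene_ids %in% enriched_genes
  p_vec <- if_else(in_fg, p_fg, cfg$go_background_prob)
  hit <- runif(length(gene_ids)) < p_vec
  if (any(hit)) {
    rows[[length(rows) + 1]] <- tibble(gene_id = gene_ids[hit],
                                       term_id = planted)
  }
  go_terms <- tibble(term_id = c(terms, planted),
                     category = c(cats, "BP"),
                     name = c(paste0("synthetic term ", seq_along(terms)),
                              "planted enriched term"))
  list(go_map = bind_rows(rows), go_terms = go_terms,
       planted_term = planted)
}

#' Generate a complete synthetic study on disk
#'
#' Runs every generator and writes the files the pipeline consumes:
#' reference and assembled GTFs, transcript and training FASTAs,
#' expression TSVs, GO tables and ground-truth TSVs. Byte-identical across
#' runs with the same config.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return A manifest list of file paths and in-memory ground truth.
#' @export
simulate_study <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  ann <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, ann)
  sq <- generate_sequences(cfg, asm)
  write_gtf(filter(ann$exons, .data$biotype == "protein_coding"),
            p("reference_coding.gtf"))
  write_gtf(filter(ann$exons, .data$biotype == "small_rna"),
            p("reference_smallrna.gtf"))
  write_gtf(asm$exons, p("assembled.gtf"))
  write_fasta(sq$seqs, p("transcripts.fa"))
  write_fasta(sq$training_coding, p("training_coding.fa"))
  write_fasta(sq$training_noncoding, p("training_noncoding.fa"))
  # expression for the planted intergenic lincRNA candidates and all genes
  linc_ids <- asm$truth$transcript_id[asm$truth$true_class == "u" &
                                        asm$truth$multi_exon]
  genes <- gene_spans(filter(ann$exons, .data$biotype == "protein_coding"))
  linc_spans <- filter(transcript_spans(asm$exons),
                       .data$transcript_id %in% linc_ids)
  lincs_bed <- tibble(chrom = linc_spans$chrom, start = linc_spans$start,
                      end = linc_spans$end, name = linc_spans$transcript_id,
                      strand = linc_spans$strand)
  pairs <- find_neighbors(lincs_bed, genes, window = 50000L)
  ex <- generate_expression(cfg, linc_ids, genes$gene_id, pairs)
  go <- generate_go(
    cfg, genes$gene_id,
    enriched_genes = unique(filter(ex$truth_pairs, .data$correlated)$gene_id)
  )
  write_expression_table(ex$linc_expr, p("linc_expression.tsv"))
  write_expression_table(ex$gene_expr, p("gene_expression.tsv"))
  readr::write_tsv(go$go_map, p("go_map.tsv"), progress = FALSE)
  readr::write_tsv(go$go_terms, p("go_terms.tsv"), progress = FALSE)
  readr::write_tsv(asm$truth, p("truth_classes.tsv"), progress = FALSE)
  readr::write_tsv(sq$truth, p("truth_coding.tsv"), progress = FALSE)
  readr::write_tsv(ex$truth_specificity, p("truth_specificity.tsv"),
                   progress = FALSE)
  readr::write_tsv(ex$truth_pairs, p("truth_pairs.tsv"), progress = FALSE)
  list(
    dir = dir,
    files = list(
      reference_coding = p("reference_coding.gtf"),
      reference_smallrna = p("reference_smallrna.gtf"),
      assembled = p("assembled.gtf"),
      transcripts = p("transcripts.fa"),
      training_coding = p("training_coding.fa"),
      training_noncoding = p("training_noncoding.fa"),
      linc_expression = p("linc_expression.tsv"),
      gene_expression = p("gene_expression.tsv"),
      go_map = p("go_map.tsv"),
      go_terms = p("go_terms.tsv")
    ),
    truth = list(classes = asm$truth, coding = sq$truth,
                 specificity = ex$truth_specificity, pairs = ex$truth_pairs,
                 planted_term = go$planted_term)
  )
}
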