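test_that("annotation generation is deterministic and respects invariants", {
  cfg <- small_cfg()
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1$exons, a2$exons)
  # all reference models pass the transcript validators
  expect_silent(validate_exons(a1$exons))
  spans <- transcript_spans(a1$exons)
  expect_true(all(spans$start < spans$end))
  expect_true(all(table(spans$biotype)[c("protein_coding", "small_rna")] ==
                    c(20, 4)))
  # an over-stuffed chromosome is rejected
  tiny <- synthetic_config(seed = 1, n_chroms = 1L, chrom_length = 50000L,
                           n_coding_genes = 30L)
  expect_error(generate_annotation(tiny), "too short")
})

test_that("planted class codes are recovered by the classifier", {
  cfg <- small_cfg()
  ann <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, ann)
  idx <- build_interval_index(ann$exons)
  coded <- classify_transcripts(asm$exons, idx,
                                run_on_distance = cfg$run_on_distance)
  joined <- dplyr::inner_join(coded, asm$truth, by = "transcript_id")
  expect_equal(joined$class_code, joined$true_class)
  # requesting zero of a class emits none
  cfg0 <- small_cfg()
  cfg0$n_assembled[["x"]] <- 0L
  asm0 <- generate_assembled(cfg0, ann)
  expect_false(any(asm0$truth$true_class == "x"))
})

test_that("planted coding labels produce the intended ORF structure", {
  sim <- get_sim()
  seqs <- read_fasta(sim$man$files$transcripts)
  truth <- sim$man$truth$coding
  orfs <- find_max_orf(seqs)
  labeled <- dplyr::inner_join(
    orfs, dplyr::filter(truth, !is.na(true_coding)), by = "transcript_id"
  )
  expect_true(all(labeled$aa_length[labeled$true_coding] > 100))
  expect_true(all(labeled$aa_length[!labeled$true_coding] <=
                    sim$cfg$noncoding_max_orf_aa))
  # sequence lengths equal spliced transcript lengths
  assembled <- read_gtf(sim$man$files$assembled)
  spans <- transcript_spans(assembled)
  m <- dplyr::inner_join(
    spans, dplyr::mutate(seqs, len = nchar(sequence)), by = "transcript_id"
  )
  expect_equal(m$len, m$spliced_length)
})

test_that("planted expression patterns carry their specificity ground truth", {
  cfg <- small_cfg()
  ex <- generate_expression(cfg, paste0("l", 1:40), paste0("g", 1:30))
  scores <- specificity_scores(ex$linc_expr)
  joined <- dplyr::inner_join(scores, ex$truth_specificity,
                              by = "transcript_id")
  single <- dplyr::filter(joined, true_pattern == "single")
  expect_gt(nrow(single), 0)
  expect_true(all(single$js_score == 1))
  expect_equal(single$argmax_condition, single$true_condition)
  ubiq <- dplyr::filter(joined, true_pattern == "ubiquitous")
  expect_true(all(ubiq$js_score < 0.5))
})

test_that("zero-noise correlated pairs have correlation exactly 1", {
  cfg <- small_cfg()
  cfg$noise_sd <- 0
  cfg$correlated_fraction <- 1
  pairs <- tibble::tibble(lincrna_id = paste0("l", 1:10),
                          gene_id = paste0("g", 1:10),
                          distance = 0L)
  ex <- generate_expression(cfg, paste0("l", 1:10), paste0("g", 1:10), pairs)
  links <- correlate_neighbors(pairs, ex$linc_expr, ex$gene_expr,
                               threshold = 0.99)
  truth <- dplyr::filter(ex$truth_pairs, correlated)
  got <- dplyr::semi_join(links, truth,
                          by = c("lincrna_id", "gene_id"))
  expect_true(all(abs(got$pcc - 1) < 1e-12))
})

test_that("GO generation plants the enriched term reproducibly", {
  cfg <- small_cfg()
  genes <- sprintf("g%03d", 1:200)
  fg <- genes[1:25]
  g1 <- generate_go(cfg, genes, fg)
  g2 <- generate_go(cfg, genes, fg)
  expect_identical(g1$go_map, g2$go_map)
  planted_fg <- sum(g1$go_map$term_id == g1$planted_term &
                      g1$go_map$gene_id %in% fg)
  planted_bg <- sum(g1$go_map$term_id == g1$planted_term &
                      !(g1$go_map$gene_id %in% fg))
  # fold-10 planting makes the term far denser in the foreground
  expect_gt(planted_fg / length(fg),
            3 * planted_bg / (length(genes) - length(fg)))
})
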