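test_that("neighbor search respects the inclusive window boundary", {
  lincs <- tibble::tibble(chrom = "chr1", start = 100000L, end = 101000L,
                          name = "linc1")
  genes <- tibble::tibble(
    gene_id = c("near", "edge", "beyond", "inside", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(111000L, 151000L, 151001L, 100500L, 111000L),
    end = c(112000L, 152000L, 152001L, 100800L, 112000L)
  )
  nb <- find_neighbors(lincs, genes, window = 50000L)
  expect_setequal(nb$gene_id, c("near", "edge", "inside"))
  expect_equal(nb$distance[nb$gene_id == "near"], 10000L)
  expect_equal(nb$distance[nb$gene_id == "edge"], 50000L)
  expect_equal(nb$distance[nb$gene_id == "inside"], 0L)
})

test_that("neighbor search matches a brute-force window scan", {
  set.seed(41)
  lincs <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 60, TRUE),
    start = sample(1e6, 60)
  ) |>
    dplyr::mutate(end = start + sample(500:3000, 60, TRUE),
                  name = sprintf("linc%02d", 1:60))
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:150),
    chrom = sample(c("chr1", "chr2"), 150, TRUE),
    start = sample(1e6, 150)
  ) |>
    dplyr::mutate(end = start + sample(1000:20000, 150, TRUE))
  w <- 50000L
  nb <- find_neighbors(lincs, genes, window = w)
  brute <- list()
  for (i in seq_len(nrow(lincs))) {
    for (j in seq_len(nrow(genes))) {
      if (lincs$chrom[i] != genes$chrom[j]) next
      d <- max(0, max(genes$start[j] - lincs$end[i],
                      lincs$start[i] - genes$end[j]))
      if (d <= w) {
        brute[[length(brute) + 1]] <-
          paste(lincs$name[i], genes$gene_id[j], d)
      }
    }
  }
  expect_setequal(paste(nb$lincrna_id, nb$gene_id, nb$distance),
                  unlist(brute))
})

test_that("correlation links flag strong pairs and drop zero-variance profiles", {
  conds <- paste0("t", 1:6)
  linc_expr <- tibble::tibble(transcript_id = c("l1", "l2"))
  linc_expr[conds] <- as.list(as.data.frame(rbind(c(1, 2, 3, 4, 5, 6),
                                                  c(2, 2, 9, 1, 4, 3))))
  gene_expr <- tibble::tibble(transcript_id = c("g1", "g2"))
  gene_expr[conds] <- as.list(as.data.frame(rbind(2 * c(1, 2, 3, 4, 5, 6),
                                                  rep(5, 6))))
  pairs <- tibble::tibble(lincrna_id = c("l1", "l2"),
                          gene_id = c("g1", "g2"),
                          distance = c(0L, 100L))
  links <- suppressMessages(
    correlate_neighbors(pairs, linc_expr, gene_expr, threshold = 0.9)
  )
  expect_equal(nrow(links), 1)          # constant profile dropped
  expect_equal(links$pcc, 1)            # exact linear relation
  expect_true(links$strong)
  # mismatched condition sets are an error
  bad <- gene_expr
  names(bad)[2] <- "other"
  expect_error(correlate_neighbors(pairs, linc_expr, bad), "conditions")
})

test_that("hypergeometric enrichment matches direct tail summation", {
  # background of 50 genes; term on 5; foreground of 10 catching 4
  background <- sprintf("g%02d", 1:50)
  with_term <- background[1:5]
  foreground <- c(background[1:4], background[40:45])
  go_map <- tibble::tibble(gene_id = with_term, term_id = "T1")
  res <- go_enrichment(foreground, background, go_map)
  expect_equal(res$k, 4L)
  expect_equal(res$p_value, oracle_hyper_tail(4, 5, 10, 50))
  expect_equal(res$p_value, 0.00408352054976, tolerance = 1e-9)

  # a term carried by every background gene is never enriched
  all_map <- tibble::tibble(gene_id = background, term_id = "T2")
  expect_equal(go_enrichment(foreground, background, all_map)$p_value, 1)

  # exact enumeration branch on a tiny universe: k = K = n
  bg <- letters[1:10]
  fg <- letters[1:3]
  tiny <- tibble::tibble(gene_id = fg, term_id = "T3")
  p <- go_enrichment(fg, bg, tiny)$p_value
  expect_equal(p, 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(p, oracle_hyper_tail(3, 3, 3, 10), tolerance = 1e-12)
})

test_that("enrichment p-values are monotone in k and BH keeps the p order", {
  ps <- vapply(1:5, function(k) oracle_hyper_tail(k, 8, 10, 100), numeric(1))
  expect_true(all(diff(ps) < 0))
  set.seed(42)
  background <- sprintf("g%03d", 1:100)
  go_map <- tibble::tibble(
    gene_id = sample(background, 300, replace = TRUE),
    term_id = sample(paste0("T", 1:20), 300, replace = TRUE)
  )
  res <- go_enrichment(sample(background, 20), background, go_map)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(all(res$adjusted_p <= 1))
  ord <- order(res$p_value)
  expect_true(all(diff(res$adjusted_p[ord]) >= -1e-15))
  expect_error(go_enrichment(character(0), background, go_map), "empty")
  expect_error(go_enrichment("not_in_background", background, go_map),
               "subset")
})
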