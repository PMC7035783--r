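# Small hand-built annotation: one multi-exon gene on + and one on -.
toy_refs <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(1000L, 2000L, 3000L, 10000L, 12000L),
    end = c(1500L, 2500L, 3500L, 10500L, 12500L),
    strand = c("+", "+", "+", "-", "-"),
    transcript_id = c("refA", "refA", "refA", "refB", "refB"),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    biotype = "protein_coding"
  )
}

tx <- function(id, starts, ends, strand = "+", chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), strand = strand,
                 transcript_id = id, gene_id = id,
                 biotype = "assembled_unknown")
}

test_that("interval index overlap queries match a linear scan", {
  set.seed(101)
  refs <- dplyr::bind_rows(lapply(seq_len(200), function(i) {
    s <- sample(1e6, 1)
    tx(sprintf("r%03d", i), s, s + sample(100:5000, 1),
       chrom = sample(c("chr1", "chr2"), 1))
  }))
  refs$biotype <- "protein_coding"
  idx <- build_interval_index(refs)
  spans <- transcript_spans(refs)
  for (q in seq_len(50)) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1)
    s <- sample(1e6, 1)
    e <- s + sample(10:10000, 1)
    hits <- sort(query_index(idx, chrom, s, e)$transcript_id)
    brute <- spans$transcript_id[spans$chrom == chrom &
                                   spans$start < e & spans$end > s]
    expect_equal(hits, sort(brute))
  }
})

test_that("class codes follow the transfrag semantics on hand-built cases", {
  idx <- build_interval_index(toy_refs())
  code_of <- function(t) assign_class_code(t, idx)$class_code

  # identical intron chain -> "="
  expect_equal(code_of(tx("q", c(900, 2000, 3000), c(1500, 2500, 3600))), "=")
  # contained sub-structure with fewer exons -> "c"
  expect_equal(code_of(tx("q", c(1100, 2000), c(1500, 2400))), "c")
  # shared junction but different chain -> "j"
  expect_equal(code_of(tx("q", c(900, 2000), c(1500, 3500))), "j")
  # single exon crossing an exon/intron boundary by >= 10 bp -> "e"
  expect_equal(code_of(tx("q", 1400, 1600)), "e")
  # entirely inside an intron, same strand -> "i"
  expect_equal(code_of(tx("q", 1600, 1900)), "i")
  # other exonic overlap -> "o"
  expect_equal(code_of(tx("q", 800, 1100)), "o")
  # within run-on distance downstream of the 3' end, same strand -> "p"
  expect_equal(code_of(tx("q", 4000, 4200)), "p")
  # far from everything -> "u" with empty best_reference
  res <- assign_class_code(tx("q", 50000, 50300), idx)
  expect_equal(res$class_code, "u")
  expect_equal(res$best_reference, "")
  # exonic overlap on the opposite strand only -> "x"
  expect_equal(code_of(tx("q", 10100, 10400, strand = "+")), "x")
  # inside an intron on the opposite strand -> "s"
  expect_equal(code_of(tx("q", 11000, 11200, strand = "+")), "s")
})

test_that("strand-unknown transcripts are never '=' or 'j'", {
  idx <- build_interval_index(toy_refs())
  same_chain <- tx("q", c(1000, 2000, 3000), c(1500, 2500, 3500),
                   strand = "*")
  code <- assign_class_code(same_chain, idx)$class_code
  expect_false(code %in% c("=", "j"))
  expect_true(code %in% c("c", "e", "o"))
  # the drop policy removes unstranded transcripts from the output
  dropped <- classify_transcripts(same_chain, idx, strand_unknown = "drop")
  expect_equal(nrow(dropped), 0)
})

test_that("classification partitions transcripts and matches planted truth", {
  sim <- get_sim()
  refs <- dplyr::bind_rows(
    read_gtf(sim$man$files$reference_coding, biotype = "protein_coding"),
    read_gtf(sim$man$files$reference_smallrna, biotype = "small_rna")
  )
  idx <- build_interval_index(refs)
  assembled <- read_gtf(sim$man$files$assembled)
  coded <- classify_transcripts(assembled, idx)
  # partition: one code per transcript, counts sum to N
  expect_equal(nrow(coded), dplyr::n_distinct(assembled$transcript_id))
  expect_equal(sum(summarize_classes(coded)$n), nrow(coded))
  # planted codes recovered
  joined <- dplyr::inner_join(coded, sim$man$truth$classes,
                              by = "transcript_id")
  expect_equal(joined$class_code, joined$true_class)
  # "u" transcripts have no exonic overlap with any reference (brute force)
  spans <- transcript_spans(assembled)
  u_ids <- coded$transcript_id[coded$class_code == "u"]
  u_exons <- dplyr::filter(assembled, transcript_id %in% u_ids)
  for (i in seq_len(nrow(u_exons))) {
    ov <- sum(pmax(0, pmin(u_exons$end[i], refs$end) -
                     pmax(u_exons$start[i], refs$start)) *
                (refs$chrom == u_exons$chrom[i]))
    expect_equal(ov, 0)
  }
})

test_that("candidate selection keeps exactly multi-exon 'u' transcripts", {
  coded <- tibble::tibble(
    transcript_id = c("a", "b", "c", "d"),
    class_code = c("u", "u", "j", "u"),
    best_reference = c("", "", "r", ""),
    n_exons = c(1L, 3L, 2L, 2L)
  )
  sel <- select_candidates(coded)
  expect_equal(sel$transcript_id, c("b", "d"))
  expect_equal(nrow(select_candidates(coded[0, ])), 0)

  # brute-force filter oracle on random codes
  set.seed(7)
  rnd <- tibble::tibble(
    transcript_id = sprintf("t%03d", 1:100),
    class_code = sample(c("=", "c", "j", "u", "x"), 100, replace = TRUE),
    best_reference = "",
    n_exons = sample(1:5, 100, replace = TRUE)
  )
  got <- select_candidates(rnd)$transcript_id
  want <- rnd$transcript_id[rnd$class_code == "u" & rnd$n_exons >= 2]
  expect_equal(got, want)
})

test_that("class summaries tally all ten codes with zero fill", {
  coded <- tibble::tibble(transcript_id = c("a", "b", "c"),
                          class_code = c("u", "u", "j"),
                          best_reference = "", n_exons = 2L)
  tab <- summarize_classes(coded)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$n[tab$class_code == "u"], 2L)
  expect_equal(tab$n[tab$class_code == "j"], 1L)
  expect_equal(sum(tab$n), 3L)
  expect_true(all(summarize_classes(coded[0, ])$n == 0))
})
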