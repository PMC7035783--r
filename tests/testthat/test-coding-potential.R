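seq_tbl <- function(...) {
  s <- c(...)
  tibble::tibble(transcript_id = paste0("s", seq_along(s)), sequence = s)
}

test_that("maximal ORF detection handles starts, stops and N codons", {
  res <- find_max_orf(seq_tbl("ATGAAATAA", "CCCCCC", "ATGNNNTAA", "AT"))
  expect_equal(res$nt_length, c(9L, 0L, 9L, 0L))
  expect_equal(res$aa_length, c(2L, 0L, 2L, 0L))
  expect_equal(res$orf_seq[1], "ATGAAATAA")
  # ORF without a stop runs to the last complete codon
  open <- find_max_orf(seq_tbl("ATGAAAAAAA"))
  expect_equal(open$nt_length, 9L)
  expect_equal(open$aa_length, 3L)
  expect_false(open$has_stop)
  # requiring a stop discards open-ended ORFs but keeps terminated ones
  strict <- find_max_orf(seq_tbl("ATGAAAAAAA", "ATGAAATAA"),
                         require_stop = TRUE)
  expect_equal(strict$nt_length, c(0L, 9L))
})

test_that("maximal ORF agrees with brute-force enumeration on random sequences", {
  set.seed(11)
  seqs <- vapply(seq_len(120), function(i) {
    random_dna(sample(3:600, 1), alphabet = c("A", "C", "G", "T", "N"))
  }, character(1))
  got <- find_max_orf(tibble::tibble(transcript_id = as.character(1:120),
                                     sequence = seqs))
  for (i in seq_len(120)) {
    want <- oracle_max_orf(seqs[i])
    expect_equal(got$nt_length[i], want$nt_length)
    expect_equal(got$aa_length[i], want$aa_length)
  }
})

test_that("three-frame translation renders stops as * and N codons as X", {
  pep <- translate_three_frames(seq_tbl("ATGAAA"))
  expect_equal(pep$peptide[pep$frame == 0], "MK")
  expect_equal(translate_three_frames(seq_tbl("ATGTAA"))$peptide[1], "M*")
  p2 <- translate_three_frames(seq_tbl("AATGAAA"))
  expect_equal(p2$peptide[p2$frame == 1], "MK")
  pn <- translate_three_frames(seq_tbl("ATGNNNAAA"))
  expect_equal(pn$peptide[pn$frame == 0], "MXK")
})

test_that("Fickett statistic matches an independent table lookup", {
  set.seed(12)
  seqs <- c(
    strrep("ACGT", 30),
    vapply(seq_len(50), function(i) random_dna(sample(30:400, 1)),
           character(1))
  )
  got <- fickett_score(tibble::tibble(transcript_id = as.character(seq_along(seqs)),
                                      sequence = seqs))
  want <- vapply(seqs, oracle_fickett, numeric(1), USE.NAMES = FALSE)
  expect_equal(round(got$fickett_score, 4), round(want, 4))
})

test_that("hexamer tables are normalized and symmetric inputs cancel", {
  seqs <- c("ATGGCCAAAGGG", "ATGCCCGGGTTT", "ATGAAACCCGGG")
  tab <- train_hexamer_table(seqs, seqs)
  expect_equal(sum(tab$f_coding), 1, tolerance = 1e-12)
  expect_equal(sum(tab$f_noncoding), 1, tolerance = 1e-12)
  # identical regimes give identical in-frame tallies only for step-3 vs
  # step-1 counting over the same hexamers; a fully symmetric check uses
  # one sequence whose sliding and in-frame hexamer sets coincide
  one <- "ATGGCCAAA"  # 9 nt: in-frame hexamers {0,3}, sliding {0..3}
  tab1 <- train_hexamer_table(one, one)
  expect_equal(sum(tab1$f_coding), 1, tolerance = 1e-12)
  # hand tally: coding step-3 hexamers of "ATGGCCAAA" are ATGGCC, GCCAAA
  expect_equal(tab1$f_coding[tab1$hexamer == "ATGGCC"], 2 / 4098)
  expect_equal(tab1$f_coding[tab1$hexamer == "GCCAAA"], 2 / 4098)
  expect_equal(tab1$f_coding[tab1$hexamer == "AAAAAA"], 1 / 4098)
})

test_that("hexamer score is a mean log ratio, zero on neutral tables", {
  neutral <- train_hexamer_table("ATGGCCAAA", "ATGGCCAAA")
  neutral$f_noncoding <- neutral$f_coding
  expect_equal(hexamer_score(c("ATGGCCAAATTTGGG"), neutral)$hexamer_score, 0)

  tab <- train_hexamer_table(c("ATGGCCAAAGGGTTT"), c("TTTTTTAAAAAA"))
  single <- hexamer_score("ATGGCC", tab)$hexamer_score
  lr <- log(tab$f_coding[tab$hexamer == "ATGGCC"] /
              tab$f_noncoding[tab$hexamer == "ATGGCC"])
  expect_equal(single, lr)
  # antisymmetry under swapping the table roles
  swapped <- tab
  swapped$f_coding <- tab$f_noncoding
  swapped$f_noncoding <- tab$f_coding
  set.seed(13)
  orfs <- vapply(1:20, function(i) random_dna(3 * sample(2:40, 1)),
                 character(1))
  s1 <- hexamer_score(orfs, tab)$hexamer_score
  s2 <- hexamer_score(orfs, swapped)$hexamer_score
  expect_equal(s1, -s2)
  # direct summation oracle
  for (sq in orfs[1:5]) {
    m <- (nchar(sq) - 6) %/% 3 + 1
    hx <- substring(sq, 3 * (seq_len(m) - 1) + 1, 3 * (seq_len(m) - 1) + 6)
    want <- mean(log(tab$f_coding[match(hx, tab$hexamer)] /
                       tab$f_noncoding[match(hx, tab$hexamer)]))
    expect_equal(hexamer_score(sq, tab)$hexamer_score, want)
  }
})

test_that("perfectly separable training data yields held-out accuracy 1", {
  set.seed(14)
  pool <- c("GCT", "GGA", "TGC", "CGA", "GAC", "GGC")
  coding <- vapply(seq_len(60), function(i) {
    paste0("ATG", paste(sample(pool, 120, replace = TRUE), collapse = ""),
           "TAA")
  }, character(1))
  noncoding <- vapply(seq_len(60), function(i) {
    random_dna(sample(200:400, 1), alphabet = c("C", "G", "T"))  # no ATG
  }, character(1))
  model <- fit_coding_model(
    tibble::tibble(transcript_id = paste0("c", 1:60), sequence = coding),
    tibble::tibble(transcript_id = paste0("n", 1:60), sequence = noncoding)
  )
  perf <- glance(model)
  expect_equal(perf$accuracy, 1)
  expect_gt(model$cutoff, 0)
  expect_lt(model$cutoff, 1)
  # ORF length coefficient is positive, so probability rises with ORF length
  est <- tidy(model)
  expect_gt(est$estimate[est$term == "orf_nt_length"], 0)
  feats <- tibble::tibble(orf_nt_length = seq(0, 600, by = 60),
                          orf_coverage = 0.5, fickett_score = 0.8,
                          hexamer_score = 0)
  probs <- lincfinder:::logistic_prob(feats, model$coefficients)
  expect_true(all(diff(probs) >= 0))
})

test_that("single-class training input is rejected", {
  seqs <- tibble::tibble(transcript_id = paste0("x", 1:60),
                         sequence = rep("ATGAAATAA", 60))
  expect_error(fit_coding_model(seqs, seqs[0, ]), "at least 50")
})

test_that("noncoding filter rules apply the documented boundaries", {
  # hand-built model: cutoff 0.348, only the intercept active
  tab <- train_hexamer_table("ATGGCCAAA", "ATGGCCAAA")
  model <- structure(
    list(coefficients = c("(Intercept)" = -2, orf_nt_length = 0,
                          orf_coverage = 0, fickett_score = 0,
                          hexamer_score = 0),
         cutoff = 0.348, hexamer_table = tab,
         heldout = tibble::tibble(sensitivity = 1, specificity = 1,
                                  accuracy = 1, n_heldout = 0),
         n_coding = 0, n_noncoding = 0),
    class = "coding_model"
  )
  short_nc <- paste0("ATG", strrep("GCA", 80), "TAA")   # 80 aa ORF
  long_orf <- paste0("ATG", strrep("GCA", 101), "TAA")  # 101 aa ORF
  seqs <- tibble::tibble(transcript_id = c("ok", "longorf"),
                         sequence = c(short_nc, long_orf))
  res <- apply_noncoding_filters(
    seqs, model,
    conservation = tibble::tibble(transcript_id = c("ok", "longorf"),
                                  score = c(-5, -5))
  )
  expect_true(res$is_noncoding[res$transcript_id == "ok"])
  # maximal ORF > 100 aa alone defeats the call
  row <- res[res$transcript_id == "longorf", ]
  expect_false(row$passes_maxorf)
  expect_false(row$is_noncoding)
  expect_true(row$passes_cpat && row$passes_conservation && row$passes_domain)

  # a conservation score of exactly zero is not negative: fails
  res0 <- apply_noncoding_filters(
    seqs[1, ], model,
    conservation = tibble::tibble(transcript_id = "ok", score = 0)
  )
  expect_false(res0$passes_conservation)
  expect_false(res0$is_noncoding)

  # a recorded domain hit excludes the transcript
  resd <- apply_noncoding_filters(
    seqs[1, ], model,
    domains = tibble::tibble(transcript_id = "ok",
                             domain_accession = "PF00001", e_value = 1e-6)
  )
  expect_false(resd$passes_domain)
  # absent optional tables pass vacuously
  resv <- apply_noncoding_filters(seqs[1, ], model)
  expect_true(resv$passes_conservation & resv$passes_domain)
  expect_true(resv$is_noncoding)
})

test_that("a serialized model round-trips through JSON", {
  sim <- get_sim()
  run <- get_identified()
  model <- run$run$model
  path <- withr::local_tempfile(fileext = ".json")
  write_coding_model(model, path)
  back <- read_coding_model(path)
  expect_equal(back$cutoff, model$cutoff)
  expect_equal(back$coefficients, model$coefficients)
  seqs <- head(read_fasta(sim$man$files$transcripts), 10)
  expect_equal(predict_coding(seqs, back)$coding_prob,
               predict_coding(seqs, model)$coding_prob)
})
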