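# Shared synthetic fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Full desk-scale synthetic study (annotation, assembled transcripts,
# sequences, expression, GO), written to a session temp dir.
get_sim <- function() {
  if (is.null(.fixture_cache$man)) {
    cfg <- synthetic_config(seed = 42L)
    .fixture_cache$cfg <- cfg
    .fixture_cache$man <- simulate_study(
      cfg, file.path(tempdir(), "lincfinder_sim_fixture")
    )
  }
  list(cfg = .fixture_cache$cfg, man = .fixture_cache$man)
}

sim_run_config <- function(man, out_dir, seed = 11L, ...) {
  run_config(
    reference_gtfs = list(protein_coding = man$files$reference_coding,
                          small_rna = man$files$reference_smallrna),
    assembled_gtf = man$files$assembled,
    transcripts_fasta = man$files$transcripts,
    training_coding_fasta = man$files$training_coding,
    training_noncoding_fasta = man$files$training_noncoding,
    linc_expression_tsv = man$files$linc_expression,
    gene_expression_tsv = man$files$gene_expression,
    go_map_tsv = man$files$go_map,
    go_terms_tsv = man$files$go_terms,
    out_dir = out_dir, seed = seed, ...
  )
}

# Identification run over the shared study.
get_identified <- function() {
  if (is.null(.fixture_cache$identified)) {
    sim <- get_sim()
    conf <- sim_run_config(sim$man,
                           file.path(tempdir(), "lincfinder_run_fixture"))
    .fixture_cache$conf <- conf
    .fixture_cache$identified <- run_identify(conf)
  }
  list(conf = .fixture_cache$conf, run = .fixture_cache$identified,
       sim = get_sim())
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A reduced configuration keeps generator-level tests quick.
small_cfg <- function(seed = 5L) {
  synthetic_config(
    seed = seed,
    n_coding_genes = 20L, n_small_rnas = 4L,
    n_assembled = c("=" = 3L, "c" = 3L, "j" = 3L, "e" = 3L, "i" = 3L,
                    "o" = 3L, "p" = 3L, "u" = 10L, "x" = 3L, "s" = 3L),
    n_single_exon_u = 3L,
    training_n = 60L
  )
}
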