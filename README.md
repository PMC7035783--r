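# lincfinder

`lincfinder` identifies and characterizes long intergenic non-coding RNAs
(lincRNAs) from an assembled transcriptome. It is aimed at transcriptomics
researchers who have assembled transcript models (e.g. from Cufflinks or
Scripture output) for a tissue of interest — such as oocytes — and want a
tested, reproducible implementation of the standard lincRNA discovery
cascade and its downstream characterization, without re-running a zoo of
external tools.

## What it computes

**Identification.** Each assembled transcript is compared to the reference
annotation (protein-coding genes plus small RNAs) and given a
Cuffcompare-style class code (`=`, `c`, `j`, `e`, `i`, `o`, `p`, `u`, `x`,
`s`). Multi-exon intergenic transcripts (class `u`) become lincRNA
candidates and pass through four non-coding filters:

1. **Coding-potential model.** An alignment-free logistic model over four
   features — maximal-ORF length *L*, ORF coverage *L/len(t)*, the Fickett
   TESTCODE statistic, and the hexamer usage bias
   *mean<sub>h∈ORF</sub> log(F<sub>coding</sub>(h)/F<sub>noncoding</sub>(h))* —
   trained on labeled CDS/noncoding sequence sets; the probability cutoff is
   chosen on held-out data by the two-graph ROC rule (maximal sensitivity +
   specificity). A transcript passes when P(coding) falls below the cutoff.
2. **Conservation rule.** When a table of precomputed conservation coding
   scores (PhyloCSF-style) is supplied, only transcripts with a *negative*
   score are retained.
3. **Domain rule.** When a protein-domain hit table (Pfam/HMMER-style) is
   supplied, any hit excludes the transcript. Three-frame peptide FASTA
   export is provided for running the external scan.
4. **Maximal-ORF rule.** Transcripts whose maximal ORF exceeds 100 amino
   acids are excluded.

**Characterization.** For the retained lincRNAs the package computes the
entropy-based Jensen–Shannon tissue-specificity score

> JS(t) = max over tissues s of 1 − sqrt( JSD(p<sub>t</sub>, e<sub>s</sub>) )

where p<sub>t</sub> is the transcript's normalized FPKM pattern,
e<sub>s</sub> the extremal single-tissue pattern and JSD the Jensen–Shannon
divergence (log base 2); JS = 1 means expression in exactly one tissue, and
scores above 0.5 are called tissue-specific. It also compares the catalogue
to external lncRNA sets by genomic-locus overlap (Venn-style region
counts), finds protein-coding genes within ±50 kb of each specific lincRNA,
correlates lincRNA–neighbor expression (Pearson), and tests GO-term
enrichment of strongly correlated neighbors with the hypergeometric upper
tail and Benjamini–Hochberg adjustment per category.

A seeded synthetic-data generator (`simulate_study()`) emulates every
input — toy annotation, assembled transcripts with known class codes,
sequences with planted coding structure, FPKM matrices with planted
specificity and correlation, GO maps with a planted enriched term — so the
whole pipeline is exercised end-to-end with ground truth.

## Worked example

```r
library(lincfinder)

cfg  <- synthetic_config(seed = 42)
man  <- simulate_study(cfg, "sim")          # writes GTF/FASTA/TSV inputs
conf <- run_config(
  reference_gtfs = list(protein_coding = man$files$reference_coding,
                        small_rna      = man$files$reference_smallrna),
  assembled_gtf            = man$files$assembled,
  transcripts_fasta        = man$files$transcripts,
  training_coding_fasta    = man$files$training_coding,
  training_noncoding_fasta = man$files$training_noncoding,
  linc_expression_tsv      = man$files$linc_expression,
  gene_expression_tsv      = man$files$gene_expression,
  go_map_tsv               = man$files$go_map,
  go_terms_tsv             = man$files$go_terms,
  out_dir = "run", seed = 1)

(run <- run_identify(conf))
#> <linc_run> 230 assembled -> 40 multi-exon intergenic candidates -> 28 lincRNAs ( 28 loci )

summarize_lincrnas(read_gtf(run$files$lincrna_gtf))
#> # A tibble: 1 × 5
#>   n_transcripts mean_length sd_length mean_exons sd_exons
#> 1            28        710.      178.       2.86    0.803

ch <- run_characterize(conf, run)
ch$specificity_summary
#> # A tibble: 1 × 4
#>   n_scored n_specific frac_specific frac_js1
#> 1       28         22         0.786    0.464

head(ch$enrichment[c("term_id", "category", "k", "K", "p_value", "adjusted_p")], 1)
#> # A tibble: 1 × 6
#>   term_id    category     k     K p_value adjusted_p
#> 1 GO:PLANTED BP           5     6 0.00104    0.00624
```

Reading the numbers: of 230 assembled transcripts, 40 are multi-exon
intergenic candidates and 28 survive the coding filters (one locus each
here, since the planted lincRNAs do not overlap). Their mean spliced length
is 710 ± 178 nt with 2.9 ± 0.8 exons. 79% are tissue-specific at the JS
> 0.5 cutoff and 46% have JS = 1 (expressed in a single condition); the
planted GO term tops the enrichment of strongly correlated neighbor genes
(BH-adjusted p = 0.006). All of this matches the generator's ground truth,
which is the point of the synthetic closed loop.

Each result table has a plotting companion (`plot_class_summary()`,
`plot_specificity()`, `plot_chromosome_counts()`, `plot_enrichment()`,
`autoplot()` on the fitted model), and the fitted coding model supports
`tidy()`/`glance()`. A thin command-line wrapper lives at
`inst/scripts/linc-pipeline.R`.

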