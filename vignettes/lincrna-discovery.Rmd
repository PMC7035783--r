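---
title: "Identifying lincRNAs from assembled transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lincRNAs from assembled transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincfinder)
```

# The problem

Long intergenic non-coding RNAs (lincRNAs) are transcripts longer than
roughly 200 nt that come from regions between annotated genes and show no
evidence of protein-coding capacity. Discovering them from RNA-Seq is a
filtering problem: transcript assembly produces tens of thousands of
transcript fragments, most of which are fragments or isoforms of known
genes, and the few genuinely novel intergenic ones must then be separated
into coding and non-coding. `lincfinder` implements this cascade — class
coding against a reference, candidate selection, coding-potential
assessment — followed by the standard downstream characterization: tissue
specificity, catalogue comparison, and cis-neighbor prediction.

The package deliberately consumes the *outputs* of upstream tools
(assembled GTFs, FPKM tables, conservation scores, domain-hit tables)
rather than wrapping the tools themselves. What it owns is the decision
logic: the class-code semantics, the coding-potential model, the
specificity metric, and the enrichment statistics.

# Class codes

Every assembled transcript is compared against each reference transcript
whose span lies within the run-on distance and receives a per-reference
relation, then the most specific one overall:

| code | meaning |
|------|---------|
| `=`  | identical intron chain (exonic overlap for single-exon pairs) |
| `c`  | exons contained in reference exons, introns a subset, fewer exons |
| `j`  | shares at least one exact splice junction, chains differ |
| `e`  | single exon overlapping a reference exon and ≥ 10 bp of intron |
| `i`  | entirely within a reference intron, same strand |
| `o`  | any other same-strand exonic overlap |
| `p`  | within the run-on distance downstream of a same-strand 3′ end |
| `x`  | exonic overlap on the opposite strand only |
| `s`  | within a reference intron on the opposite strand |
| `u`  | none of the above: unknown, intergenic |

Three points are design choices rather than forced by the definitions, and
we document them as such:

* **Precedence.** When several references yield different codes the order
  `=`, `c`, `j`, `e`, `o`, `i`, `x`, `s`, `p`, `u` wins (most specific
  first). Ties are broken by largest exonic overlap in bp, then smallest
  reference id, making classification fully deterministic.
* **Run-on distance.** The `p` code uses 2,000 bp downstream of a
  same-strand reference 3′ end by default (`run_on_distance`), the
  conventional value for polymerase run-on fragments; it is configurable.
* **Strand-unknown transcripts.** Assembled transcripts with no strand are
  compared against both strands but are never eligible for `=` or `j`,
  which require junction identity on a known strand. They are kept rather
  than dropped because single-sample assemblies commonly leave some
  transcripts unstranded.

Candidates for lincRNA status are exactly the class-`u` transcripts with
at least two exons. Single-exon intergenic transcripts are excluded
because they are the class most contaminated by assembly artifacts and
DNA contamination.

# Coding potential

The logistic model uses four alignment-free features, computed on the
forward strand only (three frames; assembled transcripts are already
oriented):

* **Maximal ORF length** (nt). The longest ATG-initiated run ending at the
  first in-frame stop; an ORF with no downstream stop runs to the last
  complete codon, accommodating truncated assemblies (a stop can be
  required via the `has_stop` column if desired). The nt length includes
  the stop codon; the amino-acid length excludes it, and the 100-aa filter
  is applied to the amino-acid length. Codons containing N never match a
  start or stop.
* **ORF coverage**: maximal ORF length over transcript length, in [0, 1].
* **Fickett TESTCODE**: the published weighted sum of eight table-converted
  parameters (per-base codon-position asymmetry and base content). The
  lookup tables are constants of the statistic and are hard-coded; N bases
  are excluded from counts.
* **Hexamer usage bias**: the mean natural-log ratio of in-frame hexamer
  frequencies between the coding and noncoding training regimes, with
  add-one pseudocounts over all 4,096 hexamers (so the score is 0 when the
  regimes coincide and negates when they are swapped). In-frame hexamers
  are counted with step 3 from the annotated CDS frame for the coding
  table and with step 1 (sliding) for the noncoding table. The noncoding
  training set pools the ncRNA-like and intron-like sequences, the common
  practice when both are available.

The model is a binomial GLM (coding = 1). A held-out fraction (default
25%, stratified by class) supplies the probability cutoff: the value
maximizing sensitivity plus specificity, i.e. the crossing point of the
two-graph ROC. A fixed external cutoff (for example 0.348, appropriate for
a model trained on bovine RefSeq CDS, Ensembl ncRNAs and RefSeq introns)
can be supplied through `run_config(cpat_cutoff = )` instead; synthetic
runs derive their own cutoff because a fixed constant is only meaningful
for the training sets it came from.

Conservation scores and domain hits enter as optional tables. Their
decision rules are strict: a conservation score of exactly 0 is *not*
negative and fails; any recorded domain hit (regardless of e-value, and
with PfamA/PfamB treated alike) excludes the transcript. When a table is
absent the corresponding filter passes vacuously and the run report lists
the stage as skipped. The final non-coding call is the conjunction of the
four flags, which makes the cascade order-independent — a property the
test suite checks explicitly.

# Tissue specificity

The expression pattern of transcript *t* across *n* conditions is
normalized to a probability vector p. The specificity score is

$$\mathrm{JS}(t) \;=\; \max_{s} \Big( 1 - \sqrt{\mathrm{JSD}(p,\, e_s)} \Big)$$

with JSD the Jensen–Shannon divergence in bits (base-2 logs,
0·log 0 = 0) and e_s the unit vector of condition *s*. This is the
entropy-based specificity metric of the lncRNA literature: it is 1 exactly
when expression is confined to one condition, strictly below 1 otherwise,
invariant to rescaling, and minimized by the uniform pattern. The score is
maximized over all conditions — the focal (oocyte-like) condition is one
column among the others — and "focal-specific" means the argmax condition
is the focal one with a score above the cutoff.

Choices worth stating:

* A score of exactly 0.5 is **non-specific** (the call is strictly
  greater-than).
* All-zero expression vectors are flagged unscorable and excluded
  downstream, with their count reported, rather than scored arbitrarily.
* No expression floor is applied by default, but `min_fpkm` exists because
  a vector like (0.001, 0, …, 0) scores a spurious 1; with a floor such
  rows become unscorable instead.

# Catalogue comparison and cis-neighbors

Catalogue overlap is strand-blind at the transcript-span level with a
1 bp minimum overlap, both configurable. External catalogues (BED-derived)
vary in strand reliability, which is why strand is ignored by default; the
span (not exon) level matches the usual "genomic position" comparisons.
Membership across several catalogues yields Venn-style region counts that
partition the primary set.

Neighbor search takes the lincRNAs already selected as specific
(JS > 0.5), extends each span by the window (default 50 kb, inclusive at
the boundary) on both sides, and reports every protein-coding gene whose
span intersects the extended interval, with edge-to-edge distance (0 for
overlap). The gene span is the union of its transcripts' spans. Pearson
correlation across the shared condition set is the normative association
measure ("strong" means |r| at or above the configurable 0.9 threshold,
which is reported in output metadata since no canonical value exists);
Spearman is available as an option. Pairs with a zero-variance profile on
either side are dropped with a message, as their correlation is undefined.

GO enrichment is the hypergeometric upper tail P(X ≥ k) for each term
annotated to at least one foreground gene, BH-adjusted within each GO
category at FDR 0.05. The background is the protein-coding genes *with
expression data*, not all annotated genes — the foreground can only have
been drawn from genes that could have been correlated. No DAG propagation
is performed; terms are tested as annotated.

# The synthetic study

`simulate_study()` generates every input with ground truth, at a desk
scale chosen to run in minutes on one CPU: 2 chromosomes × 2 Mb, 40
multi-exon coding genes plus 10 small RNAs, ~230 assembled transcripts
(20 per class code, 40 multi-exon `u`, 10 single-exon `u`), 10 expression
conditions, and 500 + 500 training sequences. These defaults are the
package's standing study conditions; the acceptance-style tests run
against them unchanged.

What it emulates, and how:

* **Class codes by construction.** Each planted transcript satisfies its
  class definition geometrically — intron chains are copied for `=`,
  terminal exons merged across an intron for `j` (preserving a shared
  junction while breaking containment), single exons placed across
  exon/intron boundaries for `e`, inside introns for `i`/`s`, and
  intergenic transcripts at least the run-on distance plus margin from
  every gene for `u`.
* **Coding structure.** Coding-labeled sequences embed an in-frame ORF of
  360–900 nt (well above the 100-aa threshold) built from a GC-biased
  codon pool; noncoding-labeled sequences come from a mildly AT-rich
  first-order Markov background and are rejection-sampled until their
  maximal ORF is at most 60 aa. The 60-aa cap sits deliberately below the
  100-aa filter so planted labels are unambiguous rather than boundary
  cases, and the first-order composition difference makes the hexamer and
  Fickett features informative without requiring real genome composition.
* **Expression patterns.** Single-condition transcripts get one positive
  FPKM; ubiquitous ones get near-uniform positive values (JS ≈ 0.13 at 10
  conditions); "few"-condition transcripts fall in between. Correlated
  lincRNA–gene pairs share a latent per-condition factor dominated by one
  condition — so correlated lincRNAs remain tissue-specific and survive
  the JS selection upstream of the neighbor stage — with independent
  multiplicative noise (sd 0.05 by default; 0 gives correlation exactly 1).
* **GO maps.** Terms are assigned at a 5% background rate; the planted
  term is assigned to foreground genes at 10× background.

What it does **not** emulate: read-level noise, assembly artifacts
(fragmented or chimeric transcripts), shared exonic sequence between
paralogs, realistic codon usage or isochore structure, FPKM estimation
error, and correlated GO annotations. Passing the closed-loop tests
therefore shows the decision logic is implemented correctly, not that the
thresholds would achieve the same sensitivity on real bovine data.

# Numerical and degenerate-input conventions

* Coordinates are 0-based half-open everywhere internally; GTF I/O
  converts at the boundary (BED is native). Strand conflicts and
  overlapping exons within a transcript are errors, not repairs.
* Hexamer pseudocount 1; natural log for the hexamer score; base-2 log
  for entropies. Fickett lookup uses "first threshold ≤ value".
* ORF ties (equal nt length) resolve to the earliest start in the lowest
  frame. Sequences shorter than 3 nt have an ORF of length 0.
* The locus count groups final lincRNAs by single-linkage over
  same-strand span overlap (strand-unknown links with either strand);
  this is an explicit rule standing in for assembler-inherited locus ids,
  and may differ from any particular assembler's grouping.
* Summary lengths are spliced (exonic) lengths; dispersions are sample
  standard deviations, 0 for a single transcript.
* The held-out split, and only it, consumes randomness during
  identification; `run_config(seed = )` pins it, and two runs with the
  same config and seed write byte-identical outputs.

# Test problem sizes

The suite regenerates all fixtures in code at run time: the desk-scale
study above (shared across test files), a ~510-transcript instance for
the index-versus-brute-force classification check, 500 random sequences
up to 2 kb for the ORF oracle, 100-vs-100 locus sets for the overlap
oracle, and 200 + 200 replicates for the planted-GO power and type-I
checks. These sizes were chosen as the smallest at which the properties
are meaningfully exercised.

# Known limitations

* Class-code semantics approximate the conventional transfrag categories
  but are not a bit-for-bit reimplementation of any particular tool's
  matching (notably fuzzy junction matching and locus merging are out of
  scope); single-exon `=` requires only exonic overlap.
* The coding-potential model is linear in its four features; transcripts
  with unusual ORF structure (selenoproteins, programmed frameshifts) will
  be misclassified, as they are by comparable tools.
* Conservation and domain evidence are consumed as precomputed tables;
  the package does not validate how they were produced.
* GO enrichment ignores the term DAG, so parent terms are only tested if
  directly annotated.
* With ~10 conditions the JS score is coarse; near the 0.5 cutoff small
  FPKM noise can flip calls, which is why the cutoff and floor are
  exposed rather than fixed.
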