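---
title: "Tag-based digital gene expression: models and design choices"
author: "tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

Tag-based digital gene expression (DGE, SAGE-style) counts transcripts by
sequencing one short tag per cDNA copy. NlaIII cuts at its palindromic
recognition site CATG; the 3'-most site of each transcript is captured on
beads, and MmeI then releases a fragment so that the sequenced read is a
21-bp tag: the CATG anchor plus 17 downstream bases. Expression profiling
reduces to counting how many times each tag is seen per library, mapping
tags back to an assembled unigene reference, and testing count differences
between libraries.

`tagdge` implements the desk side of such an experiment end to end:
simulation with known ground truth, raw-tag cleaning, reference tag
indexing and bounded-mismatch mapping, tags-per-million (TPM) and RPKM
normalisation, the Audic–Claverie exact test over a staged multi-library
comparison design, intersection / extreme-ratio screens, trend clustering,
and hypergeometric term enrichment with Bonferroni correction.

## The synthetic-data generator

`synthetic_design()` fixes the experiment: by default 1,000 genes of
200–2,000 bp, five libraries of 200,000 raw tags each, 10% of genes truly
differentially expressed at 8-fold, a per-base substitution rate of 1e-3,
~1% adaptor-only reads and a trace rate (2e-5) of N-containing reads.
These defaults describe a staged design: one non-swelling mutant baseline
(`mutant`) plus four developmental stages (`stage1`–`stage4`) of a
swelling strain, with six default comparisons — each of stages 2–4 against
the mutant and against stage 1.

Choices that matter, and why:

* **Abundances** are log-normal (meanlog 0, sdlog 1.5), normalised to sum
  to one: transcriptome expression is heavy-tailed, and the tail drives
  both the power of the exact test and the composition effects discussed
  below.
* **Fold changes** follow a monotone trajectory over the stages:
  multipliers 1, f^(1/3), f^(2/3), f for stages 1–4 and 1 in the mutant,
  mimicking progressive swelling. At the default f = 8 the stage-2
  comparisons sit at exactly 2-fold — precisely on the |log2| > 1 calling
  threshold — so an intersection over all six comparisons is a
  deliberately hard screen: genes at the boundary pass each stage-2
  comparison with probability near one half regardless of sequencing
  depth.
* **Only the 3'-most CATG site emits tags** (matching the 3'-anchored
  chemistry), although the indexer indexes every site on both strands.
  Stored unigene orientation is randomised, as for de novo assemblies, so
  about half the truth tags lie on the minus strand of the stored
  sequence.
* **Per-library truth** (sampled counts before error injection) is
  returned alongside the reads, and `true_de_flags()` derives
  per-comparison truth as "fold multipliers differ".
* One library per stage is produced (no replication), matching the
  single-library-per-condition structure that the Audic–Claverie test is
  designed for.

What the generator does *not* emulate: PCR amplification bias, MmeI
cut-length heterogeneity (20 vs 21 bp), quality-score structure, and
fragment-level coverage. The last point matters when reading coverage
reports: real libraries accumulate many distinct tags per gene (from
alternative sites, partial digests, and antisense transcripts), so real
unigene coverage often exceeds 50%; simulated coverage is essentially one
21-bp footprint per gene and stays low. Passing coverage tests here
validates the interval arithmetic, not a claim about real coverage
distributions.

Everything is seeded: `make_reference()` seeds from the design,
`simulate_library()` from the design seed plus a per-library offset, so
any library can be regenerated independently and a full pipeline rerun is
byte-identical.

## Cleaning

`filter_raw_tags()` classifies reads in a fixed order: adaptor-only or
empty reads first, then reads containing N, then malformed reads (wrong
length, missing CATG prefix, or non-ACGT characters) counted as low
quality; surviving tags are tallied, and distinct tags below two copies
are removed last (`singleton_removed`), reflecting the convention that a
tag seen once is a probable sequencing error. Two consequences are worth
stating explicitly:

* The ledger identity `raw = clean + adaptor_only + containing_N +
  low_quality + singleton_removed` holds on every input and is asserted in
  the tests.
* Singleton removal deletes *true* singletons too. In a zero-noise
  simulation a gene sampled exactly once comes back with count zero, not
  one. The round-trip identity "mapped counts equal sampled counts" is
  therefore exact when cleaning is run with `min_copy = 1`, and exact up
  to zeroed singletons under the default cleaning; both forms are tested.

"Low quality" is defined by sequence content only (no quality strings are
consulted): the category holds reads that are structurally unusable,
keeping it distinct from the N-containing category that sequencing
summaries report separately.

## Mapping

`build_tag_index()` records every CATG+17 substring on both strands of
every unigene, with gene, strand, and site rank from the 3' end; tags
found in more than one gene are flagged intrinsically ambiguous.
`map_tags()` assigns each distinct clean tag at its minimal Hamming
distance up to `max_mismatch` (default 1, configurable to 2). The CATG
anchor is enzymatically fixed, so the mismatch neighbourhood enumerates
only the 17 variable positions (51 variants at distance 1). Tie rules:

* distance 0 strictly dominates distance 1 (and 1 dominates 2);
* equal-distance hits to several *sites of one gene* count once to that
  gene — "multi-position" is read as multi-gene, and such tags count to no
  gene;
* the ledger satisfies `total_mapped = perfect + mismatch = unique +
  multi_position` and `total_clean = total_mapped + unmapped`.

Coverage is the union of mapped 21-bp footprints (both strands projected
to plus-strand coordinates) over the gene length, computed with interval
reduction and summarised as the fraction of expressed genes above one-half
coverage.

## The exact test and its numerics

For counts `x`, `y` in libraries of `N1`, `N2` clean tags, the
Audic–Claverie conditional law is

    p(y | x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),

a negative binomial in `y` with size `x+1` and success probability
`N1/(N1+N2)`. The two-sided p-value doubles the smaller of the lower tail
(`k <= y`) and the upper tail (`k >= y`), capped at 1 — the symmetric
convention consistent with calling both up- and downregulation. Numerical
choices:

* All terms are accumulated in log space via a log-sum-exp; the
  computation is stable for counts up to 1e6.
* The upper tail is summed directly (adaptive chunks past the mode of the
  conditional law) rather than computed as `1 - lower + p(y|x)`: the
  complement form loses all precision when the lower tail is near one,
  which is exactly where significant downregulation lives.
* When the lower tail is below one half it necessarily is the smaller
  tail (the upper tail contains the balance point), so the doubled lower
  tail is returned without computing the upper sum.
* Two discrete-test caveats the tests document: the two-sided value is not
  exactly invariant under swapping libraries (the swapped lower tail
  complements exactly, but the observed-point mass rescales by `N1/N2`),
  and p is monotone in count imbalance only within each side of the
  balance point `y N1 = x N2`.

Tests compare the implementation against `pnbinom`/`dnbinom` tails — an
independent code path through the incomplete beta function — to 1e-9
relative error over the full grid 0 ≤ x, y ≤ 100 with N1, N2 in
{1e5, 1e6, 3e6}.

## Calling, screening, clustering

`call_de()` tests every gene with a nonzero count in either library of a
comparison; genes at zero in both are excluded from the
Benjamini–Hochberg family so that untestable rows do not dilute the FDR.
The log2 ratio is taken on TPM with a 0.5 pseudocount on the raw counts
(ratio only — the p-value uses raw counts), so genes at zero in one
library get a finite, screenable ratio. A gene is significant when
`fdr < 0.001` and `|log2 ratio| > 1` (both configurable).

`intersect_comparisons()` is the exact intersection of the significant
sets; `screen_extremes()` keeps genes whose |log2 ratio| exceeds the
threshold (default 10) in *every* comparison with a consistent sign;
`cluster_trends()` clusters the six-ratio profiles with Euclidean
distance and average linkage (chosen as the common default for expression
trend trees; both are exposed), cutting the tree into `k = 4` groups.
Rows are sorted by gene id before clustering, so the partition is
independent of input order.

Two design points on truth and power at the default conditions, measured
by the acceptance checks rather than asserted: with f = 8 the stage-4
comparisons recover planted changes with sensitivity around 0.9, but the
six-way intersection recovers only a minority of truly-changed genes
because of the stage-2 boundary described above; and because libraries
are compositional (counts are drawn multinomially), strong upregulation
of abundant genes deflates every other gene's relative count, which can
push truly-unchanged genes past the thresholds. Both effects are
properties of the simulated conditions, not of the caller, and both are
reported as computed.

## Enrichment

`hypergeom_enrich_p()` evaluates the upper-tail hypergeometric
probability as one minus the lower-tail sum, in log space: with `N`
annotated background genes, `n` screened genes, `M` genes in the term and
`m` screened genes in the term,

    P = 1 - sum_{i=0}^{m-1} C(M, i) C(N-M, n-i) / C(N, n).

`enrich_terms()` intersects the screened set with the annotated
background first, tests only terms with `m >= 1`, and applies Bonferroni
over the number of tested terms (the divisor is configurable to all
terms). A term is enriched when the corrected p falls below 0.05. Both GO
and KO annotations use the same rule; term ancestry is not propagated —
annotations are used as given.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → clean → map → diffexp → screen →
enrich from a single YAML configuration, writes every stage product as
TSV/JSON under the output directory, and finishes with a manifest echoing
the package version, seed and parameters. All randomness flows from the
design seed; reruns are byte-identical, and pipeline outputs equal
stage-by-stage invocation (no hidden state). The bundled demonstration
configuration (`inst/extdata/pipeline.yaml`) uses 300 genes and 50,000
reads per library so a full run takes seconds; the statistical acceptance
checks use the full default design (1,000 genes, 200,000 reads per
library), which keeps every check within a few minutes on one CPU.

## Known limitations

* No dispersion-aware model: the test is the exact Poisson-ratio test,
  appropriate for single libraries per condition, not for replicated
  designs (use a negative-binomial framework there).
* No normalisation beyond per-million scaling: strong compositional
  shifts are visible in the results, as in any TPM-based DGE analysis.
* The mapper handles fixed-length anchored tags only — it is not a
  general read aligner, and tags spanning assembly gaps or splice
  boundaries are not modelled.
* Enrichment treats annotations as flat labels; no GO DAG handling.
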