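---
title: "Methods: tag-based digital gene expression with tagdge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression with tagdge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The assay and its model

Tag-based digital gene expression (DGE) counts short 3′-anchored cDNA tags
instead of whole-transcript reads. NlaIII cuts cDNA at every `CATG`; the
3′-most fragment is captured and MmeI releases a 21-bp tag: the `CATG`
anchor plus 17 downstream bases. Each transcript therefore contributes (in
the ideal case) exactly one tag species, and a tag's count in a library of
`N` total tags estimates the transcript's relative abundance. Transcripts
without a `CATG` site are invisible to the assay; `tagdge` tracks these
explicitly as *unquantifiable* genes.

Against a de novo transcriptome the mapping target is not a genome but the
set of all possible tags: every `CATG` + 17 bases in every unigene. The
reference index therefore contains **all** sites, not only the 3′-most —
internal sites matter because a sequencing error, an incomplete digest or a
shared subsequence can land a read on them, and because a tag shared by two
genes must be recognized as ambiguous.

## Cleaning, mapping, ambiguity

Raw tag tables are cleaned by four rules applied per *species* (distinct
sequence): drop empty reads and reads equal to the adapter sentinel; drop
species containing `N`; drop species with total copy number exactly 1
(singletons are overwhelmingly sequencing errors at these library sizes).
Cleaning is deliberately count-based, not quality-score-based: DGE tables
arrive as (tag, count) pairs with no per-base qualities.

Mapping allows at most one mismatch. Two decisions here were genuinely open
and are resolved as follows:

* **Exact-match precedence.** A query's candidate set is its exact matches
  if any exist, otherwise its distance-1 matches. Without precedence, a
  one-error neighbour of gene A's tag that happens to equal distance-1 of a
  paralogous gene B would turn a perfectly good exact match into an
  ambiguous one; precedence keeps a sequencing error from stealing counts
  across paralogs.
* **Neighbourhood index.** Distance-1 lookup enumerates the 3×21
  single-substitution variants of every *reference* tag once, rather than
  expanding each query. The two are equivalent (Hamming balls are
  symmetric); indexing the reference is cheaper because references are far
  fewer than distinct error species. The test suite pins this equivalence
  to a brute-force Hamming scan, gene for gene and count for count.

A species whose candidate set lies in exactly one gene is *unambiguous* and
its whole count accrues to that gene atomically; multi-gene candidate sets
are counted as ambiguous and contribute to no gene (no EM rescue — that is
out of scope). Library-wide accounting satisfies
`clean = unambiguous + ambiguous + unmapped + length-invalid`.

**TPM denominator.** "Tags per million" does not say per million *what*.
The default is total clean tags (the stated mapping universe, and the
denominator under which reported mapping percentages make sense); a flag
switches to total unambiguous tags, under which TPM sums to exactly 10⁶.

## The Audic–Claverie test

With one library per condition there is no replication, so dispersion
cannot be estimated; the appropriate exact test conditions on the observed
count. Given `x` tags for a gene in library 1 (total `N1`), the count `y`
in library 2 (total `N2`) under the null of equal rates follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

a negative-binomial distribution with size `x+1` and success probability
`N1/(N1+N2)`. Numerical contract: terms are computed from log-gamma in log
space; each tail is summed from its own small side (the lower tail
directly, the upper tail by the ascending term recurrence), so neither tail
is ever formed as `1 − (≈1)`; this is overflow-free and keeps ≥10 digits up
to library totals of 10⁷. The two-sided p-value is the doubled smaller
tail, capped at 1, the field's standard choice for this statistic. One
consequence worth stating plainly: the doubled
smaller conditional tail is **not** symmetric under swapping `x` and `y`
(the conditional pmf is symmetric for `N1 = N2`; its cumulative tails are
not), and the property tests assert the symmetry at the pmf level where it
actually holds. Extremely discordant counts underflow double precision;
p-values are floored at the smallest positive double to stay in `(0, 1]`.

DEGs are called at `FDR ≤ 0.001` (Benjamini–Hochberg step-up, the
contemporaneous standard for this design) **and**
`|log2 ratio| ≥ 1`. Ratios are computed on the TPM scale (equal to the
count scale when totals are equal; a flag is unnecessary because both
tables carry counts too). Zero TPM is floored at the TPM of a single tag in
the smaller library, `10⁶ / min(N1, N2)`: count-scaled, it turns
presence/absence genes into large finite ratios (±15 to ±17 at realistic
depths) instead of infinities.

## Enrichment

Terms are tested by the exact hypergeometric upper tail
`P(X ≥ m)` with `N` = annotated genes (the background is restricted to
annotated genes — that is how `N` is defined), `n` = DEGs among them, `M` =
genes on the term, `m` = DEGs on the term, computed as a direct log-space
sum of binomial coefficients. "Corrected P-value" for GO-style analysis is
Bonferroni (conservative, matching contemporaneous practice); KEGG-style
Q-values are BH. Both are selectable. Terms annotating no gene are skipped;
GO-DAG propagation is out of scope.

## Curation filters

Candidate detoxification genes (P450/GST/CES) are curated by three ordered
filters: length < 400 bp removed first (a documented 300-bp preset exists
for P450 screens); then longest six-frame ORF < 100 aa; then allelic
variants collapsed. "ORF" is defined as ATG-to-stop under the standard
code, the most common convention; when no
stop follows, the ORF extends to the frame's last complete codon, and a
`stop_free` mode (longest stop-free stretch, no ATG required) is available.
Variant collapsing replaces manual BLAST judgement with a numeric rule:
single-linkage clusters over pairs with ≥95 % identity across ≥80 % of the
shorter sequence, by exact local (Smith–Waterman) alignment with match +2,
mismatch −3 and linear gap −4 — simple enough that the test suite
reproduces the scores with an independent DP. Each cluster keeps its
longest member (ties to the lexicographically smallest id); non-
representatives are recorded as `removed_variant`, and merging "parts of
the same gene" into scaffolds is deliberately not attempted.

## What the simulator states, and what it does not

The generator's defaults are the package's stated world:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 2000 | large enough for FDR behaviour, small enough for a laptop |
| `length_range` | 300–2000 bp | typical unigene lengths from short-read assembly |
| `catg_free_fraction` | 0.05 | a few percent of transcripts lack a CATG site |
| `library_size` | 10⁶ tags | order of magnitude of a DGE lane after cleaning |
| `error_rate` | 0.01/base | Illumina-era substitution rate; ~19 % of 21-mers get ≥1 error |
| `fold_change`, `n_up`, `n_down` | 8×, 100, 100 | the recovery experiment's spike design |
| baseline abundance | log-normal, sdlog 1 | right-skewed expression, moderate dynamic range |
| contaminants | half adapter-sentinel, half one-`N` reads | exercises each cleaning rule separately |

Sequences are uniform-composition with accidental `CATG`s rewritten out and
1–3 sites planted explicitly, so tag extractability is guaranteed by
construction rather than by luck; spikes are assigned only to quantifiable
genes. Reads are drawn multinomially over genes (weight = baseline ×
fold-change if treated), each read being the gene's 3′-most tag with
independent per-base substitution — the simulator emits only 3′-most tags
while the reference indexes all sites, so simulated data exercise a strict
subset of the mapping logic. All randomness flows from one seed through a
single generator; identical seeds reproduce every output byte for byte.

Features of real data the simulator does **not** model: quality scores and
read-level FASTQ structure, PCR duplication, incomplete NlaIII digestion
(internal-site tags), indels, and any dependence of error rate on position
or context. A green recovery test therefore establishes that the statistics
and bookkeeping are correct under the stated model — not that the model
captures every artefact of a real lane. A real library's error and
contamination composition is rarely known; the simulator's knobs are free
parameters, not estimates.

One modelled effect deserves emphasis: **compositional closure**. Spiking
100 genes 8-fold up adds ~30 % to the treated library's total weight, so
every null gene's *relative* abundance drops by ~0.4 log2 units. With deep
libraries the Audic–Claverie test sees these shifts as highly significant;
it is the `|log2| ≥ 1` arm of the DEG rule that keeps them out of the
calls, and occasional well-expressed null genes that drift past −1 are the
false discoveries the recovery criterion budgets at ≤5 %.

## Tolerances and degenerate inputs

* AC p-values: agree with brute-force tail summation to ≤10⁻¹⁰ relative
  over the tested grid; closed form `2^(1−y)` at `x = 0`, equal totals, to
  ≤10⁻¹².
* Hypergeometric tail: exact against full enumeration for `N ≤ 12`.
* TPM with the unambiguous denominator sums to 10⁶ within 10⁻⁶ relative.
* Empty sequence → no tags (not an error); empty index → configuration
  error; zero TPM denominator → error; `m = 0` → enrichment p of exactly 1;
  a missing seed fails validation before any pipeline stage runs.
* Ties: longest ORF broken by frame order then leftmost start; cluster
  representatives by length then lexicographic id — both make results
  independent of input order.

## Build-vs-buy

The statistical core (Audic–Claverie tails, hypergeometric tail, the
mapping/cleaning/accounting rules, the simulator) is implemented in this
package and cross-checked against independent oracles in the tests.
Standard infrastructure is delegated: FASTA I/O and reverse complements to
Biostrings, local alignment to `Biostrings::pairwiseAlignment` (validated
against an in-test Smith–Waterman), BH adjustment to `stats::p.adjust`
(validated against hand step-up computations), tables to data.table, JSON
to jsonlite.

## Known limitations

No replicate-aware dispersion modelling (single-library design by
construction); no EM allocation of ambiguous tags; no GO-DAG propagation;
no homology search — family labels are input metadata, not computed. The
allelic-variant thresholds (0.95/0.8) are a numeric stand-in for manual
judgement and are configurable precisely because the original criterion was
not numeric.
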