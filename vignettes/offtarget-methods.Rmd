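---
title: "Predicting probe off-target binding: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting probe off-target binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtargetr)
```

# The model

Padlock-probe assays detect a transcript through a 40-bp probe target
sequence: two 20-bp arms hybridize adjacently, ligation seals the junction
between them, and rolling circle amplification renders the event
detectable. The assay cannot distinguish where the probe actually
hybridized, so a probe whose target sequence also occurs in another gene's
transcripts reports the *sum* of both genes' expression under the target's
name.

`offtargetr` models binding purely at the sequence level, with two regimes:

* **Strict mode** (`pl = 0`): a binding site is an exact, contiguous,
  mismatch-free occurrence of the *full* probe sequence on a transcript's
  forward strand. This is the conservative "perfect homology" criterion.
* **Pad mode** (`pl > 0`): hybridization chemistry tolerates mismatches
  near the probe ends much better than near the ligation junction. Pad mode
  therefore requires only the central core `probe[pl+1 .. L-pl]` to occur
  exactly; the `pl` bases at each end (the pads) may mismatch, indel, or
  hang off a transcript end freely. For the canonical 40-bp probe with
  `pl = 10` the core is the middle 20 bp, spanning the junction between the
  two arms. Pad disagreement is annotated (banded edit distance per side,
  clipping free at probe ends) but never filters a hit.

Thermodynamic effects (melting temperature, ΔG, probe–probe interactions)
are out of scope: the tool predicts *candidate* off-targets from sequence
identity, which is the mechanism with the clearest observable footprint and
the one a panel designer can act on.

## Why the aligner is built in, not delegated

Published practice delegates alignment to a general-purpose genome aligner
with anchoring heuristics. The acceptance rules actually applied, though,
reduce to two exact-substring predicates (full probe, or central core).
We implement those predicates directly — a w-mer index over the
transcriptome, one anchor lookup at the core start, then verification —
because the contract is then *deterministic and checkable*: a brute-force
scanner (`brute_force_hits()`) with the same contract serves as an
independent oracle, and the suite proves equivalence on randomized panels.
Correctness is independent of the index word length `w` (default
`min(20, core length)`); `w` only affects speed. `N` bases never match, in
either the probe or the transcript.

# Orientation ("flip")

Panels conventionally store probe target sequences antisense to their
targets, but not uniformly (observed in the field: 2563 of 2582 probes
antisense, with a residue of sense-stored and entirely unmatched probes).
Before alignment, each probe is tested against **its own target gene's
transcripts only** — matched by gene ID, gene name, or declared synonym —
in both orientations:

| forward | reverse | action |
|---|---|---|
| yes | no | keep |
| no | yes | reverse-complement, mark `flipped` |
| yes | yes | keep forward, log `both_orientations` |
| no | no | keep unchanged, mark `unmatched` |

Deciding orientation against the whole transcriptome instead would let a
spurious off-target hit flip a probe; restricting to the target gene makes
flip idempotent and keeps the downstream contract simple (all searches are
forward-strand only). Unmatched probes are reported with a reason code
(`no_match` vs `gene_absent`); locating them in the genome (retired exons,
intronic placements) is browser work, out of scope.

# Annotation ingest

GFF3 and GTF are normalized into one internal shape (0-based half-open
coordinates internally; conversion happens at the parser boundary).
Design choices where the conventions genuinely diverge:

* **Biotypes** collapse into six canonical labels: `protein_coding`,
  `pseudogene`, `lncRNA`, `NMD`, `miRNA`, `other`. Transcript-level biotype
  is preferred; gene-level is inherited when absent. A binding call's
  biotype is the highest-priority label among the transcripts actually hit
  (protein_coding > NMD > lncRNA > miRNA > pseudogene > other), so a gene
  hit only via its NMD isoforms reports NMD.
* **Alternative scaffolds** (`*_alt`, `*_random`, `*_fix`, `*_hap*`) are
  dropped by default; unplaced (`chrUn_*`) contigs are kept. The pattern is
  configurable because no annotation states this normalization itself.
* **RefSeq quirks** are explicit, opt-in rules (`source_rules("refseq")`):
  immunoglobulin/TCR V(D)J segment features are promoted to transcripts,
  and transcripts whose gene biotype is literally `pseudogene` are dropped
  — RefSeq annotates transcripts for only a small, inconsistent subset of
  those genes, which we treat as an annotation error. The distinct
  `transcribed_pseudogene` biotype is *kept*.
* Exons are sorted by coordinate and concatenated; minus-strand transcripts
  are reverse-complemented so stored sequences are mRNA-sense. Soft-masked
  lowercase bases are uppercased: repeat masking is not evidence of
  non-transcription for this purpose.

# On-target logic and reporting

A bound gene is on-target if it matches the declared target by gene ID,
gene name, or synonym. The synonym table is **symmetric but not
transitive**: `(A,B)` and `(B,C)` do not imply `(A,C)`, because chaining
through hub symbols welds unrelated families together. Multi-symbol target
declarations (`"CLECL1; CLECL1P"`) treat any declared symbol as on-target.

Hits are collapsed probe → gene for counting (summary tables count probes
per gene); transcript multiplicity is retained only as `n_transcripts_hit`,
so a probe hitting three isoforms counts once. Read-through genes
(hyphenated symbols with the target as a component) are *flagged*, never
silently removed — exclusion is an explicit switch, and both views are
available, since whether the published union counts were taken before or
after that manual exclusion is ambiguous.

Cross-annotation reconciliation joins on uppercased gene name (IDs are not
comparable across GENCODE/RefSeq/CHESS); genes without names fall back to
ID and are reported unjoinable. The protein-coding-only union is the
headline view: if a probe aligns off-target to a protein-coding gene under
*any* annotation, it could bind in the assay.

# Expression impact

All normalization is CPM followed by natural `log(x + 1)`. Two points the
published description leaves open, decided here:

* **CPM denominators** are the library sizes over *all* features of the
  source matrix, not the panel subset, and aggregation re-normalizes with
  those *same* library sizes. This keeps target-only and aggregated vectors
  on one scale, so their RMSEs are comparable.
* **Log base** is natural (never stated in the field's descriptions;
  the choice only rescales RMSE, not its ordering).

`concordance()` reports RMSE relative to the identity line
(`sqrt(mean((a-b)^2))`) and Pearson correlation; when either vector has
zero variance the correlation is reported as an explicit missing value,
never coerced to 0 — an unexpressed gene has *undefined*, not zero,
correlation, and that distinction is itself a diagnostic (it flips to
defined exactly when aggregation introduces signal). Cluster-level
comparison (`group_means()`) excludes groups with fewer than 10
observations from either modality, the conventional floor for a stable
mean. Spot matching and cluster assignment are consumed as precomputed
inputs; image registration and clustering are out of scope.

# The synthetic world

`simulate_panel()` states a world rather than tuning one; its defaults are
fixed once: 20 target genes × 4 probes of 40 bp on 240-bp transcripts,
three annotation sources, antisense-storage probability 0.99 (matching the
observed 2563/2582), and planted scenarios — 3 perfect-copy paralogs,
2 core-only homologies with flank mismatches at depth 10, 1 at depth 5,
2 pseudogene copies, 2 source-specific paralogs absent from the first
source, 2 retired-exon probes. Counts are negative binomial
(dispersion 10), the standard overdispersed model for expression; the
probe platform records target + planted-off-target sums plus Poisson
noise, and one planted target has zero intrinsic expression so the
missing-to-defined Pearson transition is exercised.

Cross-gene uniqueness of every 20-mer (both strands) is enforced by
rejection sampling against a global registry, which is what licenses
*exact* assertions: no accidental off-target can exist, so sensitivity and
specificity against the truth table must both be 1, and a core-scenario
probe must be detected iff `pl >= d`.

What a green synthetic run does **not** establish: performance on real
transcriptomes (repeat content, GC structure, gene families far larger
than one paralog), agreement with any specific external aligner's edge
cases, or hybridization behavior of pads beyond the exact-core model.
The generator's genome has no repeats and its paralogs differ from their
sources everywhere outside the planted window — real paralogs are
homologous throughout, which produces *more* hits, not fewer, so the
synthetic world is the harder test for specificity and the easier one for
sensitivity.

# Numerical and degenerate-input conventions

* Ties in every ranked table break lexicographically by gene name;
  outputs are deterministic given identical inputs and configuration.
* A probe shorter than `2*pl + 1` is an error, not an empty result.
* Empty synonym file → identity-only table. Empty probe FASTA, duplicate
  accessions, non-`ACGTN` characters, zero-length BED intervals,
  out-of-range exons, and missing contigs are all hard errors naming the
  offending record.
* Pad edit distances use plain Levenshtein (`utils::adist`); the band
  equals the pad length, at which width banding is a no-op, so the simple
  implementation is exact.

# Known limitations

* Genome-level (intronic/intergenic) localization of unmatched probes is
  not attempted.
* Pad mode requires nothing of the pads; if the real chemistry requires
  partial pad pairing, pad mode over-calls (conservative for panel QC).
* Exact hit-set parity with anchor-heuristic aligners on adversarial
  repeats is not guaranteed — the contract here is the exact-substring
  definition, verified against the brute-force oracle.
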