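---
title: "Methods: ortholog clustering and secretome extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog clustering and secretome extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, rules and numerical choices behind
`labsecretome`, in the order the pipeline applies them, and states which
design decisions were genuinely open and how they were resolved.

## The clustering model

The pipeline builds Lactobacillales-style clusters of orthologous groups
(LaCOGs) in three passes over a ranked all-vs-all hit table.

**Ranking.** All rules are defined over a total order of each query's
hits: bit score descending, then E-value ascending, then subject id
ascending. The subject-id tie-break is arbitrary but fixed; it guarantees
that "best hit" and "top 3 hits" are well defined and that reruns are
byte-identical. A consequence worth noting: a tie at the top never yields
two BBH partners for one protein in one genome.

**BBH cores.** A hit participates in bidirectional-best-hit detection
only if its bit score is at least 50 and its aligned overlap at least
50 %. The overlap denominator is the *longer* of the two sequences (the
Inparanoid convention); a `shorter` mode exists because the underlying
criterion is stated ambiguously in much of the literature. Cores are, by
default, greedy maximal cliques of the BBH graph: the highest-total-score
unused pair seeds a core, which grows by the unused protein adjacent to
all current members with the highest summed score to the core. This is
the stringent reading of "each member is the BBH of another member"; the
looser reading — connected components, minimum within-core BBH degree
one — is available as `bbh_core_mode = "component"`. Clique mode is the
default because core formation is meant to be conservative: extension
rules downstream can only add members, never split a bad core.

**Uniform top-3 extension.** A query is assigned to cluster C exactly
when its top k ranked hits all belong to C, with k = 3 in general and
k = 2 when C has exactly two members. Three choices here were open:

* *Hits to unclustered proteins occupy ranks* and therefore veto
  assignment. This is the literal reading of "all of the top 3 hits
  belong to the cluster"; the alternative (skip unclustered subjects when
  counting ranks) is available as `top3_skip_unclustered = TRUE`.
* *Queries with fewer than k hits are never assigned.* Hits that do not
  exist cannot confirm the rule.
* *Assignments within one pass are computed against a frozen snapshot*
  of the memberships and applied together. Extension therefore does not
  cascade within a pass, and the result is independent of query order.

New clusters receive ids `LaCOG90001`, `LaCOG90002`, … in order of their
smallest member id; numbering continues after any existing 9-prefixed ids
so that incremental updates (new genomes against an existing cluster set)
never rename or collide. Seed clusters always keep their original ids.

**Quality-control sweep.** Remaining unclustered proteins join the
cluster of their best-ranked hit that passes the distant-homolog
criterion: E ≤ 1e-3 *and* a query/hit full-length ratio
min(qlen, slen)/max(qlen, slen) ≥ 0.6. The length-ratio form is the
primary definition; an aligned-query-coverage form (`q_cov ≥ 0.6`) is
provided as `distant_criterion_mode = "query_coverage"` because both
formulations circulate. Each round is evaluated against the memberships
at the start of the round, so chains of distant homologs resolve in one
round per link, and the sweep terminates after at most one round per
protein. The same criterion, applied to hits against non-LAB reference
proteomes, separates the final leftovers into distant homologs and
ORFans.

## Alignment statistics

The built-in aligner computes optimal Smith-Waterman local alignments
under BLOSUM62 with affine gaps (open 11, extend 1; a gap of length L
costs 11 + L). Raw scores S become bit scores via the Karlin-Altschul
transform with fixed gapped parameters, bits = (0.267·S − ln 0.041)/ln 2.

`align_local()` reports a *per-pair* expectation value m·n·2^−bits — a
deterministic property of the two sequences alone. The all-vs-all search
(`all_vs_all_hits()`) instead reports E-values scaled to the whole
searched set: E = qlen · N · 2^−bits with N the total residue count of
all subjects. This is the standard database-length convention, and it is
what the pipeline's thresholds (E < 1 initial gate, E ≤ 1e-3 distant
criterion) are calibrated for: those thresholds come from database-scale
BLAST practice, and with per-pair E-values a chance 26-bit local
alignment — of which a quadratic all-vs-all search over thousands of
unrelated proteins produces many, as the Karlin-Altschul expectation
itself predicts — would pass a 1e-3 gate. Database scaling also keeps the
built-in search interchangeable with externally computed hit files,
whose E-values are database-scale by construction.

The search space is restricted by a shared-k-mer prefilter (two distinct
shared 4-mers by default). At the divergence levels the thresholds can
accept (roughly ≥ 30 % identity over ≥ 50 residues), the probability of
a true pair sharing fewer than two 4-mers is below 1e-4; pairs the filter
skips could only produce alignments far below every downstream gate.
`prefilter_kmer = 0` forces the exhaustive quadratic search.

The junction marker `x` of concatenated pseudogene assemblies is mapped
to a wildcard scoring 0 against every residue, so junctions neither
reward nor penalize alignments.

## Subcellular-location screening

The rule cascade in `heuristic_scl()` is a transparent, deterministic
stand-in for a dedicated SCL predictor. It scans Kyte-Doolittle
hydropathy with a 7-residue window; positions whose window mean exceeds
1.5 form membrane stretches (overlapping hot-window runs are merged into
one stretch). The cascade, in order: lipobox `[LVI][ASTVIG][GAS]C` in the
first 35 residues → lipid-anchored; N-terminal stretch (start ≤ 45) with
an A-x-A cleavage site and no further stretch → Sec-secreted
(Tat-secreted when `RR` precedes the stretch); a *sole* N-terminal
stretch without cleavage → N-anchored; LPxTG in the last 50 residues with
a downstream helix and charged tail → cell-wall-anchored; a sole
C-terminal stretch → C-anchored; two or more stretches → multi-TM (never
secretome); otherwise intracellular.

Two windowing effects required care. First, mildly hydrophobic alanines
of the A-x-A site ride the tail of the detected stretch, so the cleavage
search covers everything from stretch start + 7 to stretch end + 10
rather than only residues after the stretch. Second, a hydrophobic
mature-chain start can fuse with the LPxTG motif into one detected
stretch, so the cell-wall rule requires a stretch *extending past* the
motif rather than starting after it. The N-anchored rule carries an
extra "exactly one stretch" condition; without it, multi-TM proteins
with an N-terminal helix could never reach the multi-TM rule.

Two false-positive screens follow. `detect_outside_in()` flags N-anchored
calls whose positively charged residues (K/R) occur only within 10
residues downstream of the helix and never upstream — the positive-inside
rule read in reverse, indicating a cytoplasmic C-terminus — and
`screen_scl()` reclassifies such calls as intracellular.
`small_sec_filter()` removes from the secretome proteins shorter than 80
residues (junction markers excluded) whose only positive feature is a
Sec-type signal: the boundary is strict, 79 residues are dropped and 80
kept, and non-Sec classes are never touched. Entries from an external
SCL table always override the heuristic; the screens never resurrect an
overridden call.

## Secretome extraction and summaries

A cluster is exported when at least `secretome_majority_fraction` (0.5;
ties included, so exactly half qualifies) of its members carry a
secretome class. Only secretome members are exported; clusters that also
contain intracellular members are flagged mixed. Secretome members of
below-majority clusters are reported in a side table rather than dropped
silently. Assembled pseudo-proteins replace their fragments before the
majority vote, so a family's vote is over biological proteins, not
annotation artifacts. Per-genome summaries count, for each genome, the
secretome size and its exhaustive split into clustered proteins, distant
homologs and ORFans.

## Pseudogene assembly

A protein is a fragment candidate when it is shorter than 0.6 times the
median length of the other family members (strict) *and* its best family
hit covers less than 60 % of the subject. Both thresholds operationalize
"represents only a fragment of the protein" and are exposed in the
configuration. In the pipeline, clustered proteins are tested against
their own family; unclustered proteins only against the family of their
best hit, and only when that hit passes the distant-homolog gate —
motif-level matches must not nominate fragments. Candidates on one
contig and strand within 300 nt (`max_fragment_gap`; "adjacent genes"
made concrete) are grouped, each gene region is translated in its
annotated frame from the region start to the first stop codon — no start
codon required — and the translations are joined in the 5'→3' order of
the coding strand with one literal `x` per junction. Overlaps of more
than one codon abort the assembly as ambiguous. The assembled sequence is
re-screened and reassigned with the uniform top-3 rule; fragments
classified intracellular routinely become secretome proteins once
concatenated. Flagged candidates that find no partner are reported as
unassembled. Start-codon anomalies (N-terminal truncation or overhang
> 20 residues against the family's longest member) are flagged with
in-frame ATG/GTG/TTG suggestions when nucleotide context is available;
nothing is ever modified.

## Phyletic patterns and architectures

Each cluster's presence vector over genomes is classified with a fixed
precedence: ubiquitous (missing in at most `ubiquitous_max_missing` = 1
genome — full conservation and lacking-in-one are one category, with the
count retained); else niche-specific (all present genomes share one
niche tag and at least two are present — the two-genome floor keeps
niche-specific from swallowing strain-specific); else species-specific
(one species, at least two strains present); else strain-specific (one
genome); else variable. Niche tags are input data, never hard-coded.
Domain architectures are the N→C sequence of domain accessions with
adjacent repeats collapsed (`LysMx2+NLPC_P60`); overlapping hits resolve
by higher score, then earlier start, and hits outside the protein span
are ignored. Architecture-based sub-division of a cluster is only ever
*suggested* (members grouped by architecture string); membership is
never changed automatically.

## The synthetic study

`generate_synthetic_genomes()` fabricates the study the package is
validated on. Defaults: 4 genomes × 500 proteins, 100 families (70 %
present in every genome, the rest in random subsets of ≥ 2 genomes),
ancestor bodies of 120–300 residues from mildly hydrophilic background
frequencies, orthologs derived by point substitution at identity 0.8 to
the ancestor (pairwise ≈ 0.65; no indels, so within-family length ratios
are exactly 1), a planted secretome of exactly
round(0.08 × 500) = 40 proteins per genome, 10 frameshift pseudogene
pairs, and 20 % of singletons given fabricated non-LAB reference hits
(planted distant homologs; the remaining singletons are the planted
ORFans). The first two genomes are strains of one species; the first
half of the genomes is tagged `dairy`, the second `GI-tract`.

Design points that matter for interpreting test results:

* **Signal grammars are co-designed with the classifier.** Each family
  (and each secretome singleton) draws a grammar once: variable
  hydrophobic cores (8–13 residues over L/I/V/F/A), variable linkers and
  cleavage spacers around the short invariant class motif. Planted
  intracellular bodies are sanitized so that no membrane stretch,
  lipobox or LPxTG survives; grammars are verified against the cascade
  at generation time. Recovery of 100 % of planted classes therefore
  demonstrates internal consistency of grammar and cascade, not
  predictor accuracy on real sequences.
* **Planted singletons honour their own definition.** An ORFan is a
  protein with no detectable homolog under the stated criteria, so
  secretome singletons are rejection-sampled until their best raw
  alignment score against every secretome family member stays below 55
  (≈ 26 bits, i.e. E ≈ 1 against a 2000-protein set) — otherwise the
  shared class motif plus a chance body alignment can cross the E < 1
  gate, and a "singleton" that genuinely passes the pipeline's homology
  criteria would contradict its own planted label. Plain intracellular
  singletons need no such treatment: without a motif head start, the
  probability of a chance alignment reaching the gates is negligible at
  this scale.
* **Frameshift pairs** are planted one per family (secretome families
  first), by back-translating an extra family ortholog, inserting one
  base after the middle codon, and annotating the two resulting ORFs on
  a fresh contig (alternating strands). Reading the downstream ORF in
  its shifted frame recovers the C-terminal half exactly, so assemblies
  reconstruct the planted protein at 100 % identity; the ≥ 95 % bar in
  the tests leaves room for junction-adjacent artifacts.
* **Fabricated hit tables** (`synthetic_hit_table()`) score each
  within-family pair as twice the count of identical residues in the
  implied ungapped alignment — a monotone stand-in that lets every
  clustering rule be tested without running the aligner.

What the generator does *not* emulate: indels and domain shuffling
within families (an ortholog's length never drifts), genuinely
convergent signal peptides across unrelated proteins, low-complexity
sequence, paralogous expansions within a genome, and any realistic
phylogenetic correlation structure. Passing the recovery tests therefore
shows the rules are implemented faithfully and are mutually consistent
at realistic scale — not that the thresholds would achieve the same
precision on real proteomes, where all of the above exist.

## Problem sizes and determinism

The test suite exercises the full pipeline at 4 × 500 proteins with the
built-in aligner (about two minutes of alignment on one core) plus a
3 × 60 fixture on fabricated hit tables for the cheaper unit tests;
exhaustive oracles run at ≤ 50 proteins, ≤ 8 clusters (top-3 rule),
≤ 18 proteins (quadratic BBH enumeration), all 2^n labelings for
clusters up to size 10 (majority rule) and all presence patterns for up
to 6 genomes (phyletic classifier). All randomness flows through
explicit seeds; identical inputs and seeds give byte-identical output
files (clusters sorted by id, members lexicographically). The generator
restores the caller's RNG state on exit.

## Known limitations

* The SCL cascade is a transparent heuristic; it does not model signal
  peptide probability, helix prediction or cleavage-site statistics, and
  no accuracy on real sequences is claimed. The annotation-table path is
  the fidelity route.
* Non-classical secretion is representable only via annotation tables —
  no rule can produce it.
* Only the frameshift/adjacency pathway of pseudogene repair is
  automated; isolated N-/C-terminal truncations without a frameshift are
  flagged (start anomalies, unassembled candidates) but not repaired.
* In-paralog expansion (Inparanoid's second stage) is not implemented;
  within-genome paralogs enter clusters only through the top-3 and QC
  rules.
* The greedy clique heuristic does not guarantee maximum cliques; it
  trades optimality for determinism and speed, which suffices because
  extension stages recover members the greedy step leaves out.
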