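---
title: "Methods: the membrane-proteome topology census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the membrane-proteome topology census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memtopo)
```

`memtopo` analyses curated topology tables of ER-inserted alpha-helical
membrane proteins. This vignette is the package's account of the methods:
the data model and its conventions, the hydrophobicity scale, the
classification rules, the charge statistics, the synthetic-proteome
generator, and the numerical and design choices made where more than one
reasonable option existed.

## Data model and coordinate conventions

A protein record consists of a sequence, an optional cleavable signal
peptide, ordered TMD spans, and the membrane side of the N terminus
(`inside` = cytosolic, `outside` = exoplasmic). All coordinates are 1-based
and inclusive on both ends, the UniProt convention; a 19-aa TMD spanning
242–260 is consistent only with this choice.

Extramembrane segments are never taken from the input: they are deduced from
the TMD coordinates (`deduce_segments()`). The N-terminal tail runs from
residue 1 — or from `signal_end + 1` when a signal peptide is present — to
`TMD1_start − 1`; internal loops run between consecutive TMDs; the C-tail
runs from `TMDn_end + 1` to the protein end. Abutting TMDs produce
zero-length segments, represented with `end < start` and `length` clamped at
0 — zero-length loops participate in all counts and length statistics.
Membrane sides alternate segment by segment, starting from the N-terminus
side; a cleavable signal forces the mature N terminus outside. When a table
carries explicit loop columns, they are cross-checked against the recomputed
segments and disagreements are reported in the parse report rather than
resolved by guessing which source is authoritative.

The reader is deliberately tolerant about column naming (a documented alias
map) and deliberately strict about content: rows with coordinates outside
the sequence, ambiguity codes (B, Z, U, J, O), stated lengths or TMD counts
contradicting the data, duplicated accessions, or a signal peptide paired
with an inside N terminus (internally contradictory) are rejected row by
row, each with a recorded reason; nothing is dropped silently. `X` is
tolerated in sequences — such records parse and classify, but TMDs
containing `X` cannot be ΔG-scored and surface in the scoring report
instead. TMDs of unusual length (≤14 aa or ≥35 aa) are flagged, not
rejected.

## The hydrophobicity scale

ΔG_app — the apparent free energy of membrane insertion, kcal/mol — is
computed with the position-dependent biological hydrophobicity scale (full
model). For a segment of length $L$, residue $i$ (0-based) sits at the
normalized coordinate $x_i = 9\,(2i/(L-1) - 1)$, and

$$\Delta G_{app} = \sum_i \mu_{0,aa}\,e^{-\mu_{1,aa} x_i^2}
 \;+\; c_m \sqrt{\Big(\sum_i d_i \sin 100^\circ i\Big)^2 +
                 \Big(\sum_i d_i \cos 100^\circ i\Big)^2}
 \;+\; k_0 + k_1 L + k_2 L^2,$$

where $d_i$ is residue $i$'s position-specific contribution, Trp and Tyr
carry an extra symmetric two-Gaussian interface term, $c_m = 0.27045$ at the
alpha-helical periodicity of 100°/residue, and the quadratic length
correction has its minimum near 24 aa. The parameter file ships with the
package (`inst/extdata/dg_scale_full_model.tsv`) and its provenance string is
echoed in every pipeline log and report.

Three structural properties of this model are worth stating because the test
suite leans on them. First, the position profile is symmetric about the
segment midpoint and the moment magnitude is reflection-invariant, so
`dg_app()` is exactly invariant under sequence reversal. Second, no single
residue is uniformly "most hydrophobic": Ile has the lowest central
contribution, but Phe and Trp are the most favorable at the membrane
interfaces — so the only safe single-substitution monotonicity property is
central substitution by Ile (the moment coefficient being < 1 guarantees it
can only lower the score). Third, the supported segment length is 9–40 aa;
recorded TMDs longer than 40 aa are scored by the minimal-ΔG_app window
within their span, mirroring how over-long TMDs are handled in practice.

`dg_scan()` enumerates all windows over a configurable length range (default
19–23 aa, the prediction server's standard window policy) and returns the
minimal-ΔG_app window. Ties are broken deterministically: smallest start
coordinate, then smallest window length. Windows covering a nonstandard
residue are skipped; if no scorable window exists the scan errors rather
than reporting a fabricated value. Scan correctness is tested by exhaustive
brute-force enumeration on random sequences, with the oracle recomputing
every window score directly from the raw coefficient file.

## Topology classes, TMD pairs, and insertion reactions

Single-pass proteins: a cleavable signal gives Type I (`SP-I`); signal
anchors are Type II (`SP-II`, N_cyt with a C-tail > 50 aa), Type III
(`SP-III`, N_exo), or tail-anchored Type IV (`SP-IV`, N_cyt with a C-tail
≤ 50 aa — the boundary is exactly 50, and the stricter "C-tail" definition is
used rather than "TMD within ~50 aa of the C terminus"). Multipass proteins
are `MP-SS`, `MP-Nexo` or `MP-Ncyt`.

A *TMD pair* is two TMDs separated by a short (≤ 50 aa) exoplasmic loop.
Pairing is greedy left-to-right: TMD $i$ pairs with TMD $i+1$ iff the loop
between them qualifies and TMD $i$ is not already the second member of a
pair. Greedy pairing was an open design point — no pairing algorithm is
forced by the definitions — but it is deterministic, it reproduces the
canonical shapes (an N_exo 7-TMD receptor yields TMD1 + pairs (2,3), (4,5),
(6,7); an N_cyt even-TMD transporter yields (1,2), (3,4), …), and because
loop sides alternate it can never orphan a TMD between two qualifying loops.
Each pair carries a context from its preceding cytosolic flank: `first_pair`,
`internal_after_short_cyt` (≤ 50 aa), `after_long_cyt` (> 100 aa), or
`after_intermediate_cyt` (51–100 aa). The intermediate context is kept
distinct and excluded from short-versus-long contrasts instead of being
folded into either side.

Signal-anchor (SA) classes apply to cotranslationally targeted proteins
without a cleavable signal, tail-anchored proteins excluded (their route is
posttranslational): `Nexo_SA` when the N terminus is exoplasmic;
otherwise `Ncyt_pair_SA` when TMD1 opens a TMD pair, `Ncyt_long_SA` when the
translocated segment downstream of TMD1 exceeds 100 aa, and `SA_other` for
the intermediate 51–100 aa translocated domains, which plausibly access
either insertion route and are therefore reported separately rather than
forced into a class. Note that for a Type II single-pass protein the
translocated downstream segment is its (exoplasmic) C-tail, so `SP-II` with a
C-tail > 100 aa is `Ncyt_long_SA`.

Each TMD receives one of six core insertion reactions: R1 (TMD following an
SS-translocated domain; Sec61 lateral gate), R2 (N_cyt SA preceding a long
translocated loop; Sec61), R3 (N_exo SA; insertase), R4 (tail anchor;
posttranslational), R5a/R5b (the two TMDs flanking a > 100-aa exoplasmic
loop; Sec61), R6a/R6b (first/second TMD of a pair; insertase/multipass
translocon). Rules apply in that order and never relabel: an R2 signal
anchor that also flanks a long exoplasmic loop stays R2 while the TMD
terminating that loop becomes R5b. TMDs matching no rule are `residual` with
a sub-reason (intermediate exoplasmic flank, unpaired terminal TMD, …). The
final C-terminal TMD of a multipass protein is additionally available as a
context tag (`terminal_mp`) but is not a reaction of its own.

## Charge statistics

Every TMD is partitioned into five zones — exoplasmic interface (outermost
20%), three hydrophobic-core segments (15/30/15%), cytosolic interface
(innermost 20%) — with boundaries at cumulative fractions 0.20/0.35/0.65/0.80
of the length, each rounded half-up. Cumulative rounding guarantees the
zones tile the TMD at every length ≥ 5 aa (half-up rather than banker's
rounding keeps the sizes reproducible across platforms). The partition is
oriented by the TMD's flanking segment sides, and charged residues (K, R, D,
E; His is not counted) are mapped at fractional depth $(i - 0.5)/L$ from the
exoplasmic face, so no residue center ever sits on a zone boundary.

Flanking charges count K/R minus D/E in windows of 5, 10 and 15 residues
adjacent to each TMD, on each side. Windows stop at the flanking segment's
boundary — they never read into a neighboring TMD or the signal peptide.
When the available flank $L$ is shorter than the window $W$, the count is
scaled by $W/L$: of the readings compatible with "proportional charge
counts", multiplicative scaling is the one that keeps the statistic an
expected count over a full window. Scaled values carry a flag so any
summary's sensitivity to this choice can be assessed, and the scaling can be
disabled globally (`proportional = FALSE`) to obtain the count-as-is
alternative. The combined charge used in the class summaries is the net
charge of the TMD's own interfacial zone (unscaled) plus the 10-aa flank.
For a TMD pair treated as one unit, the inside bias sums the combined
cytosolic charges of both TMDs, and the outside bias is the net charge of
the entire exoplasmic loop plus both exoplasmic interfacial zones, with no
truncation or scaling.

## Sequons and census statistics

N-glycosylation sequons are N-X-[S/T]; the default motif is the strict
N!P(ST) (Pro disallowed at the second position), with plain NX(ST)
selectable. A sequon is *usable* when its Asn lies in an exoplasmic segment
at least 12 aa (configurable; the plausible range is 12–14, and the report
states the value used) from every TMD, distance counted so that a residue
immediately adjacent to a TMD is 1 away.

Census statistics follow fixed conventions: medians of even-sized samples
are the mean of the two central values; "short" means ≤ 50 aa and "long"
> 100 aa everywhere; tails and loops are pooled per segment (not per
protein) in the combined rows; empty strata are omitted from summaries, not
reported as zeros; and raw counts always accompany percentages. The report
serializes deterministically (fixed key order and digits), so identical
inputs give byte-identical reports.

## The synthetic-proteome generator

The generator exists so that every pipeline stage is testable without any
external data, and so that recovery of known truth is measurable. Its
defaults are the census study conditions: the topology-class mix
(1247/477/304/220/247/978/1390 over 4,863), TMD-count models with the
observed parity biases (0.88 odd for N_exo multipass, dominated by 7-TMD
proteins; 0.89 even for N_cyt multipass), a discretized normal TMD-length
distribution on 15–35 aa whose location is solved at build time so the mean
is exactly 23.6 aa (sd 3 aa is a free choice; no dispersion is published),
log-normal loop/tail length models pinned to the published medians and
mean/median ratios, with explicit short/intermediate/long mixture weights
(91.8/5.3/2.9% for exoplasmic and 89.4/6.2/4.4% for cytosolic inter-TMD
loops), and flanking-charge targets of +2.04/−0.17 (single-pass
inside/outside) and +0.93/−0.12 (multipass) at the 10-aa window.

Class-conditional hydrophobicity is produced by two-table composition
mixtures: a hydrophobic table and a charge-free polar table, mixed per TMD
stratum with a weight calibrated at configuration-build time against the
bundled ΔG scale (a Monte-Carlo grid over mixing weights, inverted by
monotone interpolation) to hit the published class mean ΔG_app values
(single-pass SS-following −1.89, N_cyt-long SA −1.36, N_exo SA −0.80,
N_cyt-pair SA +0.47, TMD pairs +1.12, post-N_cyt-long TMD 0.0, and so on).
The calibration is computed, not hand-entered, and runs under its own fixed
RNG stream.

Randomness uses three named substreams — structure, composition, charges —
derived from the single user seed, so adding a draw in one phase does not
shift the others, and generation restores the caller's RNG state. Flank
charges are drawn per flank as Poisson counts with intensity scaled by
(usable region)/10 and placed uniformly in the region adjacent to the TMD;
internal loops are split between their two flanking TMDs. This construction
makes the proportionally scaled 10-aa flank measurement exactly unbiased in
expectation for every loop length, the only residual bias being the rare
truncation when a drawn count exceeds the available room.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequences outside the drawn structure are
compositional filler with no homology, domain structure, or protein-family
signal; TMD interiors never contain charged residues (intramembrane charge
statistics are exercised by hand-built fixtures instead); sequons occur only
incidentally; and loop-length models reproduce medians and class proportions
but not the full empirical shapes. Exact recovery is therefore claimed only
for discrete truth (topology classes, SA classes, pair lists, loop classes —
the generator emits unambiguous geometry), while continuous targets (class
mix, mean TMD length, flank-charge means, stratum ΔG means) are recovered
within Monte-Carlo tolerances stated in `recovery_check()` and calibrated
for proteomes of roughly 5,000 proteins.

## Problem sizes and runtime choices

The shipped test suite checks the tiling/alternation invariants on 10,000
generated records, scan-versus-enumeration equivalence on 200 random
sequences (≤ 200 aa), reversal invariance on 1,000 random segments, zone
tiling for every TMD length from 5 to 40, and full truth recovery on a
5,000-protein simulation; the acceptance script reruns the pipeline on a
5,000-protein proteome in about two minutes on one CPU. These sizes keep
Monte-Carlo error comfortably inside the stated tolerances (for example, the
standard error of the single-pass inside-flank mean at n ≈ 2,300 flanks is
about 0.035 charge units against a 0.15 tolerance).

## Known limitations

Reproducing the published human census numbers requires the curated
supplementary topology table (and, for the single printed ΔG_app anchor, the
SEC61A1 sequence); the package ships no curated data and performs no
retrieval, so those reproduction checks only run when a user supplies the
files locally. Curation itself — database concordance, signal-peptide
prediction, structure-based TMD boundary assignment — is out of scope:
orientation and TMD coordinates are inputs, never predicted. The scale
parameterization matches the public predictor's full model; agreement with
any individual recorded value beyond the ±0.01 kcal/mol print precision is
assessed, not asserted. Functional classifications (channel/transporter/E3
lists) and figure rendering are likewise out of scope.
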