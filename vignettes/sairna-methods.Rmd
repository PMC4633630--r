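---
title: "Models and methods behind sairna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sairna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sairna)
```

This vignette explains the models the package implements, the parameters
that matter, and the design choices made where the underlying biology pins
down a rule only partially. It states no numbers that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Hairpin construction

All coordinates are 1-based and inclusive on the 5′→3′ strand of the stated
molecule; guide positions always number the guide 5′ end as 1. Designs are
reported in the RNA alphabet, cloning oligos in DNA; T and U interconvert at
module boundaries.

A 5′-arm design against a target window of length `stem_len + loop_len`
(21 nt for the canonical 17+4 saiRNA) follows four rules:

1. **Guide position 1 is a fixed A.** Pairing of the siRNA 5′ nucleotide
   with the target is dispensable for slicing, a 5′ A/U has the highest Ago
   affinity, and an A +1 residue initiates H1 transcription efficiently.
2. **Positions 2 through stem+loop are target-complementary** — the reverse
   complement of window positions 1..n−1, read back from the window 3′ end.
   The loop itself pairs the target; without this, the 3′ portion of a
   short-stem guide cannot engage its site and silencing collapses.
3. **The 3′ arm is the reverse complement of the 5′ arm, except opposite
   guide position 1**, where a C (default) or A mismatch is engineered to
   bias guide-strand selection. The mismatched position counts toward the
   stem length.
4. For stems whose `stem+loop` exceeds the window (long Dicer-substrate
   designs on a 21-nt window), complementarity is capped at the window and
   the remaining guide positions are copied from the mRNA context
   immediately downstream of the window: the window defines the maximal
   complementary span, but a longer stem still needs sequence.

Classic pLKO.1-style shRNAs invert the geometry: the 5′ arm is the sense
21-mer, the guide is the pure antisense 3′ arm, and the loop (default the
6-nt `CUCGAG` TRC loop) does not pair the target; no A is forced and no
mismatch engineered.

`build_sairna()` (16–18 bp) and `build_shrna_5arm()` (21–24 bp) are
range-checked wrappers over `build_hairpin_5arm()`, which accepts the full
studied 14–24 bp range — the 19–20 bp dead zone must be constructible to be
studied, even though no one should clone it.

### Candidate filtering and ranking

`scan_target_sites()` enumerates every window and filters on GC fraction
(default 0.25–0.75, the usual efficacy band) and on guide U-runs: a guide
containing ≥ 4 consecutive U would recreate a pol III terminator inside the
transcript, so such windows are rejected (`max_u_run = 4`). Ranking combines
the duplex-end asymmetry score, GC deviation from 0.5, the longest guide
homopolymer and an optional precomputed off-target load, with ties broken
toward the 5′-most site. Weights are reported alongside the order.

### Asymmetry score

The score compares the terminal 4 bp at the guide 5′ end against the
terminal 4 bp at the passenger 5′ end, using the ten Watson–Crick RNA
nearest-neighbour free energies at 37 °C (Xia et al. 1998) embedded as
constants; stacks touching a mismatched position contribute zero. We report
`dG(passenger 5′ window) − dG(guide 5′ window)` so that **negative values
mean the guide 5′ end is the less stable duplex end** — the configuration
that favours guide retention by RISC. (With standard negative free energies,
the opposite subtraction order would assign favourable designs positive
scores; the sign convention here keeps "more negative = better", and the
strand-swap antisymmetry `score(swapped) = −score(design)` holds exactly.)

## Expression cassette and ribozyme

The default HDV ribozyme is the 85-nt genomic sequence with the catalytic C
at position 75, embedded as a constant; `ribozyme_spec()` is fully
overridable for engineered variants (sequence, catalytic position, cleavage
offset). Cleavage occurs immediately 5′ of ribozyme nt 1, requires no base
pairing with the upstream flank (asserted over random spacers), leaves a
2′,3′-cyclic phosphate upstream and a 5′-OH downstream, and conserves the
sequence exactly. The C75U point mutant never cleaves, on any substrate.
`pnk_dephosphorylate()` models the T4-PNK (ATP-free) conversion of the
cyclic phosphate to a hydroxyl; end chemistry is tracked for its diagnostic
value (gel mobility) but does not alter loading or stability downstream,
matching the observation that the cyclic phosphate is functionally neutral.

The default spacer between the hairpin 3′ arm and the ribozyme is `UU`
(configurable 0–5 nt): after self-cleavage the spacer *is* the 3′ overhang,
so the default reproduces the short 2-nt overhang that licenses Ago2
binding. Spacers containing a run of ≥ 4 U are rejected as terminator
collisions. With `variant = "none"` the cassette is the bare hairpin plus
terminator — no spacer.

Pol III (H1/U6) transcription appends a templated U-tail of 4, 5 or 6 nt;
the relative abundances of the three tails are not known, so the ensemble is
weighted uniformly (configurable) and always normalized to total weight 1.
Pipelines propagate the whole weighted ensemble rather than sampling, so
default runs are deterministic; any sampling (read generation) takes an
explicit seed. T7 transcription yields a single full-length run-off
transcript with no tail model.

Folding is template-directed against the known design — the declared stem
pairs, the loop span, and the unpaired terminal runs as 5′/3′ overhangs.
No free-energy folding is attempted: the designer guarantees the intended
structure, and measuring overhangs is the only job folding has here.

## Processing model

Classification is piecewise-constant in stem length with breakpoints exactly
at 16, 19 and 21: `DICER` ≥ 21 bp, `DEAD_ZONE` 19–20 bp, `AGO2_SAI`
16–18 bp, `SUBOPTIMAL` < 16 bp.

**Dicer route.** Duplex lengths span 21–24 nt, capped at the stem, with
weights defaulting to a 21/22-dominated distribution (0.4/0.4/0.1/0.1,
configurable); every duplex carries 2-nt 3′ overhangs and both strands are
reported as RISC cargo — the passenger survives this route, which is exactly
why shRNAs have passenger-strand off-targets.

**Ago2 route.** The slice bond is fixed opposite guide positions 10/11 —
the canonical slicer register; the observation "in the middle of the 3′
strand" does not pin the register for every stem, so the fixed 10/11 rule is
an explicit modelling choice. The intermediate (5′ product) therefore has
length `stem + loop + (stem − 10)`: 28 nt for 17+4, and 32 nt (> 30) for a
19-bp stem — the dead-zone signature. For `AGO2_SAI` the intermediate is
trimmed into mature guides of 21 up to `min(24, intermediate)` nt (uniform
weights by default; the heterogeneity is real but its distribution is not
quantified), all sharing the precursor 5′ end. `DEAD_ZONE` and `SUBOPTIMAL`
yield the intermediate only. Whether sub-16-bp stems are Ago2-bound at all
is not directly established; they are treated as load-but-no-product, and
`dicer_process()` on anything below 21 bp is an error. Passenger emission is
structurally zero on this route — the slice destroys the passenger.

**Loading gate.** Ago2 binding is a monotone non-increasing step function of
the 3′-overhang length: weight 1 at ≤ 2 nt, 0.5 at 3 nt, 0 at ≥ 4 nt.
The two observed anchor states are a 2-nt overhang that binds fully and a
4–6-nt U-tail that does not bind; the 3-nt half-point is a declared
interpolation, and both thresholds are configurable. A `leak` parameter
(default 0.05) routes a small fraction of gate-blocked precursor through a
3′-trimmed 2-nt-overhang isoform, representing the minor short isoform seen
for uncleaved saiRNA; setting it to 0 removes matures entirely in the C75U
case.

**Ago partitioning.** Dicer duplexes load the guide into all four Agos
equally and the passenger into Ago1–3 (Ago4 defaults to 0, matching its
below-detection expression; configurable). Ago2-dependent outcomes place
intermediate and mature guide on Ago2 only, scaled by the loading gate;
slicing-incompetent Ago1/3/4 hold unprocessed precursor. A residual Ago3
mature weight (default 0) is available for its weak cleavage activity.
`ago2_active = FALSE` simulates an Ago2 knockout: no mature saiRNA species
anywhere.

**Weight semantics.** Species weights are fractions of one transcribed
precursor equivalent. For saiRNA, remaining precursor plus matures sum to 1
and the intermediate is additionally reported as a transient observable at
the loaded weight; in the dead zone the intermediate is terminal and enters
the balance itself.

## Off-target model

Seeds are the exact hexamer at strand positions 2–7; sites are exact reverse
complements in 3′ UTRs, with overlapping occurrences counted (7mer-m8/7mer-A1
site classes and conservation scoring are out of scope). DEG attribution
filters to control FPKM ≥ 10, classifies up/down at a treated/control ratio
of 1.5 with ties included (a relative epsilon of 1e−9 keeps exact-threshold
ratios from falling to floating-point error; both cutoffs configurable, with
an optional pseudocount defaulting to 0 because the FPKM filter removes
zeros), and intersects the downregulated set independently with guide- and
passenger-seed site presence — the two rows may overlap, and both "genes
with ≥ 1 site" and total site counts are available since the original
tabulation convention is ambiguous. For saiRNA the passenger row is `NA`:
the species does not exist. When several mature isoforms are emitted, the
seed comes from the highest-weight isoform (the major isoform). Antisense
risk is flagged when a transcript contains a site perfectly complementary to
a 21-nt passenger window — for a classic shRNA the passenger is the sense
sequence, so any antisense transcript overlapping the target site matches;
saiRNA designs always return no risk.

## Small-RNA profiler

Reads are clipped at the first occurrence of the 3′ adaptor (or a terminal
adaptor prefix of ≥ 6 nt, mismatch-free; both configurable); unclippable
reads and clipped inserts < 19 nt are removed, and survivors collapse to
unique sequences with multiplicities. Quality strings are carried but
ignored — the upstream platform quality step is out of scope. Categorization
is sequential and exhaustive: construct → miRNA → tRNA → rRNA → snoRNA →
other reference → unmapped, first match wins, so classes are disjoint and
sum to the useful total. Matching is exact substring against either strand
of the reference — a desk-scale equivalent of 0-mismatch genome alignment on
user-supplied reference sets, which preserves the 0-mismatch semantics while
replacing genome-scale indexing. miRNA counting anchors the read 5′ end
exactly at the annotated mature start and allows 3′ ends within ±2 nt, with
additions required to be templated by the precursor (untemplated tailing is
not counted; a relaxation flag exists). Normalized abundances are
`count / total miRNA counts × 1e6`, kept at full precision. End
heterogeneity tabulates (5′, 3′) isoform pairs per strand — strands assigned
by footprint midpoint relative to the construct midpoint — and reports the
top-2 isoforms and the fraction of reads sharing the modal 5′ position.

## Synthetic data: what it does and does not show

`synth_transcriptome()` builds UTRs by rejection-sampling random sequence
free of the queried seed sites, then plants exactly one site per designated
target gene (re-verified after planting) and downregulates those genes by a
known fold change on top of a lognormal baseline that passes the FPKM
filter; optional log-normal noise perturbs the rest. `synth_reads()` draws
reads from simulated species weights with optional uniform end jitter and an
appended adaptor. Both are seed-reproducible to the byte.

These generators emulate *structure*, not biology: real 3′ UTRs have
composition bias, repeats and shared motifs, so real seed matches collide
and partially-complementary (non-seed) off-targets exist; real libraries
have ligation bias, untemplated tailing and sequencing error. Passing the
planted-recovery and proportion-recovery tests therefore demonstrates that
the bookkeeping is exact — filters, intersections, anchoring, normalization
— not that the thresholds would reproduce any particular cell line's DEG
table.

## Problem sizes and numerical choices

The test suite runs at small, fixed-seed sizes chosen to exercise every rule
while keeping the whole suite in seconds: windows of 21–28 nt, UTR sets of
20–60 genes at 200–400 nt, seed-scan oracles up to 10 kb, and read libraries
of 1e5 for the proportion-recovery check (binomial 3σ tolerance). Exhaustive
loops cover all stems 14–24 and loops {2,4,7,9} where a rule has breakpoints.
Ties in ranking break deterministically (5′-most site, then input order);
all ensemble weights are renormalized at construction; degenerate inputs
(empty FASTA, empty UTR set, zero depth, zero-count normalization) are
defined — empty results where a sum is not required, errors where it is.

## Known limitations

No kinetics anywhere: cleavage, dicing, trimming and export are represented
by weights and step functions, not rates. No free-energy folding of target
or hairpin, no chemical-modification design, no machine-learned efficacy
scores, no genome-scale alignment, and no miRNA-target prediction for
upregulated genes. The slice register below 16 bp and the dead-zone kinetics
are modelling choices, flagged above, not measurements.
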