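---
title: "Designing optoXR chimeras and quantifying their assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing optoXR chimeras and quantifying their assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoxr)
```

## The model: segment swapping on a rhodopsin backbone

An optoXR is a chimera: the transmembrane core and extracellular face of a
light-sensitive opsin (rhodopsin), with the intracellular, G-protein-facing
segments of a target class-A GPCR grafted in. The design problem is purely
sequence-level once three inputs are fixed:

1. the backbone sequence and its **topology** — an ordered, contiguous,
   exhaustive partition of the residues into the canonical class-A segments
   (NTERM, TM1, ICL1, TM2, ECL1, TM3, ICL2, TM4, ECL2, TM5, ICL3, TM6,
   ECL3, TM7, optionally H8, CTERM);
2. the target sequence;
3. a **rule set** declaring, per segment, which parent contributes the
   residues, plus two offsets that place the actual cut sites.

Cut sites live on the backbone (at segment edges, displaced by the
offsets); the homologous positions on the target are obtained by projecting
them through a residue-level alignment. The chimera is then assembled
N-to-C by walking the backbone topology and copying each maximal
same-source run either from the backbone (backbone coordinates) or from the
target (projected coordinates). Every emitted residue carries provenance
(source, source index, segment), and the concatenation of the provenance
records must reproduce the chimera string exactly — an invariant the test
suite fuzzes over random receptors and rule sets.

### V1 and V2 rule sets

* **V1** (legacy): ICL1, ICL2, ICL3 and the C-terminus from the target;
  everything else backbone. `proximal_tm_offset` flanking TM residues on
  each side of each swapped loop also come from the target. A published
  two-loop variant that keeps ICL1 is available as `keep_icl1 = TRUE`.
* **V2** (optimized): ICL1 stays backbone — ICL1 residues do not contribute
  to G-protein binding — while ICL2, ICL3 and the C-terminus are swapped,
  and the C-terminal exchange point moves `cterm_cut_shift` residues from
  the TM7/C-terminus boundary into TM7, because membrane-proximal
  C-terminal residues do contribute to G-protein contacts.

Two numeric choices were genuinely open, because published chimera
sequences encode them only implicitly:

* `proximal_tm_offset` defaults to **2** residues. The design literature
  says only that "proximal" TM residues accompany swapped loops; two
  residues is the smallest flank that moves the cut out of the loop's
  helix-capping positions. It is a documented assumption, configurable per
  design.
* `cterm_cut_shift` defaults to **8** residues into TM7 for V2, enough to
  capture the membrane-proximal contact stretch while leaving most of TM7
  intact. Also configurable.

H8, when annotated, always follows the C-terminus' source assignment: the
amphipathic helix 8 is functionally part of the C-terminal exchange unit,
and no rule set treats it separately. The 1D4 epitope (`TETSQVAPA`)
defaults to on, appended after the C-terminus with provenance `EPITOPE`, so
all designs can be immunolabeled with the same anti-rhodopsin antibody; set
`epitope = ""` to disable.

Degenerate inputs are errors, not silent repairs: a projected segment that
collapses to zero length on the target, an `X` (unknown residue) inside any
region selected for exchange, and an epitope containing non-alphabet
characters all abort the design with the offending segment named.

## Alignment and cut-site projection

The package aligns internally rather than shelling out to an MSA program,
so designs are deterministic and dependency-free; an aligned FASTA from any
external tool can be supplied instead via `import_alignment()`, whose score
is recomputed under the same scoring so both routes are comparable.

The aligner is global Needleman–Wunsch with Gotoh's three-state affine-gap
recursion, maximizing substitution score minus `open + (L−1)·extend` per
gap of length `L`. Defaults are the conventional protein settings BLOSUM62
/ 11 / 1 (the matrix ships in NCBI text format and can be replaced).
Terminal gaps are penalized like internal ones — the simplest contract for
full-length receptor pairs. Tie-breaking in the traceback is fixed
(substitution over gap-in-target over gap-in-backbone, applied at every
cell), which makes outputs bit-stable across platforms. Correctness is
checked two independent ways in the tests: exhaustive enumeration of all
alignments for short sequences, and score agreement with
`Biostrings::pairwiseAlignment()` (whose per-gap cost `open' + L·extend`
maps to ours with `open' = open − extend`).

Cut-site projection uses a single boundary function: for the boundary after
backbone residue *e*, the projected target boundary is the largest target
index aligned in any column up to and including *e*'s column. When the
target is gapped at a boundary column this automatically shifts the
boundary to the nearest non-gap column toward the preceding segment's
interior, and target insertions between segments attach to the preceding
segment. Because the function is monotone, projected segments always tile
the target exactly; a segment whose projection is empty raises the
collapse error instead. With random unrelated toy receptors a collapse of
a short loop is occasionally genuine (no homologous residues survive in
the alignment), which is why the coverage property is asserted conditional
on a successful projection.

## Back-translation

`back_translate()` produces DNA whose translation under the standard
genetic code reproduces the protein exactly — the round trip is the tested
contract. `most_frequent` mode is deterministic (ties between equally
frequent codons break alphabetically); `weighted` mode samples codons
proportionally to usage and is deterministic given its seed. The shipped
table is human codon-usage fractions renormalized so each amino acid sums
to exactly 1; the loader validates any user table against the genetic code
and the sum invariant (tolerance 1e-9).

## Assay quantification

**Normalization.** Each well is divided by the mean of its first
`baseline_reads` reads (default 3, matching the three pre-activation
luminescence measurements of the assay protocol), making the baseline mean
exactly 1. The RLU maximum is the raw post-stimulus maximum of the
normalized trace: whether published maxima use the whole post-stimulus
window or a fixed interval is not stated anywhere we could verify, so the
whole window is used and an optional smoothing window exists but defaults
to off. Normalization is scale-invariant by construction (property-tested).

**Dose–response.** The 4PL model
`r(d) = bottom + (top − bottom)/(1 + (EC50/d)^hill)` is fitted by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Initialization is
deterministic — `bottom = min`, `top = max`, EC50 at the dose whose mean
response is nearest the half-maximum, `hill = 1` — with EC50 bounded in
`[min(dose)/10, max(dose)·10]`, which is robust on monotone data and never
depends on random starts. The identity `r(EC50) = (top + bottom)/2` holds
for every fit by construction and is asserted to 1e-9. On noiseless
synthetic data all four parameters are recovered to ≤1% across an
EC50 × hill grid spanning two orders of magnitude.

With 5% Gaussian noise the informative question is the sampling design: a
4-parameter curve fitted to five single wells is underdetermined (median
EC50 error around 25% in our simulations). The assays this package
supports run technical duplicates with at least three independent trials,
so the simulated study conditions use duplicates over a seven-level dose
series (the `simulate_plate()` default, median EC50 error ≈13%) and six
wells per level for the light-intensity curve, whose fitted half-maximal
intensity lands at ≈50 µW/cm².

**Action spectra** average per-well RLU maxima by activation wavelength;
the peak is the smallest wavelength achieving the maximum mean, a
deterministic tie-break that matters only for flat profiles. **BRET2**
ratios are acceptor (GFP2) over donor (RLuc8) per read, with the ratio
change defined against the mean of the first `baseline_reads` reads, so
the corrected baseline is 0 by construction; a non-positive donor read is
an error because the ratio is then undefined.

## Behavior and imaging metrics

The indices are exactly their defining ratios: preference
`(n_odor − n_blank)/n_total` (mid-zone animals count toward the total but
neither side), learning index `(Pref_paired − Pref_unpaired)/2`,
performance index `(n_CS+ − n_CS−)/n_total` with the reciprocal pair
(odors interchanged as CS+) averaged when supplied. All are antisymmetric
under label swap, which the suite fuzzes. Rolling contingencies are
summarized as a fraction with a **Wilson** score interval — unlike the Wald
interval it behaves at small n and at 0 or 1, where escape-response data
actually live.

Locomotion summaries use unsmoothed centroid displacement between
consecutive frames times the frame rate (default 10 frames/s) and the sum
of absolute bending angles, over the first 30 s by default. Bending angles
are treated as unsigned because the sign convention of tracker output
varies; this is a documented assumption. Summaries are invariant under
rigid translation of the coordinates.

ΔF/F uses `F0 =` mean of the first `baseline_frames` frames (default 95,
the confocal protocol; pass 50 for the intact-larva two-photon variant),
`dff = (F − F0)/F0`, and `dff_max` as the post-stimulus maximum. The
computation is invariant under scaling the whole trace, and a non-positive
baseline is an error.

## What the synthetic generators emulate — and what they do not

Every generator is a pure function of its parameters and seed
(`withr::with_seed`; no process-global RNG state), and generated objects
always satisfy the invariants of the types they instantiate.

* `make_toy_gpcr()` draws TM segments from a hydrophobic-biased pool
  (A, C, F, G, I, L, M, S, T, V, W, Y) and loops from the full 20-letter
  alphabet, so alignments of toy receptors concentrate their reliable
  columns in the TMs, as real topologies do. Toy receptors have no
  conserved motifs, no disulfides and no real homology, so design tests on
  them exercise the cut-and-stitch machinery, not biological plausibility
  of any particular chimera.
* `simulate_plate()` puts a 4PL fold-change (default bottom 1, top 6,
  EC50 50, hill 1 over a 1–1000 nM series) on a flat baseline of 1000
  counts with 5% multiplicative Gaussian noise (reflected at zero),
  technical duplicates per dose. Real traces have kinetics — rise and decay
  within the read window — which the flat post-stimulus plateau ignores;
  consequently the tests validate normalization and fitting, not kinetic
  modeling.
* `simulate_fluorescence()` uses an instantaneous rise to `peak_dff`
  followed by exponential decay (default τ = 10 s at 7.5 frames/s,
  600 frames, 95 baseline frames), so the noiseless peak is recovered
  exactly; real indicators have finite rise times.
* `simulate_behavior_counts()` is a seeded multinomial over
  (odor, blank, middle); `simulate_tracks()` is a constant-speed
  random-heading walk with Gaussian bending. Neither models thigmotaxis,
  collisions or stimulus-locked kinematics.

Passing tests therefore demonstrate that the formulas and algorithms are
implemented exactly and behave stably under realistic noise — not that any
particular wet-lab result is reproduced, since those depend on cells and
animals.

## Problem sizes and numerical choices

The shipped test suite and the acceptance script size their simulations to
run comfortably on a laptop: 200 toy receptors for the identity round
trip, 20 backbone/target pairs for V2 conformance, a few thousand short
sequence pairs against the exhaustive alignment oracle (all pairs up to
length 2 plus a seeded sample up to length 5), 1,000 random proteins for
the back-translation round trip, and 100 Monte-Carlo replicates for noisy
EC50 recovery. Integer substitution scores make alignment score equality
exact; 4PL assertions use the tolerances stated above; everything else is
exact arithmetic.

## Known limitations

* The shipped backbone topology (and its rhodopsin-like example sequence,
  explicitly labelled synthetic) is an implementer-provided stand-in; real
  designs should supply the user's own backbone FASTA and topology TSV.
* The internal aligner is pairwise; reproducing a specific published
  chimera built on a multiple alignment may require importing that
  alignment.
* Default offsets (`proximal_tm_offset = 2`, `cterm_cut_shift = 8`) are
  documented assumptions, not published constants; conformance to a
  specific published chimera sequence should pin them explicitly.
* Statistical comparison between experimental groups (ANOVA, rank tests,
  multiple-comparison corrections) is deliberately out of scope; standard
  tools already do this on the tidy outputs.
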