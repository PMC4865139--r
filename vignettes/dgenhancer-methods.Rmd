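---
title: "Methods: ΔG-guided element discovery and oligo design in 5'UTRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dG-guided element discovery and oligo design in 5'UTRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgenhancer)
```

## The problem

Initiation is the rate-limiting step of translation, and stable secondary
structure in a 5' untranslated region (5'UTR) slows it down.  Empirically,
the relative translation efficiency of a reporter behind different 5'UTR
variants falls off exponentially with the leader's Gibbs folding energy
ΔG.  Structured leaders therefore carry *regulatory potential*: if a short
oligonucleotide (a "dGoligo") disrupts the inhibitory structure, or
releases a translation-enhancing element such as an IRES from a distant
pairing partner, translation can rise many-fold.

`dgenhancer` implements the in-silico half of that programme: find the
sub-sequences whose structure matters most (the scanning algorithm), model
the ΔG–efficiency relation, and design candidate oligos.

## Folding engines

The scanning algorithm only needs *some* consistent map from sequence to
folding energy; it is deliberately engine-agnostic.  Three engines are
provided.

**PAIRMAX** (`energy_model("pairmax")`) is a weighted
base-pair-maximisation model: every admissible pair contributes its
pair-class weight (defaults, kcal/mol: GC/CG −3, AU/UA −2, GU/UG −1) and
loops are free.  It is fast, fully transparent, and ideal for exhaustive
verification.

**NN** (`energy_model("nn")`) is a simplified nearest-neighbor
thermodynamic model: helices are scored by stacking energies between
adjacent pairs, loops by size-dependent initiation penalties with
logarithmic extrapolation (coefficient 1.75·R·T ≈ 1.079 kcal/mol at 37 °C)
beyond the tabulated range, and multiloops by an affine term
(offset 3.4, +0.4 per branch, 0.0 per unpaired nucleotide).  The parameter
file (`inst/extdata/nn_params.yaml`) carries Turner-like free energies at
37 °C.  Deliberate simplifications, each standard in teaching
implementations and documented here so the numbers are interpreted
correctly: no dangling-end or coaxial-stacking terms, no internal-loop
asymmetry penalty, no enthalpy/entropy decomposition (a single fixed
temperature), interior loops capped at 30 unpaired residues in the search.
Consequently NN energies are *comparable* to, but not numerically
interchangeable with, RNAstructure or ViennaRNA outputs; published ΔG
values from those engines are treated as given inputs, never as folding
targets.

**External** (`fold_external()`) adapts any engine with the RNAfold
contract (sequence in, dot-bracket + energy out) for users who want a
specific parameter set.

Shared admissibility rules: pair classes out of {AU, UA, GC, CG, GU, UG};
hairpin loops of at least `min_hairpin_loop = 3` unpaired residues; and an
optional no-lone-pair constraint (default: lone pairs allowed in PAIRMAX,
disallowed in NN, the common practice).  The no-lone-pair constraint is
enforced *exactly* by a helix decomposition: every helix has at least two
stacked pairs, and the innermost pair of a helix closes a hairpin, bulge,
internal loop or multiloop.  This matters for verification — the
exhaustive enumeration oracle (`enumerate_structures()`, refusal above 14
nt) applies the same structural filter, so the dynamic program and the
oracle agree to machine precision rather than approximately.

Determinism: ties in the traceback are broken by a fixed
branch-preference order under which the 5'-most pair opens as early as
possible; two identical calls return identical structures, not merely
equal energies.  The reference state is the open chain at 0 kcal/mol, so
reported ΔG is never positive.

## The scanning algorithm

For a UTR of length L, all 3L single-nucleotide substitutions are folded
and each position scored as

> s_i = mean over the three non-wild-type bases b of
> |ΔG(mutant i→b) − ΔG(wild type)|.

The mean runs over the three *non*-wild-type bases only; including the
identity substitution would add a guaranteed zero and simply rescale the
profile.  Absolute values are used because both stabilising and
destabilising substitutions indicate that the position participates in
structure; a signed mode (`aggregate = "signed"`) is exposed for
exploration.

The raw profile is smoothed by a sliding arithmetic mean over
`window = 6` consecutive positions ("signal"), using the valid-window
convention: no padding is invented at the edges, so the signal has
L − window + 1 entries and the window starting at position j covers raw
positions j…j+5.  For display the signal is min–max rescaled to 0–100
("signal intensity"); a constant signal maps to all zeros by convention,
and `scaling = "none"` / `"zscore"` are available.  The window of 6 is the
method's published operating point; whether the original smoothing ran
over 6 positions or 6 mutant sequences is not recoverable, so the
6-position reading is the default and the window is a plain argument.

Cost: at most 3L folds (identical mutants are impossible, so no caching
is needed beyond building the engine tables once per scan).  A 200-nt UTR
scans in a few seconds with either built-in engine on one CPU.

## Element calling

`call_elements()` thresholds the signal at a percentile of its
distribution (default 90), groups above-threshold windows into runs, and
merges runs whose *raw-coordinate footprints* (window start to
start + window − 1) are separated by at most `merge_gap` nucleotides
(default: one window).  Footprint-based merging is deliberate: a hairpin's
two arms produce twin signal peaks separated by the loop's dip, and
measuring the gap between footprints rather than window indices lets a
single window-width bridge the loop, so one physical stem-loop yields one
element rather than two.  Each merged run becomes an element spanning the
footprint of its windows; the top `max_elements` (default 3, matching the
e1–e3 reporting style) are returned labelled `e1, e2, …` by descending
peak signal.

The percentile should match the search: the default 90 keeps ~10% of
windows and is appropriate for nominating the top elements of one long
UTR.  When a fixed number k of elements is expected to cover a fraction f
of the sequence (e.g. two 26-nt stem-loops in 120 nt, f ≈ 0.4), the
threshold must admit at least that coverage — percentile ≤ 100(1 − f) —
otherwise the stronger element monopolises the admitted windows.  The
two-stem analyses in the test-suite therefore use percentile 75 with
`max_elements = 2`.

A constant signal (e.g. a homopolymer UTR) has no maxima: the caller
reports no elements and says so.

## The efficiency model

Relative translation efficiency y (% of an unstructured control leader)
versus folding energy X (kcal/mol) is modelled as y = a·e^(b·X).  Fitting
is ordinary least squares of ln y on X — a = exp(intercept), b = slope —
and r² is reported on that log-linear scale, matching how the relation was
originally analysed; no weighted or intercept-free variants are offered.
Records with non-positive efficiency are rejected by name (the log is
taken), and fewer than two distinct X values is a degenerate fit.

Two published fits for the TRβ1 5'UTR variant series ship as presets,
`trb1_primary` (a = 127.29, b = 0.0248) and `trb1_alternate` (a = 140.46,
b = 0.0307).  The source reports both without adjudicating, so the package
hard-codes neither; both are available and the choice is the user's.

*Translational regulatory potential* is the ratio of a reference
efficiency to a variant's lower efficiency — the headroom an oligo could
release.  On model predictions it has the closed form
e^(b·(X_ref − X_var)), independent of a.  The measured basal efficiencies
of the weakly and strongly folded variants (24.09% and 4.03% of control)
give 5.98; the published 5.96 was computed from unrounded assay means, so
agreement is expected within 1%, not exactly.

Properties the tests enforce: scale equivariance (rescaling efficiencies
rescales a only), the shift law (X → X + c multiplies a by e^(−bc)),
strict monotonicity of predictions for b > 0, and exact recovery of
generating parameters from noiseless data.

## Oligo design

For a called element the designer emits up to four categories:

* **sense** — the element subsequence itself; binds *distant* sequences
  that fold with the element, releasing it;
* **antisense** — the reverse complement; binds the element directly;
* **miR-like** (sense or antisense parent) — a 2–3-nt insertion after
  residue ⌊n/2⌋ of the parent.  On binding, the insertion loops out,
  mimicking a metazoan microRNA duplex.  The inserted base repeats the
  base least complementary (Watson–Crick or wobble) to the two target
  residues flanking the insertion point, ties resolved in A < C < G < U
  order, so the loop cannot accidentally pair.  "The middle" is fixed at
  ⌊n/2⌋ because no more precise convention is recoverable; the insertion
  length defaults to 3 (the published oligos are described both as 2–3 nt
  and as 3 nt; both are supported).
* **scrambled** — a seeded Fisher–Yates shuffle of a parent, redrawn until
  its longest perfectly complementary run against the *full* target UTR is
  below `max_run = 7`; composition and length are preserved exactly and
  the result is reproducible from (parent, seed).  Homopolymer parents are
  flagged degenerate (every shuffle is the parent).

Chemistry is annotation plus lettering: `dna` emits T, `2ome`
(2'-O-methyl RNA, the nuclease-resistant chemistry for work in cells)
emits U.  GC% and a Wallace-rule Tm (2·(A+T) + 4·(G+C)) are attached as
rough, clearly-labelled annotations only.

`hybridization_report()` scans every gapless antiparallel alignment of an
oligo against a target and reports the alignment with the most
Watson–Crick matches (ties towards more G:U appositions, then the 5'-most
offset), the G:U count at that alignment, and the globally longest perfect
complementary run.  G:U appositions are true wobble pairs only for RNA
chemistry; for DNA oligos they are reported under the same column but are
not base pairs.  The report is the in-silico analogue of a binding assay:
it checks construction invariants (a miR-like oligo shows one flank-length
run; removing its insertion restores the full-length run) and drives the
scrambled-control rejection bound.

## The synthetic-data generator

`generate_fixture_utr()` emulates the one property of real 5'UTRs the
scanning method relies on: a thermodynamically dominant structural element
inside an otherwise weakly folded leader.  Background residues are drawn
i.i.d. at GC 0.4 (AU-rich, like a weakly folded leader); each planted
stem-loop has exact reverse-complement arms drawn at GC 0.75 (10 bp stem,
4-nt loop by default), centred in equal-width blocks when several stems
are planted.  Ground-truth coordinates are returned, generation is
bit-reproducible per seed, and the caller's RNG state is untouched.

What the generator does *not* emulate: real 5'UTRs have correlated
composition, uORFs and start codons with sequence-level (not
structure-level) function, IRESs whose activity is not reducible to ΔG,
pseudoknots, and long-range tertiary contacts.  Passing the planted-element
tests therefore demonstrates that the scanner localises
*thermodynamically* dominant elements under the stated engines — it does
not certify that every functional element in a real UTR will be found
(ΔG-independent elements are explicitly invisible to this method), nor
that called elements are functional.

Fixture-based checks in the test-suite use 60-nt single-stem and 120-nt
two-stem sequences with the NN engine, sizes at which the planted helix
(≈ −20 kcal/mol) clearly dominates the background (median ≈ −4 kcal/mol);
the stem-vs-shuffled-arm contrast and the localization rates are evaluated
over 10–20 seeds each.  The oracle-equivalence checks run 200 random
8–14-nt sequences per engine mode, the scale at which exhaustive
enumeration is complete.

## Numerical choices and degenerate inputs

* Energies are doubles in kcal/mol; DP-vs-oracle and scorer-vs-DP
  comparisons use an absolute tolerance of 1e-9 (values are sums of
  table entries; observed discrepancies are at machine precision).
* Tie-breaks: traceback branch order (above); element ties at equal peak
  signal rank by earlier start; insertion-base ties by alphabet order.
* The empty structure is always admissible, so ΔG ≤ 0 and a sequence with
  no admissible pair folds to the open chain at exactly 0.
* Constant perturbation profiles scale to 0 (min–max) and yield no
  elements; homopolymer scramble parents are degenerate but accepted when
  they meet the binding bound; an unsatisfiable bound raises an
  exhaustion error suggesting a larger `max_run`.
* Coordinates are 1-based inclusive everywhere a user sees them, except
  BED export (0-based half-open).  FASTA ids are the join key across all
  outputs.

## Known limitations

* No suboptimal ensembles, partition function, base-pair probabilities or
  pseudoknots; single-structure MFE only.
* NN parameters are Turner-like but simplified (above); do not compare
  absolute energies across engines.
* The scanner scores structural involvement, not function; ΔG-independent
  regulatory elements (many IRESs, uORFs) require orthogonal evidence.
* Oligo design does not model RNase-H activity, delivery, off-target
  binding across a transcriptome, or duplex thermodynamics of the
  oligo:target hybrid.
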