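# dgenhancer

Translation of an mRNA is throttled by the secondary structure of its 5'
untranslated region (5'UTR): the more stably folded the leader (the more
negative its Gibbs folding energy ΔG), the less efficiently the downstream
open reading frame is translated.  Strongly folded 5'UTRs, such as the
alternatively spliced leaders of the *THRB* and *CDKN2A* tumor suppressors,
therefore hold a large *translational regulatory potential*: headroom that
short synthetic oligonucleotides ("dGoligos") can release by disrupting the
inhibitory structure.

`dgenhancer` is an R toolkit for this workflow, aimed at molecular
biologists designing translation-enhancing oligos against structured
5'UTRs:

1. **Scan** a 5'UTR by in-silico saturation single-nucleotide substitution.
   Each position *i* is scored by the mean absolute change in folding
   energy over the three possible substitutions,

   s_i = (1/3) Σ_b |ΔG(mutant i→b) − ΔG(wild type)|,

   smoothed by a sliding mean over 6 consecutive positions and rescaled to
   a 0–100 "signal intensity".  Positions where substitutions perturb ΔG
   most mark structure-forming, potentially *cis*-regulatory elements.
2. **Call elements** (`e1`, `e2`, …) at signal maxima and export them as
   TSV/BED.
3. **Model translation efficiency** as an exponential function of folding
   energy, y = a·e^(b·X) (y = efficiency in % of an unstructured control,
   X = ΔG in kcal/mol), fitted by ordinary least squares on the log scale,
   and compute regulatory potentials as efficiency ratios.
4. **Design dGoligos** against called elements: sense, antisense,
   microRNA-like (2–3-nt central insertion) and scrambled controls, in DNA
   or 2'-O-methyl RNA chemistry, with in-silico hybridization reports
   (Watson–Crick matches, G:U wobble appositions, longest complementary
   run).

Folding uses two built-in minimum-free-energy engines — a weighted
base-pair-maximisation model (`pairmax`) and a simplified nearest-neighbor
thermodynamic model (`nn`) — both verified exactly against an exhaustive
structure-enumeration oracle, plus an adapter for any ViennaRNA-compatible
external engine.  See the methods vignette
(`vignettes/dgenhancer-methods.Rmd`) for the models, parameters and design
choices.

## Worked example

```r
library(dgenhancer)

# a synthetic 60-nt UTR with one planted GC-rich hairpin (truth recorded)
fx <- generate_fixture_utr(length = 60, stem_len = 10, loop_len = 6, seed = 4)
fx$truth
#>    stem arm1_start arm1_end loop_start loop_end arm2_start arm2_end
#> 1     1         17       26         27       32         33       42

model <- energy_model("nn")
mfe_fold(fx$utr, model)
#> <fold_result: fixture_s4 (builtin-nn)>
#>   ................(((((((((((....))))))))))).....(((((...)))))
#>   dG = -17.30 kcal/mol

profile <- scan_utr(fx$utr, model)          # 3 x 60 mutant folds
elements <- call_elements(profile)
elements
#>   seq_id     start   end peak_signal rank_label
#> 1 fixture_s4    34    41        7.23 e1
#> 2 fixture_s4    18    25        7.21 e2
```

The two called elements are the two arms of the planted stem: exactly the
positions where a substitution breaks a base pair and shifts ΔG the most.
Designing oligos against the top element:

```r
design_oligos(fx$utr, elements[1, ],
              categories = c("sense", "antisense", "mir_like_antisense"),
              chemistry = "2ome")
#>   name         category           residues    target  gc_pct
#> 1 dG_e1_s      sense              ACGCGUAG    34-41     62.5
#> 2 dG_e1_as     antisense          CUACGCGU    34-41     62.5
#> 3 dG_e1_mir_as mir_like_antisense CUACAAAGCGU 34-41     45.5
```

The sense oligo copies the element (to decoy distant sequences folding with
it), the antisense oligo is its reverse complement (to bind it directly),
and the miR-like variant carries a central `AAA` insertion that loops out
on binding.  `make_scrambled()` adds a composition-preserving,
binding-bounded control.

The published efficiency model for the TRβ1 5'UTR variant series ships as a
preset:

```r
m <- preset_efficiency_model("trb1_primary")   # y = 127.29 e^(0.0248 X)
predict_efficiency(m, -69.0)                   # weakly folded variant A
#> [1] 22.99
predicted_potential(m, -69.0, -128.9)          # A vs the most folded F
#> [1] 4.42
regulatory_potential(24.09, 4.03)              # measured basal efficiencies
#> [1] 5.98
```

A command-line surface (`exec/dgenhancer`) exposes the same pipeline as
`scan`, `elements`, `design`, `model fit|predict|potential`, `fixture` and
`repro` subcommands.

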