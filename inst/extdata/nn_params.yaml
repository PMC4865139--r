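# Nearest-neighbor free-energy parameters (kcal/mol, 37 C) for the built-in
# NN folding engine.  Turner-like values: Watson-Crick and G:U wobble stacks,
# loop-size penalties with logarithmic extrapolation beyond the tabulated
# range, and an affine multiloop model.  No dangling-end, coaxial-stacking or
# internal-loop-asymmetry terms.
#
# Stacks are keyed by the outer pair (5' base first) then the inner pair the
# helix continues with: outer a-b enclosing inner c-d reads 5'-a c ... d b-3'.
stacks:
  AU: {AU: -0.9, CG: -2.2, GC: -2.1, GU: -0.6, UA: -1.1, UG: -1.4}
  CG: {AU: -2.1, CG: -3.3, GC: -2.4, GU: -1.4, UA: -2.1, UG: -2.1}
  GC: {AU: -2.4, CG: -3.4, GC: -3.3, GU: -1.5, UA: -2.2, UG: -2.5}
  GU: {AU: -1.3, CG: -2.5, GC: -2.1, GU: -0.5, UA: -1.4, UG: 1.3}
  UA: {AU: -1.3, CG: -2.4, GC: -2.1, GU: -1.0, UA: -0.9, UG: -1.3}
  UG: {AU: -1.0, CG: -1.5, GC: -1.4, GU: 0.3, UA: -0.6, UG: -0.5}
# Loop initiation penalties by number of unpaired residues in the loop.
hairpin:
  3: 5.4
  4: 5.6
  5: 5.7
  6: 5.4
  7: 6.0
  8: 5.5
  9: 6.4
bulge:
  1: 3.8
  2: 2.8
  3: 3.2
  4: 3.6
  5: 4.0
  6: 4.4
internal:
  2: 4.1
  3: 5.1
  4: 4.9
  5: 5.3
  6: 5.7
# Beyond the largest tabulated size s_max:
#   penalty(s) = penalty(s_max) + coef * ln(s / s_max),  coef = 1.75 * R * T
extrapolation:
  coef: 1.079
# Affine multiloop: offset + branch * (enclosed helices) + unpaired * (loop nt)
multiloop:
  offset: 3.4
  branch: 0.4
  unpaired: 0.0
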