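# shared fixtures built in code

rand_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

unit_pairmax <- function(...) {
  energy_model("pairmax",
               pair_weights = c(AU = -1, UA = -1, GC = -1, CG = -1,
                                GU = -1, UG = -1), ...)
}

# the four engine configurations exercised by the oracle
all_engine_models <- function() {
  list(
    pairmax_lone = energy_model("pairmax"),
    pairmax_nolone = energy_model("pairmax", lone_pair_allowed = FALSE),
    nn_nolone = energy_model("nn"),
    nn_lone = energy_model("nn", lone_pair_allowed = TRUE)
  )
}

rna_revcomp <- function(s) reverse_complement(s, "RNA")

# fixed non-repetitive 20-mer used by the oligo construction tests
rand_rna_fixed20 <- function() "AUGGCAUCCGAACUGUCAGU"
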