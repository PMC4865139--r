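#' Generate a synthetic 5'UTR with planted hairpins
#'
#' Test substrate emulating the structural contrast between weakly and
#' strongly folded 5'UTRs: an i.i.d. background of tunable GC content with
#' one or more planted stem-loops whose arms are exact reverse complements.
#' The defaults describe the regime the scanning method is meant for -- an
#' AU-rich, weakly structured leader (GC 40%) carrying one thermodynamically
#' dominant GC-rich hairpin (10 bp stem, 75% GC arms, 4-nt loop) -- so that
#' folding is driven by the planted element rather than the background.
#' Generation is deterministic per seed and the caller's RNG state is left
#' untouched.
#'
#' @param length Total sequence length (default 120 nt).
#' @param stem_len Paired stem length in bp (default 10).
#' @param loop_len Loop length between the arms (default 4 nt).
#' @param n_stems Number of planted stem-loops (default 1; 0 gives a
#'   structure-poor background sequence).
#' @param gc_bias Background GC fraction (default 0.4).
#' @param arm_gc GC fraction of the planted arms (default 0.75).
#' @param seed Integer seed.
#' @return A list with `utr` (one-row sequence tibble) and `truth` (a tibble
#'   of planted-feature coordinates: `stem`, `arm1_start`, `arm1_end`,
#'   `loop_start`, `loop_end`, `arm2_start`, `arm2_end`) plus the generator
#'   settings as attributes.
#' @examples
#' fx <- generate_fixture_utr(length = 60, seed = 1)
#' fx$truth
#' @export
generate_fixture_utr <- function(length = 120L, stem_len = 10L, loop_len = 4L,
                                 n_stems = 1L, gc_bias = 0.4, arm_gc = 0.75,
                                 seed = 1L) {
  length <- as.integer(length); stem_len <- as.integer(stem_len)
  loop_len <- as.integer(loop_len); n_stems <- as.integer(n_stems)
  feat_len <- 2L * stem_len + loop_len
  if (n_stems > 0L && n_stems * (feat_len + 2L) > length) {
    abort("planted features do not fit within the requested length",
          class = "dg_config_error")
  }
  draw <- function(n, gc) {
    sample(BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }

  drawn <- with_preserved_rng(seed, {
    chars <- draw(length, gc_bias)
    truth <- tibble(stem = integer(), arm1_start = integer(),
                    arm1_end = integer(), loop_start = integer(),
                    loop_end = integer(), arm2_start = integer(),
                    arm2_end = integer())
    if (n_stems > 0L) {
      # centre one feature per equal-width block
      block <- length %/% n_stems
      rows <- vector("list", n_stems)
      for (k in seq_len(n_stems)) {
        offset <- (k - 1L) * block + max(1L, (block - feat_len) %/% 2L)
        arm1 <- draw(stem_len, arm_gc)
        arm2 <- strsplit(chartr("ACGU", "UGCA",
                                paste(rev(arm1), collapse = "")), "")[[1]]
        a1s <- offset; a1e <- offset + stem_len - 1L
        ls <- a1e + 1L; le <- a1e + loop_len
        a2s <- le + 1L; a2e <- le + stem_len
        chars[a1s:a1e] <- arm1
        chars[a2s:a2e] <- arm2
        rows[[k]] <- tibble(stem = k, arm1_start = a1s, arm1_end = a1e,
                            loop_start = ls, loop_end = le,
                            arm2_start = a2s, arm2_end = a2e)
      }
      truth <- dplyr::bind_rows(rows)
    }
    list(chars = chars, truth = truth)
  })
  chars <- drawn$chars
  truth <- drawn$truth

  utr <- utr_sequence(sprintf("fixture_s%d", seed), paste(chars, collapse = ""),
                      source_alphabet = "RNA")
  attr(truth, "seed") <- as.integer(seed)
  attr(truth, "gc_bias") <- gc_bias
  attr(truth, "arm_gc") <- arm_gc
  list(utr = utr, truth = truth)
}
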