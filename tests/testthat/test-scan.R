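test_that("smooth_profile is the plain valid-window sliding mean", {
  expect_equal(smooth_profile(rep(1, 6), 6), 1)
  expect_equal(smooth_profile(c(0, 0, 0, 6, 0, 0, 0), 3), c(0, 2, 2, 2, 0))
  expect_equal(smooth_profile(c(3, 1), 2), 2)
  expect_error(smooth_profile(numeric(0), 1), class = "dg_config_error")
  expect_error(smooth_profile(c(1, 2), 3), class = "dg_config_error")
})

test_that("scan arithmetic is exact under a stub engine", {
  # stub: dG = -(number of G residues); mutating position i to G lowers dG
  # by 1, to anything else leaves it unchanged (wild type is G-free)
  stub <- function(res) -lengths(regmatches(res, gregexpr("G", res)))
  p <- scan_utr("AAUUCC", energy_model("pairmax"), window = 3, engine = stub)
  expect_equal(p$raw_ddg, rep(1 / 3, 6))        # |ddG| = 1 for 1 of 3 bases
  expect_equal(p$signal[1:4], rep(1 / 3, 4))
  expect_true(all(is.na(p$signal[5:6])))        # no full window at the tail
  expect_equal(p$wt_dg[1], 0)

  # constant perturbation: every mutant shifts dG by the same amount
  wt <- "AUGCAUGC"
  stub2 <- function(res) if (res == wt) 0 else -3
  p2 <- scan_utr(wt, energy_model("pairmax"), window = 4, engine = stub2)
  expect_equal(p2$raw_ddg, rep(3, 8))
  expect_equal(p2$signal[!is.na(p2$signal)], rep(3, 5))
  expect_equal(p2$signal_scaled[!is.na(p2$signal_scaled)], rep(0, 5)) # constant -> 0
})

test_that("a poly-A UTR yields an all-zero profile under the NN model", {
  # no single substitution can create a helix of two stacked pairs
  p <- scan_utr(strrep("A", 30), energy_model("nn"))
  expect_equal(p$raw_ddg, rep(0, 30))
  expect_equal(p$signal[!is.na(p$signal)], rep(0, 25))
  expect_message(els <- call_elements(p), "constant signal")
  expect_equal(nrow(els), 0L)
})

test_that("scanning is deterministic and the window bound is enforced", {
  m <- energy_model("pairmax")
  s <- "GGGGAAAACCCCAAAA"
  expect_identical(scan_utr(s, m), scan_utr(s, m))
  expect_error(scan_utr("AUGC", m, window = 6), class = "dg_config_error")
})

test_that("signal scaling reaches 100 at the maximum for non-constant signal", {
  fx <- generate_fixture_utr(length = 50, stem_len = 8, loop_len = 4, seed = 3)
  p <- scan_utr(fx$utr, energy_model("pairmax"))
  sc <- p$signal_scaled[!is.na(p$signal_scaled)]
  expect_equal(max(sc), 100)
  expect_gte(min(sc), 0)
})

test_that("element calling finds a single synthetic peak at exact coordinates", {
  # build a profile tibble directly: one clean plateau in the signal
  raw <- rep(0, 40); raw[18:23] <- 6
  sig <- smooth_profile(raw, 6)
  p <- tibble::tibble(
    seq_id = "s", pos = 1:40, wt_base = "A", raw_ddg = raw,
    signal = c(sig, rep(NA, 5)),
    signal_scaled = c(dgenhancer:::scale_signal(sig, "minmax"), rep(NA, 5)),
    wt_dg = -1
  )
  attr(p, "window") <- 6L
  class(p) <- c("perturbation_profile", class(p))

  els <- call_elements(p, threshold_percentile = 90, max_elements = 3)
  expect_equal(nrow(els), 1L)
  expect_equal(els$rank_label, "e1")
  # the argmax window footprint lies inside the called element
  am <- which.max(p$signal)
  expect_gte(am, els$start)
  expect_lte(am + 5, els$end)
  # coordinate consistency: every window inside the element is above threshold
  thr <- quantile(sig, 0.9)
  inside <- seq(els$start, els$end - 5)
  expect_true(all(sig[inside] >= thr))
})

test_that("element ranks are ordered by descending peak signal", {
  raw <- rep(0, 60); raw[10:15] <- 4; raw[40:45] <- 8
  sig <- smooth_profile(raw, 6)
  p <- tibble::tibble(seq_id = "s", pos = 1:60, wt_base = "A", raw_ddg = raw,
                      signal = c(sig, rep(NA, 5)),
                      signal_scaled = c(dgenhancer:::scale_signal(sig, "minmax"),
                                        rep(NA, 5)),
                      wt_dg = 0)
  attr(p, "window") <- 6L
  class(p) <- c("perturbation_profile", class(p))
  els <- call_elements(p, threshold_percentile = 80, max_elements = 3)
  expect_equal(nrow(els), 2L)
  expect_equal(els$rank_label, c("e1", "e2"))
  expect_true(els$peak_signal[1] > els$peak_signal[2])
  expect_true(els$start[1] > els$start[2]) # the stronger peak is the later one
})
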