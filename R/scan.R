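#' Saturation-substitution perturbation profile of a 5'UTR
#'
#' The core scanning step: every position of the UTR is substituted in
#' silico to each of the three non-wild-type bases, each mutant is folded,
#' and the position score is the mean absolute change in Gibbs folding
#' energy |ddG| over the three substitutions.  The per-position scores are
#' then smoothed with a sliding mean over `window` consecutive positions
#' (the "signal") and min-max rescaled to 0-100 ("signal intensity") for
#' display.  Positions where substitutions perturb the folding energy most
#' mark structure-forming, potentially translation-regulatory elements.
#'
#' @param utrs A sequence tibble (one row per UTR, see [utr_sequence()] /
#'   [read_utr_fasta()]) or a single sequence string.
#' @param model An [energy_model()] used to fold the wild type and all
#'   mutants.
#' @param window Smoothing window in positions (default 6).
#' @param scaling `"minmax"` (default; constant signal maps to all zeros),
#'   `"zscore"`, or `"none"` for the display scaling of the signal.
#' @param aggregate `"absolute"` (default): mean of |ddG|; `"signed"`:
#'   mean of ddG, for exploring the direction of perturbation.
#' @param engine Optional override of the folding engine: a function taking
#'   a residue string and returning a Gibbs energy in kcal/mol.  Defaults to
#'   [mfe_fold()] under `model`.  Mainly useful for testing the scanning
#'   arithmetic with a stub engine.
#'
#' @return A tibble of class `perturbation_profile` with one row per
#'   position: `seq_id`, `pos`, `wt_base`, `raw_ddg`, `signal` (the sliding
#'   mean whose window starts at `pos`; `NA` for the trailing positions
#'   without a full window), `signal_scaled`, and `wt_dg`.  The window and
#'   scaling are stored as attributes.
#' @examples
#' scan_utr("GGGGAAAACCCCAAAA", energy_model("pairmax"), window = 4)
#' @export
scan_utr <- function(utrs, model, window = 6L,
                     scaling = c("minmax", "zscore", "none"),
                     aggregate = c("absolute", "signed"),
                     engine = NULL) {
  scaling <- match.arg(scaling)
  aggregate <- match.arg(aggregate)
  if (is.character(utrs)) utrs <- as_utr_row(utrs)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) {
    abort("window must be a positive integer", class = "dg_config_error")
  }

  profiles <- lapply(seq_len(nrow(utrs)), function(r) {
    row <- utrs[r, ]
    L <- row$length
    if (window > L) {
      abort(sprintf("window %d exceeds sequence length %d for '%s'",
                    window, L, row$seq_id), class = "dg_config_error")
    }
    fold_one <- engine %||% local({
      payload <- model_payload(model, L)
      function(res) .fold_dp(encode_residues(res), payload)$delta_g
    })
    wt <- row$residues
    wt_dg <- fold_one(wt)
    bases_wt <- strsplit(wt, "")[[1]]
    raw <- vapply(seq_len(L), function(i) {
      others <- setdiff(BASES, bases_wt[i])
      ddg <- vapply(others, function(b) {
        mut <- wt
        substr(mut, i, i) <- b
        fold_one(mut) - wt_dg
      }, numeric(1))
      if (aggregate == "absolute") mean(abs(ddg)) else mean(ddg)
    }, numeric(1))
    signal <- c(smooth_profile(raw, window), rep(NA_real_, window - 1L))
    tibble(
      seq_id = row$seq_id, pos = seq_len(L), wt_base = bases_wt,
      raw_ddg = raw, signal = signal,
      signal_scaled = scale_signal(signal, scaling), wt_dg = wt_dg
    )
  })

  out <- dplyr::bind_rows(profiles)
  attr(out, "window") <- window
  attr(out, "scaling") <- scaling
  attr(out, "aggregate") <- aggregate
  class(out) <- c("perturbation_profile", class(out))
  out
}

scale_signal <- function(signal, scaling) {
  ok <- !is.na(signal)
  out <- rep(NA_real_, length(signal))
  x <- signal[ok]
  out[ok] <- switch(scaling,
    none = x,
    zscore = if (sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / sd(x),
    minmax = {
      rng <- range(x)
      if (diff(rng) == 0) rep(0, length(x)) else 100 * (x - rng[1]) / diff(rng)
    }
  )
  out
}

#' Sliding-mean smoothing of a per-position score vector
#'
#' Valid-window convention: output element `j` is the arithmetic mean of
#' `raw[j .. j + window - 1]`, so the output has `length(raw) - window + 1`
#' entries and no padding is invented at the edges.
#'
#' @param raw Numeric vector of per-position scores.
#' @param window Window length, at most `length(raw)`.
#' @return Numeric vector of windowed means.
#' @examples
#' smooth_profile(c(0, 0, 0, 6, 0, 0, 0), 3)
#' @export
smooth_profile <- function(raw, window) {
  if (length(raw) == 0L) {
    abort("raw profile is empty", class = "dg_config_error")
  }
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window > length(raw)) {
    abort("window must lie in 1..length(raw)", class = "dg_config_error")
  }
  cs <- cumsum(c(0, raw))
  (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
}

#' Call cis-regulatory elements from a perturbation profile
#'
#' Window positions whose signal reaches the given percentile of the signal
#' distribution are grouped into runs; runs separated by at most `merge_gap`
#' positions are merged; each run becomes an element spanning the full
#' nucleotide footprint of its windows.  The top `max_elements` elements by
#' peak signal are returned, labelled `e1`, `e2`, ... in descending peak
#' order.  A constant (e.g. all-zero) signal has no maxima and yields no
#' elements.
#'
#' @param profile A `perturbation_profile` tibble from [scan_utr()].
#' @param threshold_percentile Signal percentile above which window
#'   positions are considered element-supporting (default 90).
#' @param max_elements Maximum number of elements returned per sequence
#'   (default 3).
#' @param merge_gap Merge runs separated by at most this many positions;
#'   defaults to the profile's smoothing window.
#' @return A tibble with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `peak_signal`, and `rank_label`.
#' @export
call_elements <- function(profile, threshold_percentile = 90,
                          max_elements = 3L, merge_gap = NULL) {
  stopifnot(is.data.frame(profile))
  window <- attr(profile, "window") %||% 6L
  merge_gap <- as.integer(merge_gap %||% window)
  if (threshold_percentile < 0 || threshold_percentile > 100) {
    abort("threshold_percentile must be in [0, 100]", class = "dg_config_error")
  }

  per_seq <- lapply(split(profile, profile$seq_id), function(p) {
    p <- p[order(p$pos), ]
    sig <- p$signal[!is.na(p$signal)]
    if (length(sig) == 0L) return(NULL)
    if (diff(range(sig)) == 0) {
      inform(sprintf("constant signal for '%s': no elements called", p$seq_id[1]))
      return(NULL)
    }
    thr <- quantile(sig, threshold_percentile / 100, names = FALSE)
    hot <- which(sig >= thr)
    if (length(hot) == 0L) return(NULL)

    # each hot window covers raw positions [j, j + window - 1]; merge the
    # footprints whose raw-coordinate gap is <= merge_gap
    breaks <- which(diff(hot) - 1L > window - 1L + merge_gap)
    run_start <- hot[c(1L, breaks + 1L)]
    run_end <- hot[c(breaks, length(hot))]

    els <- lapply(seq_along(run_start), function(k) {
      win_hot <- hot[hot >= run_start[k] & hot <= run_end[k]]
      tibble(
        seq_id = p$seq_id[1],
        start = run_start[k],
        end = run_end[k] + window - 1L,
        peak_signal = max(sig[win_hot])
      )
    })
    dplyr::bind_rows(els)
  })

  out <- dplyr::bind_rows(per_seq)
  if (nrow(out) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  peak_signal = numeric(), rank_label = character()))
  }
  out <- out |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::arrange(dplyr::desc(.data$peak_signal), .data$start, .by_group = TRUE) |>
    dplyr::slice_head(n = max_elements) |>
    dplyr::mutate(rank_label = paste0("e", dplyr::row_number())) |>
    dplyr::ungroup()
  out
}
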