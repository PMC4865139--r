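#' Build a 5'UTR sequence record
#'
#' Normalises a nucleotide sequence into the internal RNA alphabet
#' (upper-case, `T` mapped to `U`) and records which alphabet it arrived in,
#' so that the original lettering can be reproduced on output.
#'
#' @param id Short sequence label (used as the join key across all outputs).
#' @param residues Nucleotide sequence over `A,C,G,T,U` (case-insensitive).
#' @param source_alphabet `"DNA"`, `"RNA"`, or `NULL` to infer from the
#'   letters (`T` present -> DNA, `U` present -> RNA, neither -> DNA).
#'
#' @return A one-row tibble with columns `seq_id`, `residues` (RNA
#'   alphabet), `length`, and `source_alphabet`.
#' @examples
#' utr_sequence("x", "ACGT")
#' @export
utr_sequence <- function(id, residues, source_alphabet = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  res <- toupper(as.character(residues))
  if (length(res) != 1L || !nzchar(res)) {
    abort("a UTR sequence needs at least one residue", class = "dg_alphabet_error")
  }
  bad <- gsub("[ACGTU]", "", res)
  if (nzchar(bad)) {
    abort(
      sprintf("invalid residue(s) '%s' in sequence '%s'",
              paste(unique(strsplit(bad, "")[[1]]), collapse = ","), id),
      class = "dg_alphabet_error"
    )
  }
  if (grepl("T", res) && grepl("U", res)) {
    abort(sprintf("sequence '%s' mixes T and U", id), class = "dg_alphabet_error")
  }
  alpha <- source_alphabet %||% if (grepl("U", res)) "RNA" else "DNA"
  alpha <- match.arg(toupper(alpha), c("DNA", "RNA"))
  tibble(
    seq_id = id,
    residues = chartr("T", "U", res),
    length = nchar(res),
    source_alphabet = alpha
  )
}

#' Convert residues between the DNA and RNA lettering
#'
#' @param residues Character vector of sequences.
#' @param to `"DNA"` (U -> T) or `"RNA"` (T -> U).
#' @return Character vector in the requested lettering.
#' @examples
#' convert_alphabet("AUGC", "DNA")
#' @export
convert_alphabet <- function(residues, to = c("RNA", "DNA")) {
  to <- match.arg(to)
  if (to == "RNA") chartr("Tt", "Uu", residues) else chartr("Uu", "Tt", residues)
}

# Accept either a one-row sequence tibble or a bare string; returns the row.
as_utr_row <- function(seq, id = "seq") {
  if (is.character(seq) && length(seq) == 1L) {
    return(utr_sequence(id, seq))
  }
  if (is.data.frame(seq)) {
    if (nrow(seq) != 1L) {
      abort("expected a single sequence (one-row tibble)", class = "dg_config_error")
    }
    need <- c("seq_id", "residues")
    if (!all(need %in% names(seq))) {
      abort("sequence tibble needs columns seq_id, residues", class = "dg_config_error")
    }
    return(utr_sequence(seq$seq_id, seq$residues,
                        if ("source_alphabet" %in% names(seq)) seq$source_alphabet else NULL))
  }
  abort("cannot interpret input as a UTR sequence", class = "dg_config_error")
}

# integer codes A=0, C=1, G=2, U=3 for the folding kernel
encode_residues <- function(residues) {
  codes <- match(strsplit(residues, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(codes)) abort("invalid residue in sequence", class = "dg_alphabet_error")
  codes
}

#' Substitute a single base
#'
#' Returns a copy of the sequence differing at exactly one position (or an
#' identical copy when `base` equals the wild-type residue).  The input is
#' never modified.
#'
#' @param seq A one-row sequence tibble (see [utr_sequence()]) or a string.
#' @param pos 1-based position.
#' @param base Replacement residue in `{A,C,G,U}` (or `T`, mapped to `U`).
#' @return A one-row sequence tibble.
#' @examples
#' mutate_base("AUGC", 2, "A")$residues
#' @export
mutate_base <- function(seq, pos, base) {
  row <- as_utr_row(seq)
  pos <- as.integer(pos)
  if (length(pos) != 1L || is.na(pos) || pos < 1L || pos > row$length) {
    abort(sprintf("position %s outside 1..%d", paste(pos, collapse = ","), row$length),
          class = "dg_bounds_error")
  }
  base <- chartr("Tt", "Uu", toupper(base))
  if (!base %in% c("A", "C", "G", "U")) {
    abort(sprintf("invalid replacement base '%s'", base), class = "dg_alphabet_error")
  }
  res <- row$residues
  substr(res, pos, pos) <- base
  out <- row
  out$residues <- res
  out
}
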