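WC_PARTNER <- c(A = "U", U = "A", G = "C", C = "G")

pairs_with <- function(x, y) {
  # Watson-Crick or G:U wobble apposition on RNA letters
  (WC_PARTNER[[x]] == y) || (x == "G" && y == "U") || (x == "U" && y == "G")
}

#' Reverse complement of a nucleotide sequence
#'
#' @param residues Character vector of sequences.
#' @param alphabet `"DNA"` or `"RNA"`; inferred from the letters when `NULL`
#'   (`U` present -> RNA, otherwise DNA).
#' @return Character vector of reverse complements in the same alphabet.
#' @examples
#' reverse_complement("AUGC")
#' @export
reverse_complement <- function(residues, alphabet = NULL) {
  vapply(residues, function(s) {
    s <- toupper(s)
    alpha <- alphabet %||% if (grepl("U", s)) "RNA" else "DNA"
    alpha <- match.arg(toupper(alpha), c("DNA", "RNA"))
    if (alpha == "RNA") {
      if (grepl("[^ACGU]", s)) {
        abort(sprintf("invalid RNA residue in '%s'", s), class = "dg_alphabet_error")
      }
      as.character(Biostrings::reverseComplement(Biostrings::RNAString(s)))
    } else {
      if (grepl("[^ACGT]", s)) {
        abort(sprintf("invalid DNA residue in '%s'", s), class = "dg_alphabet_error")
      }
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
  }, character(1), USE.NAMES = FALSE)
}

oligo_chemistry_alphabet <- function(chemistry) {
  switch(chemistry, dna = "DNA", `2ome` = "RNA",
         abort("chemistry must be 'dna' or '2ome'", class = "dg_config_error"))
}

oligo_annotations <- function(residues) {
  chars <- strsplit(chartr("T", "U", residues), "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  au <- sum(chars %in% c("A", "U"))
  list(gc_pct = 100 * gc / length(chars), tm_wallace = 2 * au + 4 * gc)
}

# base for a miR-like insertion: the first base (A < C < G < U) that neither
# Watson-Crick- nor wobble-pairs with the partner residues flanking the
# insertion point, so the insertion is guaranteed to loop out.
insertion_base <- function(parent_rna, insert_after) {
  chars <- strsplit(parent_rna, "")[[1]]
  apposed <- unique(vapply(
    c(insert_after, min(insert_after + 1L, length(chars))),
    function(k) WC_PARTNER[[chars[k]]], character(1)
  ))
  score <- vapply(BASES, function(b)
    sum(vapply(apposed, function(t) pairs_with(b, t), logical(1))), integer(1))
  BASES[which.min(score)] # least-complementary base; ties resolve A < C < G < U
}

#' Design dGoligos against a cis-regulatory element
#'
#' Generates translation-modulating oligonucleotides for a called element:
#' the sense oligo equals the element subsequence (it decoys distant
#' sequences that fold with the element), the antisense oligo is its reverse
#' complement (it binds the element directly), and the microRNA-like
#' variants carry a short central insertion that loops out upon binding,
#' mimicking a metazoan microRNA duplex.  Sequences are emitted in the
#' requested chemistry's lettering (DNA uses `T`, 2'-O-methyl RNA uses `U`).
#'
#' @param utr A one-row sequence tibble or string (the target UTR).
#' @param elements An element tibble from [call_elements()] (columns
#'   `seq_id`, `start`, `end`, `rank_label`), or a similar hand-made table.
#' @param categories Any of `"sense"`, `"antisense"`, `"mir_like_sense"`,
#'   `"mir_like_antisense"`.
#' @param chemistry `"dna"` (synthesis as DNA) or `"2ome"` (nuclease-
#'   resistant 2'-O-methyl RNA for work in cells).
#' @param insertion_len Length of the miR-like central insertion, 2 or 3
#'   (default 3).  Inserted after residue `floor(n/2)` of the parent.
#' @return A tibble with one row per oligo: `name`, `category`, `chemistry`,
#'   `residues`, `target_seq_id`, `target_start`, `target_end`,
#'   `insertion_pos`, `insertion_seq`, `length`, `gc_pct`, `tm_wallace`.
#' @examples
#' el <- tibble::tibble(seq_id = "u", start = 3, end = 11, rank_label = "e1")
#' design_oligos("GGAUGGCAUCCAA", el, categories = c("sense", "antisense"))
#' @export
design_oligos <- function(utr, elements,
                          categories = c("sense", "antisense",
                                         "mir_like_sense", "mir_like_antisense"),
                          chemistry = c("dna", "2ome"),
                          insertion_len = 3L) {
  chemistry <- match.arg(chemistry)
  categories <- match.arg(categories, several.ok = TRUE)
  insertion_len <- as.integer(insertion_len)
  if (!insertion_len %in% c(2L, 3L)) {
    abort("insertion_len must be 2 or 3", class = "dg_config_error")
  }
  row <- as_utr_row(utr)
  stopifnot(is.data.frame(elements), nrow(elements) >= 1L)
  elements <- elements[elements$seq_id == row$seq_id | is.na(elements$seq_id), ,
                       drop = FALSE]
  if (nrow(elements) == 0L) {
    abort("no elements match the UTR's seq_id", class = "dg_config_error")
  }

  out <- lapply(seq_len(nrow(elements)), function(k) {
    el <- elements[k, ]
    if (el$start < 1L || el$end > row$length || el$start > el$end) {
      abort(sprintf("element %s [%d,%d] outside sequence 1..%d",
                    el$rank_label %||% k, el$start, el$end, row$length),
            class = "dg_bounds_error")
    }
    target_rna <- substr(row$residues, el$start, el$end)
    sense_rna <- target_rna
    antis_rna <- reverse_complement(target_rna, "RNA")
    label <- if (!is.null(el$rank_label)) el$rank_label else paste0("t", k)

    mk <- function(category, parent_rna, suffix) {
      ins_pos <- NA_integer_
      ins_seq <- NA_character_
      res_rna <- parent_rna
      if (grepl("^mir", category)) {
        n <- nchar(parent_rna)
        ins_pos <- n %/% 2L
        ins_seq <- strrep(insertion_base(parent_rna, ins_pos), insertion_len)
        res_rna <- paste0(substr(parent_rna, 1, ins_pos), ins_seq,
                          substr(parent_rna, ins_pos + 1L, n))
      }
      res <- if (chemistry == "dna") convert_alphabet(res_rna, "DNA") else res_rna
      ann <- oligo_annotations(res)
      tibble(
        name = paste0("dG_", label, suffix), category = category,
        chemistry = chemistry, residues = res,
        target_seq_id = row$seq_id,
        target_start = as.integer(el$start), target_end = as.integer(el$end),
        insertion_pos = ins_pos, insertion_seq = ins_seq,
        length = nchar(res), gc_pct = ann$gc_pct, tm_wallace = ann$tm_wallace
      )
    }

    dplyr::bind_rows(
      if ("sense" %in% categories) mk("sense", sense_rna, "_s"),
      if ("antisense" %in% categories) mk("antisense", antis_rna, "_as"),
      if ("mir_like_sense" %in% categories) mk("mir_like_sense", sense_rna, "_mir_s"),
      if ("mir_like_antisense" %in% categories)
        mk("mir_like_antisense", antis_rna, "_mir_as")
    )
  })
  dplyr::bind_rows(out)
}

#' Scrambled control oligo
#'
#' Draws seeded Fisher-Yates shuffles of the parent oligo until the shuffle
#' has no perfectly complementary stretch of `max_run` or more against the
#' full target UTR.  The control preserves the parent's length and base
#' composition exactly and is reproducible from `(parent, seed)`.
#'
#' @param parent A one-row oligo tibble from [design_oligos()] or a sequence
#'   string.
#' @param target The target UTR (one-row tibble or string) the control must
#'   not bind.
#' @param seed Integer RNG seed.
#' @param max_run Reject shuffles whose longest complementary run against
#'   the target is `>= max_run` (default 7).
#' @param max_tries Attempts before giving up (default 1000).
#' @return A one-row oligo tibble with `category = "scrambled"` and columns
#'   `seed` and `degenerate` (TRUE when the parent is a homopolymer, whose
#'   every shuffle equals the parent).
#' @export
make_scrambled <- function(parent, target, seed, max_run = 7L, max_tries = 1000L) {
  if (is.character(parent)) {
    parent <- tibble(name = "oligo", category = NA_character_,
                     chemistry = if (grepl("T", toupper(parent))) "dna" else "2ome",
                     residues = toupper(parent))
  }
  stopifnot(is.data.frame(parent), nrow(parent) == 1L)
  target_row <- as_utr_row(target)
  chars <- strsplit(parent$residues, "")[[1]]
  degenerate <- length(unique(chars)) == 1L

  accepted <- NULL
  with_preserved_rng(seed, {
    for (try in seq_len(max_tries)) {
      cand <- paste(sample(chars), collapse = "")
      rep <- hybridization_report(cand, target_row)
      if (rep$longest_complementary_run < max_run) {
        accepted <- cand
        break
      }
      if (degenerate) break # every shuffle is identical; no point retrying
    }
  })
  if (is.null(accepted)) {
    abort(sprintf(
      "no acceptable shuffle in %d tries (longest run >= %d); consider a larger max_run",
      max_tries, max_run), class = "dg_exhaustion_error")
  }
  ann <- oligo_annotations(accepted)
  tibble(
    name = paste0(parent$name, "_sc"), category = "scrambled",
    chemistry = parent$chemistry, residues = accepted,
    target_seq_id = NA_character_, target_start = NA_integer_,
    target_end = NA_integer_, insertion_pos = NA_integer_,
    insertion_seq = NA_character_, length = nchar(accepted),
    gc_pct = ann$gc_pct, tm_wallace = ann$tm_wallace,
    seed = as.integer(seed), degenerate = degenerate
  )
}

# run code under a given seed without disturbing the caller's RNG state
with_preserved_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' In-silico hybridization report of an oligo against a target
#'
#' Scans every gapless antiparallel alignment of the oligo against the
#' target and reports the alignment maximising the number of Watson-Crick
#' complementary appositions (ties broken towards more G:U wobbles, then the
#' 5'-most offset), plus the single longest perfectly complementary stretch
#' found at any offset.  G:U appositions are counted separately as wobble
#' positions; they are only true wobble base pairs for RNA-chemistry oligos.
#'
#' @param oligo A one-row oligo tibble or a sequence string (DNA or RNA
#'   lettering).
#' @param target The target UTR (one-row tibble or string).
#' @return A one-row tibble: `longest_complementary_run`,
#'   `wobble_positions`, `total_matched`, `best_offset` (target coordinate
#'   faced by the oligo's 3' residue minus 1), `overlap`.
#' @examples
#' hybridization_report("GGAUGCCAU", "AAAUGGCAUCCAA")
#' @export
hybridization_report <- function(oligo, target) {
  oligo_res <- if (is.data.frame(oligo)) oligo$residues else oligo
  o <- chartr("Tt", "Uu", toupper(oligo_res))
  t_row <- as_utr_row(target)
  t <- strsplit(t_row$residues, "")[[1]]
  # antiparallel: reverse the oligo so position i faces target position i + d
  o_rev <- rev(strsplit(o, "")[[1]])
  Lo <- length(o_rev); Lt <- length(t)

  best <- list(wc = -1L, wobble = -1L, offset = NA_integer_, overlap = 0L)
  longest <- 0L
  for (d in (1L - Lo):(Lt - 1L)) {
    i <- seq_len(Lo)
    ok <- i + d >= 1L & i + d <= Lt
    if (!any(ok)) next
    oi <- o_rev[ok]
    ti <- t[i[ok] + d]
    wc <- WC_PARTNER[oi] == ti
    wobble <- (oi == "G" & ti == "U") | (oi == "U" & ti == "G")
    n_wc <- sum(wc)
    runs <- rle(wc)
    run_max <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    longest <- max(longest, run_max)
    if (n_wc > best$wc ||
        (n_wc == best$wc && sum(wobble) > best$wobble)) {
      best <- list(wc = n_wc, wobble = sum(wobble), offset = d,
                   overlap = sum(ok))
    }
  }
  tibble(
    longest_complementary_run = as.integer(longest),
    wobble_positions = as.integer(best$wobble),
    total_matched = as.integer(best$wc),
    best_offset = as.integer(best$offset),
    overlap = as.integer(best$overlap)
  )
}
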