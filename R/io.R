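#' Read 5'UTR sequences from a FASTA file
#'
#' Sequences are normalised to the internal RNA alphabet (upper case,
#' `T -> U`); ids are taken from the headers up to the first whitespace.
#' Empty files, duplicate ids and non-nucleotide characters raise named
#' parse errors that report the offending line.
#'
#' @param path FASTA file (DNA or RNA lettering).
#' @return A sequence tibble, one row per record (see [utr_sequence()]).
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "dg_io_error")
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(sprintf("cannot parse FASTA %s: %s", path, conditionMessage(e)),
                          class = "dg_parse_error")
                  })
  if (length(set) == 0L) {
    abort(sprintf("no FASTA records in %s", path), class = "dg_parse_error")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(sprintf("duplicate sequence id '%s' in %s (line %d)",
                  dup, path, fasta_line_of(path, dup, occurrence = 2L)),
          class = "dg_parse_error")
  }
  rows <- lapply(seq_along(set), function(k) {
    res <- toupper(as.character(set[[k]]))
    bad <- regmatches(res, regexpr("[^ACGTU]", res))
    if (length(bad) && nzchar(bad)) {
      abort(sprintf("non-nucleotide character '%s' in record '%s' of %s (line %d)",
                    bad, ids[k], path, fasta_bad_line(path, ids[k])),
            class = "dg_parse_error")
    }
    utr_sequence(ids[k], res)
  })
  dplyr::bind_rows(rows)
}

fasta_line_of <- function(path, id, occurrence = 1L) {
  lines <- readLines(path, warn = FALSE)
  hits <- which(grepl(paste0("^>", id, "(\\s|$)"), lines))
  if (length(hits) >= occurrence) hits[occurrence] else NA_integer_
}

fasta_bad_line <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  start <- fasta_line_of(path, id)
  if (is.na(start)) return(NA_integer_)
  k <- start + 1L
  while (k <= length(lines) && !startsWith(lines[k], ">")) {
    if (grepl("[^ACGTUacgtu]", lines[k])) return(k)
    k <- k + 1L
  }
  NA_integer_
}

#' Write / read a perturbation profile as TSV
#'
#' Columns: `seq_id, pos, wt_base, raw_ddg, signal, signal_scaled, wt_dg`;
#' positions are 1-based.  Reading back reproduces the in-memory tibble.
#'
#' @param profile A `perturbation_profile` tibble.
#' @param path Output file.
#' @return `path`, invisibly (writer); the profile tibble (reader).
#' @export
write_profile_tsv <- function(profile, path) {
  header <- sprintf(
    "# dgenhancer perturbation profile; window=%d scaling=%s aggregate=%s",
    attr(profile, "window") %||% NA_integer_,
    attr(profile, "scaling") %||% "minmax",
    attr(profile, "aggregate") %||% "absolute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  window <- as.integer(sub(".*window=(\\d+).*", "\\1", first))
  scaling <- sub(".*scaling=(\\S+).*", "\\1", first)
  aggregate <- sub(".*aggregate=(\\S+).*", "\\1", first)
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c(seq_id = "character", pos = "integer",
                                  wt_base = "character", raw_ddg = "numeric",
                                  signal = "numeric",
                                  signal_scaled = "numeric",
                                  wt_dg = "numeric"))
  out <- as_tibble(df)
  attr(out, "window") <- window
  attr(out, "scaling") <- scaling
  attr(out, "aggregate") <- aggregate
  class(out) <- c("perturbation_profile", class(out))
  out
}

#' Write called elements as TSV (1-based) or BED (0-based half-open)
#'
#' @param elements An element tibble from [call_elements()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_elements_tsv <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dgenhancer elements; coordinates 1-based inclusive", con)
  write.table(as.data.frame(elements), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_elements_tsv
#' @export
read_elements_tsv <- function(path) {
  as_tibble(read.delim(path, sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE))
}

#' @rdname write_elements_tsv
#' @export
write_elements_bed <- function(elements, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dgenhancer elements (BED: 0-based half-open)", con)
  if (nrow(elements) > 0L) {
    bed <- data.frame(
      chrom = elements$seq_id,
      chromStart = elements$start - 1L,
      chromEnd = elements$end,
      name = elements$rank_label,
      score = round(elements$peak_signal, 4)
    )
    write.table(bed, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write designed oligos as TSV and FASTA
#'
#' The FASTA header carries `name|category|chemistry`.
#'
#' @param oligos An oligo tibble from [design_oligos()] / [make_scrambled()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_oligos_tsv <- function(oligos, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dgenhancer oligos; target coordinates 1-based inclusive", con)
  write.table(as.data.frame(oligos), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_oligos_tsv
#' @export
write_oligos_fasta <- function(oligos, path) {
  lines <- unlist(lapply(seq_len(nrow(oligos)), function(k) {
    c(sprintf(">%s|%s|%s", oligos$name[k], oligos$category[k],
              oligos$chemistry[k]),
      oligos$residues[k])
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Serialise / restore an efficiency model as JSON
#'
#' @param model An `efficiency_model`.
#' @param path JSON file.
#' @return `path`, invisibly (writer); the model (reader).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "efficiency_model"))
  jsonlite::write_json(
    list(a = model$a, b = model$b, r_squared = model$r_squared,
         n_points = model$n_points, source = model$source),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_efficiency_model(
    a = x$a, b = x$b,
    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
    n_points = x$n_points %||% 0L, fit_log = NULL,
    source = x$source %||% "json"
  )
}

#' Flat key=value run configuration
#'
#' Every command-line flag of the `dgenhancer` script has a counterpart key;
#' command-line values override the file.  Unknown keys raise an error so
#' typos do not silently fall back to defaults.
#'
#' @param path Config file with one `key = value` per line; `#` comments.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  defaults <- default_run_config()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "dg_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) {
      abort(sprintf("malformed config line: '%s'", ln), class = "dg_parse_error")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) {
      abort(sprintf("unknown config key '%s'", key), class = "dg_config_error")
    }
    proto <- defaults[[key]]
    defaults[[key]] <- if (is.numeric(proto)) as.numeric(val)
      else if (is.logical(proto)) as.logical(val) else val
  }
  defaults
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    engine = "pairmax", params_file = "", window = 6, percentile = 90,
    max_elements = 3, categories = "sense,antisense", chemistry = "dna",
    insertion_len = 3, max_run = 7, seed = 1, out_dir = ".",
    log_level = "info"
  )
}
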