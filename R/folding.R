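#' Predict the minimum-free-energy secondary structure
#'
#' Runs the dynamic program for the given energy model and returns the
#' structure whose energy is minimal over all admissible structures, together
#' with its Gibbs folding energy (kcal/mol; the open chain is the reference
#' state at 0, so the result is always <= 0).  The computation is
#' deterministic: ties are broken by a fixed branch-preference order in the
#' traceback under which the 5'-most pair opens as early as possible.
#'
#' @param seq A one-row sequence tibble (see [utr_sequence()]) or a string.
#' @param model An [energy_model()].
#' @return An object of class `fold_result`: a list with `seq_id`,
#'   `structure` (dot-bracket), `delta_g` (kcal/mol) and `engine`.
#' @examples
#' mfe_fold("GGGAAACCC", energy_model("pairmax"))
#' @export
mfe_fold <- function(seq, model) {
  row <- as_utr_row(seq)
  payload <- model_payload(model, row$length)
  res <- .fold_dp(encode_residues(row$residues), payload)
  fold_result(row$seq_id, res$structure, res$delta_g,
              engine = paste0("builtin-", model$mode))
}

fold_result <- function(seq_id, structure, delta_g, engine) {
  structure(
    list(seq_id = seq_id, structure = structure,
         delta_g = delta_g, engine = engine),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result: %s (%s)>\n", x$seq_id, x$engine))
  cat(" ", x$structure, "\n")
  cat(sprintf("  dG = %.2f kcal/mol\n", x$delta_g))
  invisible(x)
}

#' @export
tidy.fold_result <- function(x, ...) {
  tibble(seq_id = x$seq_id, structure = x$structure,
         delta_g = x$delta_g, engine = x$engine)
}

# dot-bracket -> integer pair table (0 = unpaired, else partner index)
parse_dotbracket <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    abort("structure may contain only '.', '(' and ')'", class = "dg_structure_error")
  }
  n <- length(chars)
  ptab <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) {
        abort("unbalanced dot-bracket structure", class = "dg_structure_error")
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ptab[j] <- i
      ptab[i] <- j
    }
  }
  if (length(stack) > 0L) {
    abort("unbalanced dot-bracket structure", class = "dg_structure_error")
  }
  ptab
}

pairs_to_dotbracket <- function(pairs, n) {
  chars <- rep(".", n)
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      chars[pairs[k, 1]] <- "("
      chars[pairs[k, 2]] <- ")"
    }
  }
  paste(chars, collapse = "")
}

#' Score a secondary structure under an energy model
#'
#' The shared scoring kernel: the enumeration oracle and the consistency
#' checks on the dynamic program both call it.  The structure is first
#' validated against the model's admissibility rules (balanced brackets,
#' allowed pair classes, hairpin loops of at least `min_hairpin_loop`
#' residues, no lone pairs when the model disallows them).
#'
#' @inheritParams mfe_fold
#' @param structure Dot-bracket string of the same length as the sequence.
#' @return Energy in kcal/mol; the all-unpaired structure scores 0.
#' @examples
#' structure_energy("GGGAAACCC", "(((...)))", energy_model("pairmax"))
#' @export
structure_energy <- function(seq, structure, model) {
  row <- as_utr_row(seq)
  if (nchar(structure) != row$length) {
    abort("structure length differs from sequence length", class = "dg_structure_error")
  }
  ptab <- parse_dotbracket(structure)
  bases <- strsplit(row$residues, "")[[1]]
  n <- length(bases)

  idx <- which(ptab > seq_len(n))
  for (i in idx) {
    j <- ptab[i]
    if (!model$can_pair[bases[i], bases[j]]) {
      abort(sprintf("pair %s:%s at (%d,%d) is not an allowed pair class",
                    bases[i], bases[j], i, j), class = "dg_structure_error")
    }
    if (!model$lone_pair_allowed) {
      stacked_in <- i + 1 <= n && ptab[i + 1] == j - 1 && j - 1 >= 1
      stacked_out <- i - 1 >= 1 && j + 1 <= n && ptab[i - 1] == j + 1
      if (!stacked_in && !stacked_out) {
        abort(sprintf("lone pair at (%d,%d) is inadmissible under this model", i, j),
              class = "dg_structure_error")
      }
    }
  }

  total <- 0
  for (i in idx) {
    j <- ptab[i]
    # children: pairs directly enclosed by (i, j)
    children <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (ptab[k] > 0L) {
        children[[length(children) + 1L]] <- c(k, ptab[k])
        k <- ptab[k] + 1L
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    if (length(children) == 0L && unpaired < model$min_hairpin_loop) {
      abort(sprintf("hairpin loop of %d < %d at pair (%d,%d)",
                    unpaired, model$min_hairpin_loop, i, j),
            class = "dg_structure_error")
    }
    if (model$mode == "pairmax") {
      total <- total + model$pair_weights[bases[i], bases[j]]
    } else {
      nn <- model$nn
      if (length(children) == 0L) {
        total <- total + loop_penalty(nn$hairpin, nn$extrapolation_coef, unpaired)
      } else if (length(children) == 1L) {
        p <- children[[1]][1]; q <- children[[1]][2]
        l1 <- p - i - 1L; l2 <- j - q - 1L
        if (l1 == 0L && l2 == 0L) {
          e <- nn$stack[bases[i], bases[j], bases[p], bases[q]]
          if (is.na(e)) {
            abort("missing stack energy in parameter table", class = "dg_config_error")
          }
          total <- total + e
        } else if (l1 == 0L || l2 == 0L) {
          total <- total + loop_penalty(nn$bulge, nn$extrapolation_coef, l1 + l2)
        } else {
          total <- total + loop_penalty(nn$internal, nn$extrapolation_coef, l1 + l2)
        }
      } else {
        ml <- nn$multiloop
        total <- total + ml$offset + ml$branch * length(children) +
          ml$unpaired * unpaired
      }
    }
  }
  unname(total)
}

#' Enumerate every admissible secondary structure
#'
#' Brute-force oracle for verifying the dynamic program: generates all
#' structures admissible under the model (including the empty structure) and
#' scores each with [structure_energy()].  Refuses sequences longer than
#' `max_len` to guard against combinatorial blow-up.
#'
#' @inheritParams mfe_fold
#' @param max_len Refusal threshold (default 14).
#' @return A tibble with columns `structure` and `energy`, sorted by energy.
#' @examples
#' enumerate_structures("GGGAAACCC", energy_model("pairmax"))
#' @export
enumerate_structures <- function(seq, model, max_len = 14L) {
  row <- as_utr_row(seq)
  n <- row$length
  if (n > max_len) {
    abort(sprintf("sequence length %d exceeds max_len = %d", n, max_len),
          class = "dg_config_error")
  }
  bases <- strsplit(row$residues, "")[[1]]
  min_hp <- model$min_hairpin_loop
  memo <- new.env(parent = emptyenv())

  region <- function(i, j) {
    if (i >= j) return(list(NULL))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- lapply(region(i + 1L, j), identity)   # i unpaired
    ks <- if (i + min_hp + 1L <= j) seq.int(i + min_hp + 1L, j) else integer(0)
    for (k in ks) {
      if (!model$can_pair[bases[i], bases[k]]) next
      left <- region(i + 1L, k - 1L)
      right <- region(k + 1L, j)
      for (L in left) {
        for (R in right) {
          out[[length(out) + 1L]] <- rbind(c(i, k), L, R)
        }
      }
    }
    memo[[key]] <- out
    out
  }

  structs <- region(1L, n)
  db <- vapply(structs, pairs_to_dotbracket, character(1), n = n)
  if (!model$lone_pair_allowed) {
    keep <- !vapply(db, has_lone_pair, logical(1))
    db <- db[keep]
  }
  energy <- vapply(db, function(s) structure_energy(row, s, model), numeric(1))
  out <- tibble(structure = unname(db), energy = unname(energy))
  dplyr::arrange(out, .data$energy, .data$structure)
}

has_lone_pair <- function(structure) {
  ptab <- parse_dotbracket(structure)
  n <- length(ptab)
  for (i in which(ptab > seq_len(n))) {
    j <- ptab[i]
    stacked_in <- i + 1 <= n && j - 1 >= 1 && ptab[i + 1] == j - 1
    stacked_out <- i - 1 >= 1 && j + 1 <= n && ptab[i - 1] == j + 1
    if (!stacked_in && !stacked_out) return(TRUE)
  }
  FALSE
}

#' Fold with an external ViennaRNA-compatible engine
#'
#' Adapter for a command-line folding engine with the RNAfold contract:
#' sequence on stdin, dot-bracket plus free energy on stdout.  Useful for
#' cross-checking the built-in engines against an independent thermodynamic
#' implementation; note the built-in NN tables are not parameter-identical
#' to any external engine, so energies are comparable but not equal.
#'
#' @inheritParams mfe_fold
#' @param command Name or path of the engine binary (default `RNAfold`).
#' @param args Extra command-line arguments.
#' @return A `fold_result` with `engine = "external"`.
#' @export
fold_external <- function(seq, command = "RNAfold", args = c("--noPS")) {
  row <- as_utr_row(seq)
  if (Sys.which(command) == "") {
    abort(sprintf("external folding engine '%s' not found on PATH", command),
          class = "dg_config_error")
  }
  out <- suppressWarnings(system2(command, args = args, input = row$residues,
                                  stdout = TRUE, stderr = FALSE))
  line <- grep("^[.()]+\\s+\\(", out, value = TRUE)
  if (length(line) == 0L) {
    abort("could not parse external engine output", class = "dg_io_error")
  }
  structure_str <- sub("\\s.*$", "", line[1])
  dg <- as.numeric(gsub("[()]", "", sub("^[.()]+\\s+", "", line[1])))
  if (is.na(dg)) {
    abort("could not parse external engine energy", class = "dg_io_error")
  }
  fold_result(row$seq_id, structure_str, dg, engine = "external")
}
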