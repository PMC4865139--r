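BASES <- c("A", "C", "G", "U")
PAIR_CLASSES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Construct a folding energy model
#'
#' Two modes are available.  `"pairmax"` is a weighted base-pair-maximisation
#' model (Nussinov-style): every admissible pair contributes its pair-class
#' weight and loops are free.  `"nn"` is a simplified nearest-neighbor
#' thermodynamic model with stacking energies, loop-size penalties and an
#' affine multiloop term, read from a packaged parameter file.  Both modes
#' share the admissibility rules: only the allowed pair classes, hairpin
#' loops of at least `min_hairpin_loop` unpaired residues and, when
#' `lone_pair_allowed = FALSE`, no isolated pairs (every helix has at least
#' two stacked pairs).
#'
#' @param mode `"pairmax"` or `"nn"`.
#' @param allowed_pairs Character vector of pair classes out of
#'   `AU, UA, GC, CG, GU, UG`.
#' @param min_hairpin_loop Minimum unpaired residues enclosed by an innermost
#'   pair (default 3, the standard steric minimum).
#' @param lone_pair_allowed Allow helices of a single pair.  Defaults to
#'   `TRUE` for `"pairmax"` and `FALSE` for `"nn"` (standard practice).
#' @param pair_weights Named energies (kcal/mol) per pair class, used by
#'   `"pairmax"` only.  Stabilising weights are negative.
#' @param params_file YAML file with the nearest-neighbor tables, used by
#'   `"nn"` only; defaults to the packaged Turner-like file.
#' @param max_interior_loop Cap on bulge/internal loop size searched by the
#'   dynamic program (default 30, standard).
#'
#' @return An object of class `energy_model`.
#' @examples
#' energy_model("pairmax")
#' energy_model("nn")
#' @export
energy_model <- function(mode = c("pairmax", "nn"),
                         allowed_pairs = PAIR_CLASSES,
                         min_hairpin_loop = 3L,
                         lone_pair_allowed = NULL,
                         pair_weights = c(AU = -2, UA = -2, GC = -3,
                                          CG = -3, GU = -1, UG = -1),
                         params_file = NULL,
                         max_interior_loop = 30L) {
  mode <- match.arg(mode)
  if (!all(allowed_pairs %in% PAIR_CLASSES)) {
    abort("allowed_pairs must be drawn from AU, UA, GC, CG, GU, UG",
          class = "dg_config_error")
  }
  min_hairpin_loop <- as.integer(min_hairpin_loop)
  if (is.na(min_hairpin_loop) || min_hairpin_loop < 0L) {
    abort("min_hairpin_loop must be a non-negative integer", class = "dg_config_error")
  }
  lone_pair_allowed <- lone_pair_allowed %||% (mode == "pairmax")

  can_pair <- matrix(FALSE, 4, 4, dimnames = list(BASES, BASES))
  for (p in allowed_pairs) {
    can_pair[substr(p, 1, 1), substr(p, 2, 2)] <- TRUE
  }

  pw <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  if (mode == "pairmax") {
    if (!all(allowed_pairs %in% names(pair_weights))) {
      abort("pair_weights must cover every allowed pair class",
            class = "dg_config_error")
    }
    for (p in allowed_pairs) {
      pw[substr(p, 1, 1), substr(p, 2, 2)] <- pair_weights[[p]]
    }
  }

  nn <- NULL
  if (mode == "nn") {
    params_file <- params_file %||%
      system.file("extdata", "nn_params.yaml", package = "dgenhancer")
    if (!file.exists(params_file)) {
      abort(sprintf("energy parameter file not found: %s", params_file),
            class = "dg_config_error")
    }
    nn <- read_nn_params(params_file)
    nn$params_file <- params_file
    nn$params_md5 <- unname(tools::md5sum(params_file))
  }

  structure(
    list(
      mode = mode,
      allowed_pairs = allowed_pairs,
      min_hairpin_loop = min_hairpin_loop,
      lone_pair_allowed = lone_pair_allowed,
      max_interior_loop = as.integer(max_interior_loop),
      can_pair = can_pair,
      pair_weights = pw,
      nn = nn
    ),
    class = "energy_model"
  )
}

read_nn_params <- function(path) {
  y <- yaml::yaml.load_file(path)
  need <- c("stacks", "hairpin", "bulge", "internal", "extrapolation", "multiloop")
  if (!all(need %in% names(y))) {
    abort(sprintf("parameter file %s is missing sections: %s", path,
                  paste(setdiff(need, names(y)), collapse = ", ")),
          class = "dg_config_error")
  }
  stack <- array(NA_real_, dim = c(4, 4, 4, 4),
                 dimnames = list(BASES, BASES, BASES, BASES))
  for (outer in names(y$stacks)) {
    for (inner in names(y$stacks[[outer]])) {
      a <- substr(outer, 1, 1); b <- substr(outer, 2, 2)
      c_ <- substr(inner, 1, 1); d <- substr(inner, 2, 2)
      stack[a, b, c_, d] <- y$stacks[[outer]][[inner]]
    }
  }
  tab <- function(section) {
    sizes <- as.integer(names(y[[section]]))
    vals <- unlist(y[[section]], use.names = FALSE)
    if (any(vals < 0)) {
      abort(sprintf("%s loop penalties must be non-negative", section),
            class = "dg_config_error")
    }
    list(sizes = sizes, values = as.numeric(vals))
  }
  list(
    stack = stack,
    hairpin = tab("hairpin"),
    bulge = tab("bulge"),
    internal = tab("internal"),
    extrapolation_coef = as.numeric(y$extrapolation$coef),
    multiloop = list(
      offset = as.numeric(y$multiloop$offset),
      branch = as.numeric(y$multiloop$branch),
      unpaired = as.numeric(y$multiloop$unpaired)
    )
  )
}

# Loop penalty for a given size, with logarithmic extrapolation past the
# tabulated range; +Inf below the smallest tabulated size (inadmissible).
loop_penalty <- function(tab, coef, size) {
  smax <- max(tab$sizes)
  vmax <- tab$values[which.max(tab$sizes)]
  vapply(size, function(s) {
    if (s < min(tab$sizes)) return(Inf)
    hit <- match(s, tab$sizes)
    if (!is.na(hit)) return(tab$values[hit])
    if (s <= smax) {
      # untabulated interior size: interpolate between neighbors
      lo <- max(tab$sizes[tab$sizes < s]); hi <- min(tab$sizes[tab$sizes > s])
      vlo <- tab$values[match(lo, tab$sizes)]; vhi <- tab$values[match(hi, tab$sizes)]
      return(vlo + (vhi - vlo) * (s - lo) / (hi - lo))
    }
    vmax + coef * log(s / smax)
  }, numeric(1))
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model: %s>\n", x$mode))
  cat(sprintf("  allowed pairs      : %s\n", paste(x$allowed_pairs, collapse = " ")))
  cat(sprintf("  min hairpin loop   : %d\n", x$min_hairpin_loop))
  cat(sprintf("  lone pairs allowed : %s\n", x$lone_pair_allowed))
  if (x$mode == "pairmax") {
    w <- vapply(x$allowed_pairs, function(p)
      x$pair_weights[substr(p, 1, 1), substr(p, 2, 2)], numeric(1))
    cat("  pair weights       :",
        paste(sprintf("%s=%g", x$allowed_pairs, w), collapse = " "), "\n")
  } else {
    cat(sprintf("  parameter file     : %s (md5 %s)\n",
                basename(x$nn$params_file), x$nn$params_md5))
  }
  invisible(x)
}

# Flatten the model for the C++ kernel, with loop tables extended to cover
# loops up to length n.
model_payload <- function(model, n) {
  stopifnot(inherits(model, "energy_model"))
  INF <- 1e9
  sizes <- 0:(n + 1)
  if (model$mode == "nn") {
    nn <- model$nn
    hp <- loop_penalty(nn$hairpin, nn$extrapolation_coef, sizes)
    bu <- loop_penalty(nn$bulge, nn$extrapolation_coef, sizes)
    il <- loop_penalty(nn$internal, nn$extrapolation_coef, sizes)
    stack_flat <- as.numeric(aperm(nn$stack, c(4, 3, 2, 1)))  # index a*64+b*16+c*4+d
    stack_flat[is.na(stack_flat)] <- INF
    ml <- nn$multiloop
  } else {
    hp <- bu <- il <- rep(0, length(sizes))
    stack_flat <- rep(0, 256)
    ml <- list(offset = 0, branch = 0, unpaired = 0)
  }
  hp[!is.finite(hp)] <- INF
  bu[!is.finite(bu)] <- INF
  il[!is.finite(il)] <- INF
  list(
    mode_code = if (model$mode == "pairmax") 0L else 1L,
    lone_pair_allowed = model$lone_pair_allowed,
    min_hairpin_loop = model$min_hairpin_loop,
    max_interior_loop = model$max_interior_loop,
    pair_weight_matrix = unname(model$pair_weights),
    can_pair_matrix = unname(model$can_pair),
    stack_flat = stack_flat,
    hairpin_by_size = hp,
    bulge_by_size = bu,
    internal_by_size = il,
    multiloop_offset = ml$offset,
    multiloop_branch = ml$branch,
    multiloop_unpaired = ml$unpaired
  )
}
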