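# Probe self-structure: minimum-free-energy folding.
#
# A probe that folds on itself into a stable hairpin ("low free energy")
# hybridizes poorly and must be avoided, so every candidate is folded and
# its MFE printed in the result file. The folder is a self-contained
# dynamic program over non-crossing structures (stacking energies from the
# nearest-neighbor table, affine loop penalties, helices of at least two
# consecutive pairs, hairpin loops of at least three bases) with an
# exhaustive enumeration oracle for verification. DNA parameters are the
# default; the table accessor is the hook for an RNA alphabet.

FOLD_MAX_LEN <- 60L
BRUTE_MAX_LEN <- 22L
FOLD_EPS <- 1e-7

.fold_cache <- new.env(parent = emptyenv())

base_codes <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(x)) {
    stop("folding requires concrete A/C/G/T sequences", call. = FALSE)
  }
  x
}

interp_loop <- function(sizes, values, max_size, temp_k) {
  grid <- stats::approx(sizes, values, xout = seq_len(max(sizes)))$y
  out <- rep(NA_real_, max_size)
  out[seq_along(grid)] <- grid
  if (max_size > max(sizes)) {
    # Jacobson-Stockmayer extrapolation beyond the table
    n_ext <- (max(sizes) + 1):max_size
    out[n_ext] <- grid[max(sizes)] +
      1.75 * 0.0019872 * 310.15 * log(n_ext / max(sizes))
  }
  out[is.na(out)] <- 1e9
  # loop penalties are treated as purely entropic: scale with temperature
  out * temp_k / 310.15
}

#' Folding energy tables at a given temperature
#'
#' Builds the stack free energies (from the nearest-neighbor delta-H/delta-S
#' at the requested temperature) and loop penalty vectors used by both
#' [fold_mfe()] and the enumeration oracle [brute_force_mfe()]. Loop
#' penalties are scaled entropically with absolute temperature.
#'
#' @param temp_c Temperature in degrees C.
#' @param wobble Allow G.T wobble pairs (default off for DNA). Stacks that
#'   involve a wobble pair take a single coarse stacking value.
#' @return List of tables consumed by the folding routines.
#' @export
fold_energy_tables <- function(temp_c = 37, wobble = FALSE) {
  key <- sprintf("tab_%.6f_%d", temp_c, as.integer(wobble))
  if (!is.null(.fold_cache[[key]])) {
    return(.fold_cache[[key]])
  }
  temp_k <- temp_c + 273.15
  nn <- nn_table("dna")
  bases <- c("A", "C", "G", "T")
  stack16 <- numeric(16)
  for (a in 0:3) {
    for (b in 0:3) {
      din <- paste0(bases[a + 1], bases[b + 1])
      row <- nn[nn$dinuc == din, ]
      stack16[a * 4 + b + 1] <- row$dh - temp_k * row$ds / 1000
    }
  }
  path <- system.file("extdata", "loop_energies_dna.tsv", package = "fishdesign")
  loops <- readr::read_tsv(path,
    comment = "#",
    col_types = readr::cols(
      type = readr::col_character(),
      size = readr::col_integer(), dg37 = readr::col_double()
    ),
    progress = FALSE
  )
  pick <- function(type) loops[loops$type == type, ]
  hp <- interp_loop(pick("hairpin")$size, pick("hairpin")$dg37, FOLD_MAX_LEN, temp_k)
  hp[1:2] <- 1e9 # hairpin loops below 3 bases are disallowed
  bu <- interp_loop(pick("bulge")$size, pick("bulge")$dg37, FOLD_MAX_LEN, temp_k)
  il <- interp_loop(pick("internal")$size, pick("internal")$dg37, FOLD_MAX_LEN, temp_k)
  il[1] <- 1e9
  scale <- temp_k / 310.15
  tabs <- list(
    stack16 = stack16,
    hairpin = hp, bulge = bu, internal = il,
    ml_a = pick("multiloop_offset")$dg37 * scale,
    ml_b = pick("multiloop_branch")$dg37 * scale,
    ml_c = pick("multiloop_unpaired")$dg37 * scale,
    wobble = wobble,
    # coarse wobble stack: dH -6.0 kcal/mol, dS -17.0 cal/mol/K
    wobble_stack = -6.0 - temp_k * (-17.0) / 1000,
    temp_c = temp_c
  )
  .fold_cache[[key]] <- tabs
  tabs
}

pairs_to_dotbracket <- function(n, pairs) {
  db <- rep(".", n)
  if (nrow(pairs) > 0) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

new_fold_result <- function(seq, mfe, pairs, temp_c) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2)
  colnames(pairs) <- c("i", "j")
  structure(
    list(
      seq = seq, mfe = mfe,
      structure = pairs_to_dotbracket(nchar(seq), pairs),
      pairs = pairs, temp_c = temp_c
    ),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> mfe = %.2f kcal/mol at %.1f C\n", x$mfe, x$temp_c))
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Minimum-free-energy self-structure of a probe
#'
#' Dynamic-programming minimum over all non-crossing secondary structures of
#' a single strand under the shipped energy model. If no negative-energy
#' structure exists the probe is reported unstructured (MFE 0, all-dot).
#' Ties are broken deterministically: the traceback pairs the leftmost
#' pairable position with its smallest co-optimal partner.
#'
#' @param seq A single concrete A/C/G/T string of length 1--60.
#' @param temp_c Folding temperature, degrees C.
#' @param wobble Allow G.T wobble pairs.
#' @return A `fold_result`: list with `mfe` (kcal/mol, <= 0), `structure`
#'   (dot-bracket), and `pairs` (1-based i/j matrix).
#' @export
fold_mfe <- function(seq, temp_c = 37, wobble = FALSE) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n < 1 || n > FOLD_MAX_LEN) {
    stop("fold_mfe() accepts lengths 1..", FOLD_MAX_LEN, " (probes only)",
      call. = FALSE
    )
  }
  codes <- base_codes(seq)
  tabs <- fold_energy_tables(temp_c, wobble)
  res <- cpp_fold(codes, tabs)
  new_fold_result(seq, res$mfe, res$pairs, temp_c)
}

#' Structure filter on folded candidates
#'
#' A candidate passes iff its self-fold MFE is at or above the configured
#' floor (`mfe >= mfe_floor`, inclusive); candidates forming more stable
#' self-structures are rejected.
#'
#' @param result A `fold_result`, or a numeric MFE.
#' @param params [design_params()].
#' @return Logical.
#' @export
passes_structure_filter <- function(result, params = design_params()) {
  mfe <- if (inherits(result, "fold_result")) result$mfe else result
  mfe >= params$mfe_floor
}

# ---- shared energy function and validators -------------------------------

can_pair_codes <- function(a, b, wobble) {
  (a + b == 3L) || (wobble && ((a == 2L && b == 3L) || (a == 3L && b == 2L)))
}

#' Energy of an explicit secondary structure
#'
#' Scores a set of base pairs with the identical energy function used by the
#' dynamic program: stacking terms for adjacent pairs, hairpin/bulge/internal
#' loop penalties, and the affine multiloop penalty. Used by the enumeration
#' oracle and by validity tests.
#'
#' @param seq Concrete A/C/G/T string.
#' @param pairs Integer matrix (or list of length-2 vectors) of 1-based pairs.
#' @param tables Output of [fold_energy_tables()].
#' @return Energy in kcal/mol (0 for the empty structure).
#' @export
structure_energy <- function(seq, pairs, tables = fold_energy_tables()) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0L) {
    return(0)
  }
  s <- base_codes(seq)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  np <- nrow(pairs)
  # parent of pair k: the tightest enclosing pair
  parent <- rep(0L, np)
  for (k in seq_len(np)) {
    enclosing <- which(pairs[, 1] < pairs[k, 1] & pairs[, 2] > pairs[k, 2])
    if (length(enclosing) > 0) {
      parent[k] <- enclosing[which.min(pairs[enclosing, 2] - pairs[enclosing, 1])]
    }
  }
  wobble <- isTRUE(tables$wobble)
  stack_of <- function(i, j) {
    wc1 <- s[i] + s[j] == 3L
    wc2 <- s[i + 1] + s[j - 1] == 3L
    if (wc1 && wc2) tables$stack16[s[i] * 4 + s[i + 1] + 1] else tables$wobble_stack
  }
  e <- 0
  for (k in seq_len(np)) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    kids <- which(parent == k)
    if (length(kids) == 0L) {
      e <- e + tables$hairpin[j - i - 1]
    } else if (length(kids) == 1L) {
      a <- pairs[kids, 1]
      b <- pairs[kids, 2]
      n1 <- a - i - 1
      n2 <- j - b - 1
      if (n1 == 0 && n2 == 0) {
        e <- e + stack_of(i, j)
      } else if (n1 == 0 || n2 == 0) {
        e <- e + tables$bulge[n1 + n2]
      } else {
        e <- e + tables$internal[n1 + n2]
      }
    } else {
      unpaired <- (j - i - 1) -
        sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + tables$ml_a + tables$ml_b * (length(kids) + 1) +
        tables$ml_c * unpaired
    }
  }
  e
}

#' Validate a secondary structure
#'
#' Checks the structural constraints of the folding model: pairs are
#' position-disjoint and non-crossing, every pair is Watson-Crick (or wobble
#' when enabled), hairpin loops hold at least `min_hairpin` unpaired bases,
#' and no pair is isolated (every helix has >= 2 consecutive pairs).
#'
#' @param seq Concrete A/C/G/T string.
#' @param pairs 1-based pair matrix.
#' @param wobble Allow G.T pairs.
#' @param min_hairpin Minimum hairpin loop size.
#' @return TRUE, or a character scalar naming the violated constraint.
#' @export
validate_structure <- function(seq, pairs, wobble = FALSE, min_hairpin = 3) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0L) {
    return(TRUE)
  }
  s <- base_codes(seq)
  if (any(pairs[, 1] >= pairs[, 2])) {
    return("pair with i >= j")
  }
  pos <- c(pairs[, 1], pairs[, 2])
  if (anyDuplicated(pos)) {
    return("position in more than one pair")
  }
  np <- nrow(pairs)
  for (k in seq_len(np)) {
    if (!can_pair_codes(s[pairs[k, 1]], s[pairs[k, 2]], wobble)) {
      return("non-complementary pair")
    }
  }
  if (np > 1) {
    for (k in seq_len(np - 1)) {
      for (l in (k + 1):np) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        a <- pairs[l, 1]; b <- pairs[l, 2]
        nested <- (a > i && b < j) || (i > a && j < b)
        disjoint <- (a > j) || (i > b)
        if (!nested && !disjoint) {
          return("crossing pairs (pseudoknot)")
        }
      }
    }
  }
  key <- paste(pairs[, 1], pairs[, 2])
  has_pair <- function(i, j) paste(i, j) %in% key
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    inner <- which(pairs[, 1] > i & pairs[, 2] < j)
    if (length(inner) == 0L && (j - i - 1) < min_hairpin) {
      return("hairpin loop below minimum size")
    }
    if (!has_pair(i + 1, j - 1) && !has_pair(i - 1, j + 1)) {
      return("isolated base pair")
    }
  }
  TRUE
}

# ---- enumeration oracle ---------------------------------------------------

#' Exhaustive minimum-free-energy search (verification oracle)
#'
#' Enumerates every non-crossing structure that satisfies the folding
#' constraints (helix of >= 2 stacked pairs, hairpin >= 3), scores each with
#' [structure_energy()], and returns the minimum. Ties are broken exactly as
#' in [fold_mfe()]: among co-optimal structures the one whose sorted pair
#' list pairs the leftmost position with the smallest partner wins (a
#' structure extending a co-optimal prefix with further pairs is preferred).
#' Limited to 22 nt because of the combinatorial blow-up.
#'
#' @inheritParams fold_mfe
#' @return A `fold_result`.
#' @export
brute_force_mfe <- function(seq, temp_c = 37, wobble = FALSE) {
  stopifnot(length(seq) == 1L)
  n <- nchar(seq)
  if (n > BRUTE_MAX_LEN) {
    stop("brute_force_mfe() is limited to length ", BRUTE_MAX_LEN, call. = FALSE)
  }
  s <- base_codes(seq)
  tabs <- fold_energy_tables(temp_c, wobble)
  wob <- isTRUE(wobble)
  memo <- new.env(parent = emptyenv())

  gen <- function(i, j) {
    if (j - i + 1 < 7) {
      return(list(list()))
    }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) {
      return(memo[[key]])
    }
    out <- gen(i + 1, j) # i unpaired
    for (k in (i + 6):j) {
      # deepest stacked run rooted at (i,k)
      hmax <- 0L
      while (TRUE) {
        t <- hmax
        if (i + t >= k - t) break
        if (!can_pair_codes(s[i + t], s[k - t], wob)) break
        hmax <- hmax + 1L
        if (k - i - 2 * hmax + 1 < 0) break
      }
      if (hmax < 2) next
      for (h in 2:hmax) {
        lo <- i + h
        hi <- k - h
        gap <- hi - lo + 1
        inner_list <- if (gap >= 7) gen(lo, hi) else list(list())
        helix <- lapply(0:(h - 1), function(t) c(i + t, k - t))
        outer_list <- gen(k + 1, j)
        for (inner in inner_list) {
          if (length(inner) == 0L && gap < 3) next
          # skip inner structures that merely continue this helix
          if (length(inner) > 0L &&
            any(vapply(inner, function(p) p[1] == lo && p[2] == hi, logical(1)))) {
            next
          }
          for (outer in outer_list) {
            out[[length(out) + 1L]] <- c(helix, inner, outer)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }

  structs <- gen(1L, n)
  energies <- vapply(structs, function(p) structure_energy(seq, p, tabs), numeric(1))
  mfe <- min(energies)
  if (mfe > -FOLD_EPS) {
    return(new_fold_result(seq, 0, matrix(integer(0), ncol = 2), temp_c))
  }
  coopt <- structs[energies <= mfe + FOLD_EPS]
  keys <- vapply(coopt, function(p) {
    m <- do.call(rbind, p)
    m <- m[order(m[, 1]), , drop = FALSE]
    paste(sprintf("%03d%03d", m[, 1], m[, 2]), collapse = "")
  }, character(1))
  # leftmost-smallest pairing preferred; a structure that extends a
  # co-optimal prefix with further pairs beats the bare prefix, so pad
  # shorter keys with a high sentinel before taking the lexicographic min
  w <- max(nchar(keys))
  padded <- paste0(keys, strrep("9", w - nchar(keys)))
  best <- coopt[[order(padded, method = "radix")[1]]]
  m <- do.call(rbind, best)
  m <- m[order(m[, 1]), , drop = FALSE]
  new_fold_result(seq, mfe, m, temp_c)
}

#' Fold every probe in a candidate table
#'
#' Pipeline verb: adds a `self_mfe` column (kcal/mol) by folding each
#' `probe_seq` at the given temperature.
#'
#' @param candidates Tibble with a `probe_seq` column.
#' @param temp_c Folding temperature, degrees C.
#' @param wobble Allow G.T pairs.
#' @return `candidates` with a `self_mfe` column appended.
#' @export
add_self_structure <- function(candidates, temp_c = 37, wobble = FALSE) {
  stopifnot("probe_seq" %in% names(candidates))
  candidates$self_mfe <- purrr::map_dbl(
    candidates$probe_seq,
    function(s) fold_mfe(s, temp_c, wobble)$mfe
  )
  candidates
}
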