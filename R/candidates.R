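# Candidate probe enumeration and composition filters.
#
# Candidates are every window of every allowed length over the target
# species' reference record (the first record carrying the target label);
# the probe is the reverse complement of the sense-strand window, written
# 5'->3'. Other strains of the species enter through target coverage.
# Coordinates are 1-based inclusive on the sense strand.

#' Design parameter set
#'
#' Numeric defaults follow common rRNA-FISH practice and are fully
#' configurable; the structure filter (`mfe_floor`) rejects candidates whose
#' self-fold minimum free energy is below the floor.
#'
#' @param length_range Probe length range in nt, within \[12, 40\].
#' @param gc_range Allowed GC fraction.
#' @param min_mismatch_nontarget Minimum mismatches required against every
#'   non-target record.
#' @param mfe_floor Self-structure MFE floor, kcal/mol (<= 0); candidates
#'   with `self_mfe < mfe_floor` are rejected.
#' @param tm_range Allowed melting temperature window, degrees C, at the
#'   design condition.
#' @param min_target_coverage Minimum fraction of target records carrying a
#'   perfect-match site.
#' @param max_report Maximum number of ranked probes reported.
#' @return A list with class `design_params`.
#' @export
design_params <- function(length_range = c(18L, 22L),
                          gc_range = c(0.40, 0.60),
                          min_mismatch_nontarget = 2L,
                          mfe_floor = -2.0,
                          tm_range = c(54, 66),
                          min_target_coverage = 1.0,
                          max_report = 50L) {
  stopifnot(
    length(length_range) == 2, length_range[1] <= length_range[2],
    length_range[1] >= 12, length_range[2] <= 40,
    gc_range[1] >= 0, gc_range[2] <= 1, gc_range[1] <= gc_range[2],
    mfe_floor <= 0, min_target_coverage >= 0, min_target_coverage <= 1,
    max_report >= 1
  )
  structure(
    list(
      length_range = as.integer(length_range), gc_range = gc_range,
      min_mismatch_nontarget = as.integer(min_mismatch_nontarget),
      mfe_floor = mfe_floor, tm_range = tm_range,
      min_target_coverage = min_target_coverage,
      max_report = as.integer(max_report)
    ),
    class = "design_params"
  )
}

#' @export
print.design_params <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<design_params> length %d-%d nt, GC %.0f-%.0f%%, >=%d mismatches to\n",
      "  non-targets, self-MFE floor %.1f kcal/mol, Tm %.0f-%.0f C,\n",
      "  target coverage >= %.2f, report <= %d probes\n"
    ),
    x$length_range[1], x$length_range[2], 100 * x$gc_range[1],
    100 * x$gc_range[2], x$min_mismatch_nontarget, x$mfe_floor,
    x$tm_range[1], x$tm_range[2], x$min_target_coverage, x$max_report
  ))
  invisible(x)
}

#' GC content of concrete sequences
#'
#' @param seq Character vector of non-empty A/C/G/T strings.
#' @return Numeric vector, (#G + #C) / length.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence", call. = FALSE)
  if (any(grepl("[^ACGT]", seq))) {
    stop("gc_content() requires concrete A/C/G/T sequences (expand first)",
      call. = FALSE
    )
  }
  (nchar(gsub("[^GC]", "", seq))) / nchar(seq)
}

#' Enumerate candidate probes from a target species
#'
#' Every window of every allowed length over the first target record yields
#' one candidate (the window's reverse complement, 5'->3'). Windows that
#' contain degenerate codes are dropped (probes are synthesized concrete).
#' No thermodynamics are computed at this stage; candidates are annotated
#' with GC content only and ordered by (start, length).
#'
#' @param targets Tibble of records, all with the same species label.
#' @param params [design_params()].
#' @return Tibble of candidates: `target_species`, `ref_id`, `start`,
#'   `length`, `window_seq`, `probe_seq`, `gc`, `gc_pass`.
#' @export
enumerate_candidates <- function(targets, params = design_params()) {
  stopifnot(nrow(targets) >= 1)
  if (length(unique(targets$species)) != 1L) {
    stop("all target records must share one species label", call. = FALSE)
  }
  ref <- targets[1, ]
  lens <- seq(params$length_range[1], params$length_range[2])
  if (ref$length < min(lens)) {
    stop(
      "target record ", ref$id, " (", ref$length,
      " nt) is shorter than the minimum probe length", call. = FALSE
    )
  }
  lens <- lens[lens <= ref$length]
  grid <- tidyr::expand_grid(
    start = seq_len(ref$length),
    length = lens
  ) |>
    dplyr::filter(.data$start + .data$length - 1L <= ref$length) |>
    dplyr::arrange(.data$start, .data$length)
  window_seq <- substring(ref$seq, grid$start, grid$start + grid$length - 1L)
  concrete <- !grepl("[^ACGT]", window_seq)
  out <- tibble::tibble(
    target_species = ref$species,
    ref_id = ref$id,
    start = grid$start,
    length = grid$length,
    window_seq = window_seq,
    probe_seq = NA_character_,
    gc = NA_real_
  )
  out$probe_seq[concrete] <- revcomp(window_seq[concrete])
  out$gc[concrete] <- gc_content(window_seq[concrete])
  out <- out[concrete, , drop = FALSE]
  out$gc_pass <- out$gc >= params$gc_range[1] & out$gc <= params$gc_range[2]
  out
}

#' Fraction of target records carrying a perfect-match site
#'
#' A species-level probe must label every strain of the species, so coverage
#' is the fraction of target records containing a window with zero
#' mismatches to the probe (sense-strand comparison of the probe's reverse
#' complement).
#'
#' @param probe_seq Character vector of concrete probes.
#' @param targets Tibble of target records (non-empty).
#' @return Numeric vector of coverage fractions, one per probe.
#' @export
target_coverage <- function(probe_seq, targets) {
  if (nrow(targets) == 0L) stop("empty target list", call. = FALSE)
  if (length(probe_seq) == 0L) return(numeric(0))
  scan <- cpp_min_mismatch_multi(revcomp(probe_seq), targets$seq)
  mm <- scan[, 2 * seq_len(nrow(targets)) - 1, drop = FALSE]
  rowMeans(mm == 0L)
}
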