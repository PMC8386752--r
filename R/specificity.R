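# Mismatch-based specificity screening and in-silico staining prediction.
#
# Specificity is combinatorial: the probe's reverse complement is compared
# against every length-matched sense-strand window of each non-target
# record and the minimum Hamming distance decides the screen. Comparison is
# ungapped (18-22 nt probe/rRNA duplexes); degenerate subject positions
# count as a match iff the probe base lies in the code's set. All positions
# weigh equally.

#' Minimum mismatches of a probe against a subject record
#'
#' Compares `revcomp(probe_seq)` against every length-matched sense-strand
#' window of the subject and returns the minimum Hamming distance and its
#' leftmost 1-based position.
#'
#' @param probe_seq Single concrete A/C/G/T probe (5'->3', antisense).
#' @param subject A subject sequence (character) or a one-row record tibble.
#' @return List with `count` and `pos`.
#' @export
min_mismatches <- function(probe_seq, subject) {
  subject_seq <- if (is.character(subject)) subject else subject$seq
  stopifnot(length(probe_seq) == 1L, length(subject_seq) == 1L)
  if (nchar(probe_seq) > nchar(subject_seq)) {
    stop("probe longer than subject", call. = FALSE)
  }
  counts <- cpp_window_mismatches(revcomp(probe_seq), subject_seq)
  list(count = min(counts), pos = which.min(counts))
}

#' Screen candidate probes against the non-target database
#'
#' For each candidate, computes the minimum mismatch count over every
#' non-target record, the nearest off-target record and position, the list
#' of sub-threshold off-target hits, and the target coverage. A candidate
#' passes iff `min_mismatch_nontarget >= params$min_mismatch_nontarget` and
#' `target_coverage >= params$min_target_coverage`.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()] (any
#'   tibble with `probe_seq` and `target_species`).
#' @param db Full reference tibble containing target and non-target records.
#' @param params [design_params()].
#' @return `candidates` with columns `min_mismatch_nontarget`,
#'   `nearest_offtarget_id`, `nearest_offtarget_pos`, `offtarget_hits`
#'   (list-column of tibbles sorted by mismatches then id),
#'   `target_coverage`, and `spec_pass` appended.
#' @export
screen_specificity <- function(candidates, db, params = design_params()) {
  stopifnot(nrow(candidates) >= 1)
  species <- unique(candidates$target_species)
  stopifnot(length(species) == 1L)
  parts <- split_target(db, species)
  if (nrow(parts$nontarget) == 0L) {
    stop("empty non-target set: specificity screen is meaningless",
      call. = FALSE
    )
  }
  nt <- parts$nontarget
  rc <- revcomp(candidates$probe_seq)
  scan <- cpp_min_mismatch_multi(rc, nt$seq)
  mm <- scan[, 2 * seq_len(nrow(nt)) - 1, drop = FALSE]
  pos <- scan[, 2 * seq_len(nrow(nt)), drop = FALSE]
  best <- apply(mm, 1, which.min)
  candidates$min_mismatch_nontarget <-
    as.integer(mm[cbind(seq_len(nrow(mm)), best)])
  candidates$nearest_offtarget_id <- nt$id[best]
  candidates$nearest_offtarget_pos <- as.integer(pos[cbind(seq_len(nrow(pos)), best)])
  candidates$offtarget_hits <- purrr::map(seq_len(nrow(mm)), function(k) {
    sub <- mm[k, ] < params$min_mismatch_nontarget
    hits <- tibble::tibble(
      id = nt$id[sub], mismatches = as.integer(mm[k, sub]),
      pos = as.integer(pos[k, sub])
    )
    hits[order(hits$mismatches, hits$id), , drop = FALSE]
  })
  candidates$target_coverage <- target_coverage(candidates$probe_seq, parts$target)
  candidates$spec_pass <-
    candidates$min_mismatch_nontarget >= params$min_mismatch_nontarget &
      candidates$target_coverage >= params$min_target_coverage
  candidates
}

#' Predict an in-silico FISH staining matrix
#'
#' The in-silico analog of the wet-lab probe-specificity controls: a probe
#' "stains" a taxon iff some record of that taxon carries a site with fewer
#' than `rule` mismatches (the default `rule = 1` is perfect-match-only
#' staining). Universal positive controls (a probe against a conserved
#' block) and nonsense negative controls are handled like any other probe
#' row.
#'
#' @param probes Tibble with columns `name` and `probe_seq`.
#' @param community Record tibble (the community to stain).
#' @param rule Mismatch reject distance; stain iff `min_mismatch < rule`.
#' @param taxa Optional taxa to stain against (default: every species in
#'   the community). Unknown labels are an error.
#' @return A long tibble (`probe`, `taxon`, `stained`) with class
#'   `stain_matrix` and attribute `rule`.
#' @export
predict_staining <- function(probes, community, rule = 1L, taxa = NULL) {
  stopifnot(nrow(probes) >= 1, nrow(community) >= 1)
  present <- unique(community$species)
  if (is.null(taxa)) {
    taxa <- present
  } else if (!all(taxa %in% present)) {
    stop(
      "unknown taxon label(s): ",
      paste(setdiff(taxa, present), collapse = ", "),
      call. = FALSE
    )
  }
  grid <- tidyr::expand_grid(probe = probes$name, taxon = taxa)
  seq_of <- stats::setNames(probes$probe_seq, probes$name)
  grid$stained <- purrr::map2_lgl(grid$probe, grid$taxon, function(pn, tx) {
    p <- seq_of[[pn]]
    rc <- revcomp(p)
    recs <- community$seq[community$species == tx]
    any(purrr::map_lgl(recs, function(s) {
      min(cpp_window_mismatches(rc, s)) < rule
    }))
  })
  structure(grid, class = c("stain_matrix", class(grid)), rule = as.integer(rule))
}

#' Widen a staining matrix to probes x taxa
#'
#' @param x A `stain_matrix`.
#' @return Tibble, one row per probe, logical columns per taxon.
#' @export
stain_wide <- function(x) {
  tidyr::pivot_wider(
    tibble::as_tibble(x),
    names_from = "taxon", values_from = "stained"
  )
}

#' Universal and nonsense control probes for a community
#'
#' Builds the in-silico analogs of the canonical universal-bacterial
#' positive control and its nonsense negative control: the universal probe
#' is the antisense of a window inside a conserved block (so it should stain
#' every taxon), and the nonsense probe is the reverse complement of the
#' universal probe's target-facing sequence (so it should stain none).
#'
#' @param db Record tibble from [simulate_community()].
#' @param conserved_start 1-based start of the conserved window used.
#' @param length Probe length.
#' @return Tibble with `name` and `probe_seq` for the two controls.
#' @export
control_probes <- function(db, conserved_start = 30L, length = 18L) {
  win <- substring(db$seq[1], conserved_start, conserved_start + length - 1L)
  tibble::tibble(
    name = c("UNIV", "NONSENSE"),
    probe_seq = c(revcomp(win), win)
  )
}
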