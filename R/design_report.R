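# Pipeline orchestration, ranking, nomenclature, and the result file.
#
# design_probes() runs enumerate -> composition filter -> specificity
# screen -> thermodynamics -> self-structure filter -> rank, and the result
# file carries the free energy of every reported candidate so the user can
# pick the most appropriate probe.

REPORT_COLUMNS <- c(
  "name", "target_species", "probe_seq", "start", "length", "gc_pct",
  "tm_c", "dg37_kcal_mol", "self_mfe_kcal_mol", "min_mismatch_nontarget",
  "target_coverage", "rank"
)

#' Derive a short probe name stem from a species label
#'
#' Genus initial plus the first three letters of the species epithet
#' ("Bacteroides fragilis" -> "Bfra").
#'
#' @param species Binomial species label.
#' @return Short name, <= 4 characters.
#' @export
species_short_name <- function(species) {
  purrr::map_chr(species, function(sp) {
    parts <- strsplit(trimws(sp), "\\s+")[[1]]
    if (length(parts) >= 2) {
      paste0(
        toupper(substr(parts[1], 1, 1)),
        tolower(substr(parts[2], 1, 3))
      )
    } else {
      substr(gsub("[^A-Za-z]", "", sp), 1, 4)
    }
  })
}

#' Name a probe by the rRNA-targeted probe nomenclature
#'
#' Species-level probes are named `S-S-<Name>-<position, zero-padded to
#' 4>-<version>-A-<length>`; domain-level controls use `S-D-...`. The
#' position is the probe's 5'-most sense-strand coordinate.
#'
#' @param target_label Short name stem, 1--4 alphanumeric characters.
#' @param position 1-based target position; must fit the 4-digit field.
#' @param version Version letter ("a", "b", ...).
#' @param length Probe length, >= 12 nt.
#' @param level `"species"` or `"domain"`.
#' @return The probe name.
#' @export
#' @examples
#' name_probe("Bfra", 123, "a", 18) # "S-S-Bfra-0123-a-A-18"
name_probe <- function(target_label, position, version = "a", length = 18L,
                       level = c("species", "domain")) {
  level <- match.arg(level)
  if (!grepl("^[A-Za-z][A-Za-z0-9]{0,3}$", target_label)) {
    stop("malformed short name: ", target_label, call. = FALSE)
  }
  stopifnot(position >= 1, length >= 12)
  if (position > 9999) {
    stop("position ", position, " exceeds the 4-digit field", call. = FALSE)
  }
  sprintf(
    "S-%s-%s-%04d-%s-A-%d",
    if (level == "species") "S" else "D",
    target_label, as.integer(position), version, as.integer(length)
  )
}

#' Rank fully annotated candidates
#'
#' Lexicographic ranking: more mismatches to the nearest non-target first,
#' then self-fold MFE closest to zero (least self-structure), then Tm
#' closest to 10 degrees above the hybridization temperature, then smaller
#' start, then sequence.
#'
#' @param rows Candidate tibble carrying `min_mismatch_nontarget`,
#'   `self_mfe`, `tm_c`, `start`, `probe_seq`.
#' @param condition [hybridization_condition()].
#' @return `rows` reordered, with a `rank` column.
#' @export
rank_candidates <- function(rows, condition = hybridization_condition()) {
  need <- c("min_mismatch_nontarget", "self_mfe", "tm_c", "start", "probe_seq")
  missing_col <- setdiff(need, names(rows))
  if (length(missing_col) > 0 ||
    (nrow(rows) > 0 && anyNA(rows[need]))) {
    stop("rank_candidates() requires fully annotated rows", call. = FALSE)
  }
  out <- dplyr::arrange(
    rows,
    dplyr::desc(.data$min_mismatch_nontarget),
    dplyr::desc(.data$self_mfe),
    abs(.data$tm_c - condition$temp_c - 10),
    .data$start,
    .data$probe_seq
  )
  out$rank <- seq_len(nrow(out))
  out
}

#' Design species-specific FISH probes
#'
#' Full pipeline: enumerate candidate antisense oligos from the target
#' species' reference record, filter on GC content, screen specificity
#' against every non-target record, annotate nearest-neighbor
#' thermodynamics and filter on the Tm window, fold each survivor and
#' reject stable self-structures, then rank and name the survivors. The
#' report is empty (with a warning) when no candidate passes.
#'
#' @param target_species Species label present in `db`.
#' @param db Reference tibble with target and non-target records.
#' @param params [design_params()].
#' @param condition [hybridization_condition()]. Self-structure is folded
#'   at `condition$temp_c`.
#' @return A `probe_report`: tibble of ranked passing candidates with
#'   attributes `params`, `condition`, `provenance`, `target_species`, and
#'   `n_enumerated`.
#' @export
design_probes <- function(target_species, db,
                          params = design_params(),
                          condition = hybridization_condition()) {
  parts <- split_target(db, target_species)
  if (nrow(parts$nontarget) == 0L) {
    stop("database has no non-target records", call. = FALSE)
  }
  cand <- enumerate_candidates(parts$target, params)
  n_enumerated <- nrow(cand)
  cand <- dplyr::filter(cand, .data$gc_pass)
  rows <- cand[0, ]
  if (nrow(cand) > 0) {
    th <- nn_thermo(cand$probe_seq, condition)
    cand$tm_c <- th$tm_c
    cand$dg37 <- th$dg37
    cand <- dplyr::filter(
      cand,
      .data$tm_c >= params$tm_range[1], .data$tm_c <= params$tm_range[2]
    )
  }
  if (nrow(cand) > 0) {
    cand <- add_self_structure(cand, temp_c = condition$temp_c)
    cand <- dplyr::filter(cand, .data$self_mfe >= params$mfe_floor)
  }
  if (nrow(cand) > 0) {
    cand <- screen_specificity(cand, db, params)
    rows <- dplyr::filter(cand, .data$spec_pass)
  }
  if (nrow(rows) == 0L) {
    warning(
      "no specific region: no candidate passed for ", target_species,
      call. = FALSE
    )
    rows <- tibble::tibble(
      target_species = character(0), ref_id = character(0),
      start = integer(0), length = integer(0), probe_seq = character(0),
      gc = numeric(0), tm_c = numeric(0), dg37 = numeric(0),
      self_mfe = numeric(0), min_mismatch_nontarget = integer(0),
      target_coverage = numeric(0), rank = integer(0), name = character(0)
    )
  } else {
    rows <- rank_candidates(rows, condition)
    rows <- utils::head(rows, params$max_report)
    rows$rank <- seq_len(nrow(rows))
    short <- species_short_name(target_species)
    rows <- rows |>
      dplyr::group_by(.data$start) |>
      dplyr::mutate(version = letters[dplyr::row_number()]) |>
      dplyr::ungroup()
    rows$name <- purrr::pmap_chr(
      list(rows$start, rows$version, rows$length),
      function(st, v, len) name_probe(short, st, v, len)
    )
    rows$version <- NULL
  }
  provenance <- list(
    tool = "fishdesign", version = as.character(utils::packageVersion("fishdesign")),
    db_digest = rlang::hash(db[c("id", "seq")]),
    fluorophore = "5'-FAM (annotation only; not modeled thermodynamically)"
  )
  structure(
    rows,
    class = c("probe_report", class(tibble::tibble())),
    params = params, condition = condition, provenance = provenance,
    target_species = target_species, n_enumerated = n_enumerated
  )
}

#' Write a probe design report
#'
#' Tab-separated result file with a fixed column contract (including the
#' self-fold free-energy column for every row), floats to 2 decimals, and
#' optionally a FASTA of the probe sequences.
#'
#' @param report A `probe_report`.
#' @param path Output TSV path.
#' @param probes_fasta Optional path for a probe FASTA.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, probes_fasta = NULL) {
  rows <- tibble::as_tibble(report)
  out <- tibble::tibble(
    name = rows$name,
    target_species = rows$target_species,
    probe_seq = rows$probe_seq,
    start = rows$start,
    length = rows$length,
    gc_pct = sprintf("%.2f", 100 * rows$gc),
    tm_c = sprintf("%.2f", rows$tm_c),
    dg37_kcal_mol = sprintf("%.2f", rows$dg37),
    self_mfe_kcal_mol = sprintf("%.2f", rows$self_mfe),
    min_mismatch_nontarget = rows$min_mismatch_nontarget,
    target_coverage = sprintf("%.2f", rows$target_coverage),
    rank = rows$rank
  )
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(probes_fasta)) {
    set <- Biostrings::BStringSet(rows$probe_seq)
    names(set) <- rows$name
    Biostrings::writeXStringSet(set, probes_fasta, width = 80L)
  }
  invisible(path)
}

#' Read a probe design report written by [write_report()]
#'
#' @param path TSV path.
#' @return Tibble with the report columns (numerics parsed).
#' @export
read_report <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      name = readr::col_character(),
      target_species = readr::col_character(),
      probe_seq = readr::col_character(),
      start = readr::col_integer(),
      length = readr::col_integer(),
      gc_pct = readr::col_double(),
      tm_c = readr::col_double(),
      dg37_kcal_mol = readr::col_double(),
      self_mfe_kcal_mol = readr::col_double(),
      min_mismatch_nontarget = readr::col_integer(),
      target_coverage = readr::col_double(),
      rank = readr::col_integer()
    ),
    progress = FALSE
  )
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf(
    "<probe_report> %s: %d passing probe(s) of %d enumerated candidates\n",
    attr(x, "target_species"), nrow(x), attr(x, "n_enumerated")
  ))
  NextMethod()
}
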