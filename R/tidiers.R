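# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a probe report
#'
#' @param x A `probe_report` from [design_probes()].
#' @param ... Unused.
#' @return A plain tibble of the ranked probe rows.
#' @export
tidy.probe_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a probe design run
#'
#' @param x A `probe_report`.
#' @param ... Unused.
#' @return Tibble with one row: target species, candidates enumerated,
#'   probes passing, and the best probe's key statistics.
#' @export
glance.probe_report <- function(x, ...) {
  tibble::tibble(
    target_species = attr(x, "target_species"),
    n_enumerated = attr(x, "n_enumerated"),
    n_passing = nrow(x),
    best_probe = if (nrow(x) > 0) x$name[1] else NA_character_,
    best_min_mismatch = if (nrow(x) > 0) x$min_mismatch_nontarget[1] else NA_integer_,
    best_self_mfe = if (nrow(x) > 0) x$self_mfe[1] else NA_real_,
    best_tm_c = if (nrow(x) > 0) x$tm_c[1] else NA_real_
  )
}

#' Tidy a QC result
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return Tibble with one row per input read: `id`, `kept`, `reasons`.
#' @export
tidy.qc_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = x$kept$id, kept = TRUE, reasons = ""),
    tibble::tibble(
      id = x$rejected$id, kept = FALSE,
      reasons = purrr::map_chr(x$rejected$reasons, paste, collapse = ",")
    )
  )
}

#' One-row summary of a QC run
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return Tibble with input/kept/rejected counts and per-reason counts.
#' @export
glance.qc_result <- function(x, ...) {
  tibble::tibble(
    profile = x$profile,
    n_input = x$input_n,
    n_kept = nrow(x$kept),
    n_rejected = nrow(x$rejected),
    n_len = x$counts[["LEN"]],
    n_qual = x$counts[["QUAL"]],
    n_ambig = x$counts[["AMBIG"]],
    n_hqfrac = x$counts[["HQFRAC"]]
  )
}
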