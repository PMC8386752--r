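# Nearest-neighbor duplex thermodynamics.
#
# Duplex stability is the sum of published nearest-neighbor stack enthalpies
# and entropies plus terminal initiation terms (unified DNA/DNA parameter
# set, shipped as a plain-text table under inst/extdata with its literature
# source in the header). Tm is computed from the two-state model with an
# entropy-based monovalent-salt correction, and formamide stringency is a
# linear Tm depression. The package environment caches the parsed table.

.thermo_cache <- new.env(parent = emptyenv())

GAS_CONSTANT <- 1.9872 # cal / (mol K)

#' Nearest-neighbor stack parameter table
#'
#' @param table Which parameter set to load; currently only `"dna"` (the
#'   unified DNA/DNA set) ships with the package. The accessor is the hook
#'   for a DNA/RNA hybrid table.
#' @return Tibble with columns `dinuc`, `dh` (kcal/mol), `ds` (cal/mol/K).
#' @export
nn_table <- function(table = "dna") {
  key <- paste0("nn_", table)
  if (is.null(.thermo_cache[[key]])) {
    path <- system.file("extdata",
      switch(table, dna = "nn_stacks_dna.tsv",
        stop("unknown NN table: ", table, call. = FALSE)
      ),
      package = "fishdesign"
    )
    .thermo_cache[[key]] <- readr::read_tsv(path,
      comment = "#",
      col_types = readr::cols(
        dinuc = readr::col_character(),
        dh = readr::col_double(), ds = readr::col_double()
      ),
      progress = FALSE
    )
  }
  .thermo_cache[[key]]
}

#' Hybridization buffer condition
#'
#' Container for the hybridization conditions under which Tm is evaluated.
#' Defaults mirror a standard rRNA-FISH hybridization buffer: 0.9 M NaCl,
#' no formamide, 46 degrees C, with 5e-7 M total oligo strand concentration
#' for the two-state Tm.
#'
#' @param na_molar Monovalent cation concentration, mol/L. Must be > 0.
#' @param formamide_pct Formamide, percent v/v, in \[0, 80\].
#' @param temp_c Hybridization temperature, degrees C.
#' @param probe_conc_molar Total strand concentration C_T for Tm, mol/L.
#' @return A list with class `hybridization_condition`.
#' @export
hybridization_condition <- function(na_molar = 0.9, formamide_pct = 0,
                                    temp_c = 46, probe_conc_molar = 5e-7) {
  stopifnot(na_molar > 0, probe_conc_molar > 0)
  if (formamide_pct < 0 || formamide_pct > 80) {
    stop("formamide_pct must be in [0, 80]", call. = FALSE)
  }
  structure(
    list(
      na_molar = na_molar, formamide_pct = formamide_pct,
      temp_c = temp_c, probe_conc_molar = probe_conc_molar
    ),
    class = "hybridization_condition"
  )
}

#' @export
print.hybridization_condition <- function(x, ...) {
  cat(sprintf(
    "<hybridization_condition> %.2g M Na+, %g%% formamide, %.1f C, C_T = %.2g M\n",
    x$na_molar, x$formamide_pct, x$temp_c, x$probe_conc_molar
  ))
  invisible(x)
}

#' Nearest-neighbor duplex thermodynamics for probe sequences
#'
#' Sums stack and initiation enthalpies/entropies over each probe sequence
#' and derives the standard free energy at 37 C and the two-state melting
#' temperature under the supplied hybridization condition. The salt
#' correction is entropic (0.368 x N_stacks x ln\[Na+\] cal/mol/K added to
#' delta-S before the Tm quotient); `dg37` is reported at the 1 M reference
#' state so that `dg37 == dh - 310.15 * ds / 1000` exactly. Formamide
#' depresses Tm linearly via [formamide_adjusted_tm()].
#'
#' @param probe_seq Character vector of concrete A/C/G/T sequences,
#'   8--40 nt each.
#' @param condition A [hybridization_condition()].
#' @return Tibble with columns `probe_seq`, `dh` (kcal/mol), `ds`
#'   (cal/mol/K), `dg37` (kcal/mol), `tm_c` (degrees C at the condition,
#'   formamide included).
#' @export
nn_thermo <- function(probe_seq, condition = hybridization_condition()) {
  stopifnot(inherits(condition, "hybridization_condition"))
  lens <- nchar(probe_seq)
  if (any(lens < 8 | lens > 40)) {
    stop("nn_thermo() requires sequence lengths in [8, 40]", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", probe_seq))) {
    stop("nn_thermo() requires concrete A/C/G/T sequences", call. = FALSE)
  }
  tab <- nn_table("dna")
  dh_map <- stats::setNames(tab$dh, tab$dinuc)
  ds_map <- stats::setNames(tab$ds, tab$dinuc)

  sums <- purrr::map(probe_seq, function(s) {
    n <- nchar(s)
    dinucs <- substring(s, 1:(n - 1), 2:n)
    ends <- c(substring(s, 1, 1), substring(s, n, n))
    init <- ifelse(ends %in% c("A", "T"), "init_AT", "init_GC")
    c(
      dh = sum(dh_map[dinucs]) + sum(dh_map[init]),
      ds = sum(ds_map[dinucs]) + sum(ds_map[init])
    )
  })
  dh <- purrr::map_dbl(sums, "dh")
  ds <- purrr::map_dbl(sums, "ds")
  dg37 <- dh - 310.15 * ds / 1000
  ds_salt <- ds + 0.368 * (lens - 1) * log(condition$na_molar)
  tm_k <- dh * 1000 /
    (ds_salt + GAS_CONSTANT * log(condition$probe_conc_molar / 4))
  tm_c <- formamide_adjusted_tm(tm_k - 273.15, condition$formamide_pct)
  tibble::tibble(probe_seq = probe_seq, dh = dh, ds = ds, dg37 = dg37, tm_c = tm_c)
}

#' Formamide-adjusted melting temperature
#'
#' Linear Tm depression by formamide: `tm_c - k * formamide_pct`. The
#' coefficient defaults to 0.65 degrees C per percent formamide, the
#' accepted value for short DNA duplexes, and may be set within
#' \[0.6, 0.72\].
#'
#' @param tm_c Melting temperature(s), degrees C, at 0% formamide.
#' @param formamide_pct Formamide percentage in \[0, 80\].
#' @param k Depression coefficient, degrees C per percent.
#' @return Adjusted Tm, degrees C.
#' @export
formamide_adjusted_tm <- function(tm_c, formamide_pct, k = 0.65) {
  if (any(formamide_pct < 0 | formamide_pct > 80)) {
    stop("formamide_pct must be in [0, 80]", call. = FALSE)
  }
  if (k < 0.6 || k > 0.72) {
    stop("formamide coefficient k must be in [0.6, 0.72]", call. = FALSE)
  }
  tm_c - k * formamide_pct
}
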