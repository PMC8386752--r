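# Sequence input/output and IUPAC alphabet utilities.
#
# Sequences are stored sense-strand (the 16S gene as sequenced); probes are
# antisense and are always derived via revcomp(). All records live in plain
# tibbles with one row per sequence so the rest of the package can chain
# dplyr verbs over them.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N"
)

#' Normalize a nucleotide string to the internal alphabet
#'
#' Uppercases, converts U to T, and validates against the IUPAC alphabet.
#'
#' @param seq Character vector of nucleotide strings.
#' @param what Label used in error messages.
#' @return Character vector of normalized sequences.
#' @keywords internal
normalize_seq <- function(seq, what = "sequence") {
  seq <- chartr("u", "T", toupper(seq))
  seq <- chartr("U", "T", seq)
  bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_CODES), collapse = "")), seq)
  if (any(bad)) {
    stop(sprintf(
      "%s contains non-IUPAC characters: %s",
      what, paste(utils::head(seq[bad], 3), collapse = ", ")
    ), call. = FALSE)
  }
  if (any(!nzchar(seq))) {
    stop(sprintf("%s must be non-empty", what), call. = FALSE)
  }
  seq
}

parse_taxonomy_header <- function(header, taxonomy_from = "semicolon") {
  if (!identical(taxonomy_from, "semicolon")) {
    stop("unknown taxonomy_from dialect: ", taxonomy_from, call. = FALSE)
  }
  header <- trimws(header)
  pos_ws <- regexpr("\\s", header)[[1]]
  pos_semi <- regexpr(";", header, fixed = TRUE)[[1]]
  if (pos_semi > 0 && (pos_ws < 0 || pos_semi < pos_ws)) {
    # id;family;genus;species (no whitespace before the first semicolon)
    id <- substr(header, 1, pos_semi - 1)
    tax <- substr(header, pos_semi + 1, nchar(header))
  } else if (pos_ws > 0) {
    # id family;genus;species
    id <- substr(header, 1, pos_ws - 1)
    tax <- trimws(substr(header, pos_ws + 1, nchar(header)))
  } else {
    id <- header
    tax <- ""
  }
  ranks <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
  length(ranks) <- 3L
  ranks[is.na(ranks)] <- ""
  list(id = id, family = ranks[[1]], genus = ranks[[2]], species = ranks[[3]])
}

#' Read a taxonomy-tagged FASTA file
#'
#' Reads a FASTA file of 16S gene sequences whose headers carry taxonomy
#' labels. The default header dialect is semicolon-delimited ranks
#' (family;genus;species) following either the first whitespace or, when the
#' header has no whitespace, the first semicolon after the record id.
#' Sequences are uppercased and U is normalized to T on load.
#'
#' @param path Path to a FASTA file.
#' @param taxonomy_from Header-parsing dialect; only `"semicolon"` is defined.
#' @return A tibble with columns `id`, `family`, `genus`, `species`, `seq`,
#'   and `length`, one row per record, input order preserved.
#' @export
read_fasta <- function(path, taxonomy_from = "semicolon") {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path, call. = FALSE)
  parsed <- purrr::map(names(set), parse_taxonomy_header,
    taxonomy_from = taxonomy_from
  )
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(
      "record(s) with empty sequence: ",
      paste(purrr::map_chr(parsed[empty], "id"), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- purrr::map_chr(parsed, "id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate record id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_seq(unname(seqs), what = "sequence")
  tibble::tibble(
    id = ids,
    family = purrr::map_chr(parsed, "family"),
    genus = purrr::map_chr(parsed, "genus"),
    species = purrr::map_chr(parsed, "species"),
    seq = seqs,
    length = nchar(seqs)
  )
}

#' Write a taxonomy-tagged FASTA file
#'
#' Inverse of [read_fasta()]: headers are written as
#' `id family;genus;species` so that a read/write round trip preserves ids,
#' taxonomy, and sequences.
#'
#' @param db Tibble with columns `id`, `family`, `genus`, `species`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  stopifnot(all(c("id", "family", "genus", "species", "seq") %in% names(db)))
  set <- Biostrings::BStringSet(db$seq)
  names(set) <- sprintf("%s %s;%s;%s", db$id, db$family, db$genus, db$species)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Degenerate codes are complemented by their set complements (R to Y, K to M,
#' B to V, D to H; S, W, and N are self-complementary). U is normalized to T
#' first. Vectorized over `seq`.
#'
#' @param seq Character vector over the IUPAC alphabet.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAAC") # "GTTT"
revcomp <- function(seq) {
  seq <- normalize_seq(seq, what = "revcomp() input")
  comp <- chartr(
    paste(names(IUPAC_COMPLEMENT), collapse = ""),
    paste(unname(IUPAC_COMPLEMENT), collapse = ""),
    seq
  )
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
}

#' Expand a degenerate IUPAC string into concrete sequences
#'
#' Returns every concrete A/C/G/T realization of a possibly degenerate
#' sequence, in lexicographic order. The expansion count is the product of the
#' cardinalities of the codes; an error is raised when it exceeds `cap`.
#'
#' @param seq Single IUPAC string.
#' @param cap Maximum number of expansions allowed.
#' @return Character vector of concrete sequences.
#' @export
#' @examples
#' expand_degenerate("AR") # "AA" "AG"
expand_degenerate <- function(seq, cap = 4096L) {
  stopifnot(length(seq) == 1L, cap >= 1)
  seq <- normalize_seq(seq, what = "expand_degenerate() input")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sets <- strsplit(unname(IUPAC_CODES[chars]), "", fixed = TRUE)
  n <- prod(lengths(sets))
  if (n > cap) {
    stop(sprintf("expansion count %d exceeds cap %d", n, as.integer(cap)),
      call. = FALSE
    )
  }
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Partition a reference database into target and non-target records
#'
#' @param db Tibble of records as returned by [read_fasta()].
#' @param target_species Species label of the design target.
#' @return List with tibbles `target` and `nontarget`; the two partition `db`.
#' @export
split_target <- function(db, target_species) {
  stopifnot("species" %in% names(db))
  hit <- db$species == target_species
  if (!any(hit)) {
    stop("target species not found in database: ", target_species, call. = FALSE)
  }
  list(target = db[hit, , drop = FALSE], nontarget = db[!hit, , drop = FALSE])
}
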