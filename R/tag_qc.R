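# Read/tag quality control.
#
# Two filter profiles used for sequencing QC:
#  * amplicon tags: keep iff 220 <= length <= 500 (inclusive), mean Phred
#    >= 20, and at most 3 ambiguous N bases;
#  * metagenomic reads: (1) remove reads with more than 3 N, (2) trim
#    3'-terminal bases with Q < 20 (longest suffix of sub-threshold bases;
#    a both-ends mode is available), (3) delete reads whose post-trim
#    fraction of bases with Phred >= 20 is below 60%.
# Reason codes: LEN, QUAL, AMBIG, HQFRAC.

new_qc_result <- function(kept, rejected, input_n, profile) {
  reasons <- unlist(rejected$reasons)
  counts <- table(factor(reasons, levels = c("LEN", "QUAL", "AMBIG", "HQFRAC")))
  structure(
    list(
      kept = kept, rejected = rejected,
      counts = stats::setNames(as.integer(counts), names(counts)),
      input_n = input_n, profile = profile
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf(
    "<qc_result> profile %s: %d in, %d kept, %d rejected (%s)\n",
    x$profile, x$input_n, nrow(x$kept), nrow(x$rejected),
    paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", ")
  ))
  invisible(x)
}

count_n <- function(seq) nchar(seq) - nchar(gsub("N", "", seq, fixed = TRUE))

#' Quality filter for 16S amplicon tags
#'
#' Keeps a tag iff its length lies in `len_range` (inclusive on both ends),
#' the average Phred score of its bases is at least `min_mean_q`, and it
#' carries no more than `max_ambig` ambiguous N bases. Every failing reason
#' is recorded. Tags are judged as given (no trimming).
#'
#' @param reads Tibble with `id`, `seq`, `qual` (list of integer Phred).
#' @param len_range Inclusive length bounds in bp.
#' @param min_mean_q Minimum mean Phred.
#' @param max_ambig Maximum N count.
#' @return A `qc_result`: list with tibbles `kept` and `rejected` (with
#'   list-column `reasons`), and per-reason `counts`.
#' @export
qc_filter_tags <- function(reads, len_range = c(220L, 500L),
                           min_mean_q = 20, max_ambig = 3L) {
  if (nrow(reads) == 0L) {
    return(new_qc_result(reads, tibble::tibble(
      id = character(0), reasons = list()
    ), 0L, "tag"))
  }
  len <- nchar(reads$seq)
  meanq <- purrr::map_dbl(reads$qual, mean)
  n_amb <- count_n(reads$seq)
  reasons <- purrr::pmap(list(len, meanq, n_amb), function(l, q, a) {
    r <- character(0)
    if (l < len_range[1] || l > len_range[2]) r <- c(r, "LEN")
    if (q < min_mean_q) r <- c(r, "QUAL")
    if (a > max_ambig) r <- c(r, "AMBIG")
    r
  })
  keep <- lengths(reasons) == 0L
  new_qc_result(
    kept = reads[keep, , drop = FALSE],
    rejected = tibble::tibble(id = reads$id[!keep], reasons = reasons[!keep]),
    input_n = nrow(reads), profile = "tag"
  )
}

trim_low_q <- function(seq, qual, trim_q, mode) {
  n <- length(qual)
  lo <- 1L
  hi <- n
  while (hi >= lo && qual[hi] < trim_q) hi <- hi - 1L
  if (mode == "both-ends") {
    while (lo <= hi && qual[lo] < trim_q) lo <- lo + 1L
  }
  if (hi < lo) {
    list(seq = "", qual = integer(0))
  } else {
    list(seq = substring(seq, lo, hi), qual = qual[lo:hi])
  }
}

#' Quality filter for metagenomic reads
#'
#' Applies, in order: (1) remove reads containing more than `max_ambig` N
#' bases; (2) trim terminal bases with Phred < `trim_q` (3' suffix by
#' default, or both ends); (3) delete reads whose post-trim fraction of
#' high-quality bases (Phred >= `trim_q`) is below `min_hq_frac`. Kept reads
#' are returned trimmed.
#'
#' @inheritParams qc_filter_tags
#' @param trim_q Quality threshold for trimming and the high-quality
#'   fraction.
#' @param min_hq_frac Minimum post-trim fraction of bases with Phred >=
#'   `trim_q`.
#' @param trim_mode `"suffix"` (3' only) or `"both-ends"`.
#' @return A `qc_result`.
#' @export
qc_filter_metagenomic <- function(reads, max_ambig = 3L, trim_q = 20,
                                  min_hq_frac = 0.60,
                                  trim_mode = c("suffix", "both-ends")) {
  trim_mode <- match.arg(trim_mode)
  if (nrow(reads) == 0L) {
    return(new_qc_result(reads, tibble::tibble(
      id = character(0), reasons = list()
    ), 0L, "metagenomic"))
  }
  n_amb <- count_n(reads$seq)
  ambig <- n_amb > max_ambig
  kept_rows <- list()
  rej_ids <- character(0)
  rej_reasons <- list()
  for (k in seq_len(nrow(reads))) {
    if (ambig[k]) {
      rej_ids <- c(rej_ids, reads$id[k])
      rej_reasons <- c(rej_reasons, list("AMBIG"))
      next
    }
    tr <- trim_low_q(reads$seq[k], reads$qual[[k]], trim_q, trim_mode)
    hq <- if (length(tr$qual) == 0L) 0 else mean(tr$qual >= trim_q)
    if (hq < min_hq_frac) {
      rej_ids <- c(rej_ids, reads$id[k])
      rej_reasons <- c(rej_reasons, list("HQFRAC"))
    } else {
      kept_rows[[length(kept_rows) + 1L]] <- tibble::tibble(
        id = reads$id[k], seq = tr$seq, qual = list(tr$qual)
      )
    }
  }
  kept <- if (length(kept_rows) > 0) {
    dplyr::bind_rows(kept_rows)
  } else {
    reads[0, , drop = FALSE]
  }
  new_qc_result(
    kept = kept,
    rejected = tibble::tibble(id = rej_ids, reasons = rej_reasons),
    input_n = nrow(reads), profile = "metagenomic"
  )
}
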