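# Independent oracles and fixture builders shared across the suite.
# Everything here deliberately avoids the package's own fast paths: the
# mismatch scan is a plain double loop over windows, and the
# nearest-neighbor sum re-reads the shipped table with base R.

random_seq <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# naive window scan: revcomp(probe) against every sense window, plain loops
naive_min_mismatch <- function(probe, subject) {
  rc <- revcomp(probe)
  pc <- strsplit(rc, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  L <- length(pc)
  m <- length(sc)
  best <- L + 1L
  bestpos <- NA_integer_
  for (off in 0:(m - L)) {
    mm <- 0L
    for (k in seq_len(L)) {
      if (!(pc[k] %in% IUPAC_SETS[[sc[off + k]]])) mm <- mm + 1L
    }
    if (mm < best) {
      best <- mm
      bestpos <- off + 1L
    }
  }
  list(count = best, pos = bestpos)
}

# independent nearest-neighbor summation straight off the shipped table
naive_nn_sum <- function(seq) {
  path <- system.file("extdata", "nn_stacks_dna.tsv", package = "fishdesign")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  dh <- 0
  ds <- 0
  ch <- strsplit(seq, "")[[1]]
  for (k in seq_len(length(ch) - 1)) {
    row <- tab[tab$dinuc == paste0(ch[k], ch[k + 1]), ]
    dh <- dh + row$dh
    ds <- ds + row$ds
  }
  for (end in c(ch[1], ch[length(ch)])) {
    key <- if (end %in% c("A", "T")) "init_AT" else "init_GC"
    row <- tab[tab$dinuc == key, ]
    dh <- dh + row$dh
    ds <- ds + row$ds
  }
  list(dh = dh, ds = ds, dg37 = dh - 310.15 * ds / 1000)
}

# per-community window-matrix cache for fast naive re-screens
make_window_index <- function(db, lengths) {
  purrr::map(stats::setNames(db$seq, db$id), function(s) {
    sc <- strsplit(s, "")[[1]]
    purrr::map(stats::setNames(lengths, lengths), function(L) {
      nwin <- length(sc) - L + 1
      matrix(sc[outer(seq_len(L) - 1L, seq_len(nwin), "+")], nrow = L)
    })
  })
}

naive_min_mm_indexed <- function(probe, index_record) {
  pc <- strsplit(revcomp(probe), "")[[1]]
  mat <- index_record[[as.character(length(pc))]]
  min(colSums(mat != pc))
}

default_planted_range <- function() {
  sp <- community_spec()
  c(sp$planted_region[1], sp$planted_region[1] + sp$planted_region[2] - 1)
}

make_read <- function(id, seq, quals) {
  tibble::tibble(id = id, seq = seq, qual = list(as.integer(quals)))
}
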