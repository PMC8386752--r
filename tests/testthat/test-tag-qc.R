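test_that("tag filter boundary behavior matches the stated bounds exactly", {
  reads <- dplyr::bind_rows(
    make_read("len219", random_seq(219), rep(30L, 219)),
    make_read("len220", random_seq(220), rep(30L, 220)),
    make_read("len500", random_seq(500), rep(30L, 500)),
    make_read("len501", random_seq(501), rep(30L, 501)),
    make_read("q1999", random_seq(300), c(rep(20L, 297), rep(19L, 3))), # mean 19.99
    make_read("q20", random_seq(300), rep(20L, 300)),
    make_read("n3", paste0(strrep("N", 3), random_seq(297)), rep(35L, 300)),
    make_read("n4", paste0(strrep("N", 4), random_seq(296)), rep(35L, 300))
  )
  res <- qc_filter_tags(reads)
  expect_setequal(res$kept$id, c("len220", "len500", "q20", "n3"))
  reason_of <- stats::setNames(res$rejected$reasons, res$rejected$id)
  expect_identical(reason_of[["len219"]], "LEN")
  expect_identical(reason_of[["len501"]], "LEN")
  expect_identical(reason_of[["q1999"]], "QUAL")
  expect_identical(reason_of[["n4"]], "AMBIG")
})

test_that("tag filter records every failing reason", {
  r <- make_read("multi", paste0(strrep("N", 5), random_seq(100)), rep(10L, 105))
  res <- qc_filter_tags(r)
  expect_setequal(res$rejected$reasons[[1]], c("LEN", "QUAL", "AMBIG"))
  expect_equal(res$counts[["LEN"]], 1L)
  expect_equal(res$counts[["QUAL"]], 1L)
  expect_equal(res$counts[["AMBIG"]], 1L)
})

test_that("metagenomic filter applies its three steps in order", {
  reads <- dplyr::bind_rows(
    # >3 N removed at step 1 regardless of quality
    make_read("ambig", paste0(strrep("N", 4), random_seq(96)), rep(40L, 100)),
    # suffix of Q10 trimmed, rest kept at 90 bp
    make_read("trim", random_seq(100), c(rep(30L, 90), rep(10L, 10))),
    # post-trim 59/100 high-quality -> deleted
    make_read("hq59", random_seq(101), c(rep(30L, 59), rep(15L, 41), 30L)),
    # all good
    make_read("clean", random_seq(80), rep(35L, 80))
  )
  res <- qc_filter_metagenomic(reads)
  expect_setequal(res$kept$id, c("trim", "clean"))
  expect_equal(nchar(res$kept$seq[res$kept$id == "trim"]), 90L)
  reason_of <- stats::setNames(res$rejected$reasons, res$rejected$id)
  expect_identical(reason_of[["ambig"]], "AMBIG")
  expect_identical(reason_of[["hq59"]], "HQFRAC")
})

test_that("suffix trimming removes only the terminal low-quality run", {
  # internal low-Q bases stay and count against the 60% rule
  r <- make_read("mid", random_seq(50), c(rep(30L, 20), rep(10L, 10), rep(30L, 15), rep(5L, 5)))
  res <- qc_filter_metagenomic(r)
  expect_equal(nchar(res$kept$seq), 45L)
  expect_equal(res$kept$qual[[1]][21:30], rep(10L, 10))
})

test_that("both-ends trim mode also removes the 5' low-quality run", {
  r <- make_read("ends", random_seq(60), c(rep(5L, 5), rep(30L, 50), rep(5L, 5)))
  suf <- qc_filter_metagenomic(r, trim_mode = "suffix")
  both <- qc_filter_metagenomic(r, trim_mode = "both-ends")
  expect_equal(nchar(suf$kept$seq), 55L)
  expect_equal(nchar(both$kept$seq), 50L)
})

test_that("an all-low-quality read trims to nothing and is deleted", {
  r <- make_read("allbad", random_seq(40), rep(5L, 40))
  res <- qc_filter_metagenomic(r)
  expect_equal(nrow(res$kept), 0L)
  expect_identical(res$rejected$reasons[[1]], "HQFRAC")
})

test_that("QC partitions the input and is idempotent", {
  sp <- community_spec(seed = 41)
  db <- simulate_community(sp)
  reads <- simulate_reads(db,
    n = 1000, length_range = c(180, 520),
    q_mean = 24, q_sd = 8, n_rate = 0.005, seed = 42
  )
  for (res in list(qc_filter_tags(reads), qc_filter_metagenomic(reads))) {
    expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(reads))
    expect_setequal(c(res$kept$id, res$rejected$id), reads$id)
    expect_true(all(lengths(res$rejected$reasons) >= 1))
    expect_gte(sum(res$counts), nrow(res$rejected))
  }
  # idempotence: filtering the kept set again changes nothing
  t1 <- qc_filter_tags(reads)
  t2 <- qc_filter_tags(t1$kept)
  expect_identical(t2$kept, t1$kept)
  expect_equal(nrow(t2$rejected), 0L)
  m1 <- qc_filter_metagenomic(reads)
  m2 <- qc_filter_metagenomic(m1$kept)
  expect_identical(m2$kept, m1$kept)
  expect_equal(nrow(m2$rejected), 0L)
})

test_that("with clean high-quality reads only length bounds reject tags", {
  sp <- community_spec(seed = 43)
  db <- simulate_community(sp)
  reads <- simulate_reads(db,
    n = 500, length_range = c(200, 540),
    q_mean = 30, q_sd = 0, n_rate = 0, seed = 44
  )
  res <- qc_filter_tags(reads)
  lens <- nchar(reads$seq)
  expect_equal(nrow(res$kept), sum(lens >= 220 & lens <= 500))
  expect_true(all(unlist(res$rejected$reasons) == "LEN"))
})

test_that("empty input yields an empty result", {
  empty <- tibble::tibble(id = character(0), seq = character(0), qual = list())
  res <- qc_filter_tags(empty)
  expect_equal(res$input_n, 0L)
  expect_equal(nrow(res$kept), 0L)
})
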