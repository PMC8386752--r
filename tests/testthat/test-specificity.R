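mutate_at <- function(s, pos, to = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) {
    ch[p] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else to
  }
  paste(ch, collapse = "")
}

rec <- function(id, seq, species = "Sp x") {
  tibble::tibble(
    id = id, family = "", genus = "Gen", species = species,
    seq = seq, length = nchar(seq)
  )
}

test_that("min_mismatches finds self-matches at their position", {
  withr::local_seed(61)
  subject <- random_seq(120)
  p <- 40L
  probe <- revcomp(substring(subject, p, p + 17))
  got <- min_mismatches(probe, subject)
  expect_equal(got$count, 0L)
  expect_equal(got$pos, p)
})

test_that("min_mismatches reports the leftmost best window", {
  got <- min_mismatches(strrep("T", 18), strrep("A", 100))
  expect_equal(got$count, 0L)
  expect_equal(got$pos, 1L)
})

test_that("min_mismatches locates a constructed 2-mismatch best window", {
  withr::local_seed(67)
  subject <- random_seq(150)
  p <- 77L
  window <- substring(subject, p, p + 17)
  probe <- revcomp(mutate_at(window, c(4, 11))) # 2 planted mismatches
  oracle <- naive_min_mismatch(probe, subject)
  got <- min_mismatches(probe, subject)
  expect_equal(got, oracle)
  expect_lte(got$count, 2L)
})

test_that("window scan equals the naive double loop, degenerate codes included", {
  withr::local_seed(71)
  alpha_deg <- c(rep(c("A", "C", "G", "T"), 10), "R", "Y", "N", "S", "W")
  for (k in 1:25) {
    subject <- random_seq(sample(40:90, 1), alphabet = alpha_deg)
    probe <- random_seq(18)
    expect_identical(min_mismatches(probe, subject), naive_min_mismatch(probe, subject))
  }
})

test_that("degenerate subject positions match iff the probe base is in the code set", {
  subject <- paste0(strrep("G", 20), "ANRT", strrep("G", 20))
  # window "ANRT" at 21..24: probe matching A,C,G,T versus code sets
  expect_equal(min_mismatches(revcomp("AAGT"), subject)$count, 0L) # A in N, G in R
  expect_equal(min_mismatches(revcomp("ACCT"), subject)$count, 1L) # C in N, C not in R
  expect_error(min_mismatches(strrep("A", 80), subject), "longer than subject")
})

test_that("specificity screen separates planted, conserved, and near-miss candidates", {
  sp <- community_spec(
    seed = 9, n_species = 3L, strains_per_species = 2L, gene_length = 400L,
    conserved_blocks = list(c(1L, 60L), c(200L, 60L)),
    planted_region = c(100L, 30L)
  )
  db <- simulate_community(sp)
  params <- design_params(length_range = c(18L, 18L))
  target <- split_target(db, db$species[1])$target

  planted_cand <- enumerate_candidates(target, params) |>
    dplyr::filter(.data$start >= 100, .data$start + .data$length - 1 <= 129)
  scr <- screen_specificity(planted_cand, db, params)
  expect_true(all(scr$min_mismatch_nontarget >= sp$d_min))
  expect_true(all(scr$target_coverage == 1))
  expect_true(all(scr$spec_pass))

  conserved_cand <- enumerate_candidates(target, params) |>
    dplyr::filter(.data$start >= 1, .data$start + .data$length - 1 <= 60) |>
    utils::head(5)
  scr2 <- screen_specificity(conserved_cand, db, params)
  expect_true(all(scr2$min_mismatch_nontarget == 0L))
  expect_false(any(scr2$spec_pass))
  expect_true(all(purrr::map_int(scr2$offtarget_hits, nrow) > 0))
})

test_that("a single-site off-target difference fails the screen and is reported", {
  withr::local_seed(73)
  base <- random_seq(200)
  probe_window <- substring(base, 90, 107)
  db <- dplyr::bind_rows(
    rec("t1", base, "Sp target"),
    rec("n1", mutate_at(base, 99), "Sp near"), # one in-window substitution
    rec("n2", paste0(random_seq(100), substring(base, 101, 200)), "Sp far")
  )
  cand <- tibble::tibble(
    target_species = "Sp target", ref_id = "t1", start = 90L, length = 18L,
    window_seq = probe_window, probe_seq = revcomp(probe_window),
    gc = gc_content(probe_window), gc_pass = TRUE
  )
  scr <- screen_specificity(cand, db, design_params(min_mismatch_nontarget = 2L))
  expect_equal(scr$min_mismatch_nontarget, 1L)
  expect_equal(scr$nearest_offtarget_id, "n1")
  expect_false(scr$spec_pass)
  expect_true("n1" %in% scr$offtarget_hits[[1]]$id)
})

test_that("screening without non-targets is an error", {
  db <- rec("only", random_seq(100), "Sp solo")
  cand <- enumerate_candidates(db, design_params())
  expect_error(screen_specificity(cand, db, design_params()), "non-target")
})

test_that("universal, nonsense, and absent-species controls behave as designed", {
  sp <- community_spec(seed = 13)
  db <- simulate_community(sp)
  ctl <- control_probes(db)
  stains <- predict_staining(ctl, db, rule = 1L)
  wide <- stain_wide(stains)
  univ <- unlist(wide[wide$probe == "UNIV", -1])
  nons <- unlist(wide[wide$probe == "NONSENSE", -1])
  expect_true(all(univ)) # conserved-block probe stains every taxon
  expect_false(any(nons)) # reverse-complement nonsense probe stains none

  # probe designed for a species, stained against a community lacking it
  rep5 <- design_probes("Synthcoccus sp05", db)
  without5 <- db[db$species != "Synthcoccus sp05", ]
  row <- predict_staining(
    tibble::tibble(name = rep5$name[1], probe_seq = rep5$probe_seq[1]),
    without5,
    rule = 1L
  )
  expect_false(any(row$stained))

  expect_error(predict_staining(ctl, db, taxa = "Synthcoccus sp99"), "unknown taxon")
})

test_that("congeneric panel stains are diagonal at the perfect-match rule", {
  sp <- community_spec(seed = 31, n_species = 8L, strains_per_species = 2L)
  db <- simulate_community(sp)
  species <- unique(db$species)
  probes <- dplyr::bind_rows(purrr::map(species, function(s) {
    r <- design_probes(s, db)
    tibble::tibble(name = r$name[1], probe_seq = r$probe_seq[1], species = s)
  }))
  stains <- predict_staining(probes[, c("name", "probe_seq")], db, rule = 1L)
  for (k in seq_along(species)) {
    row <- stains[stains$probe == probes$name[k], ]
    expect_identical(row$taxon[row$stained], species[k])
  }
})
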