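test_that("probe nomenclature follows the naming grammar", {
  expect_identical(name_probe("Bfra", 123, "a", 18), "S-S-Bfra-0123-a-A-18")
  expect_identical(
    name_probe("Bact", 338, "a", 18, level = "domain"),
    "S-D-Bact-0338-a-A-18"
  )
  expect_error(name_probe("Bfra", 12345, "a", 18), "4-digit")
  expect_error(name_probe("B fra", 12, "a", 18), "malformed short name")
  expect_error(name_probe("Toolong5", 12, "a", 18), "malformed short name")
  expect_identical(species_short_name("Bacteroides fragilis"), "Bfra")
})

test_that("ranking prefers specificity, then weakest self-structure, then Tm fit", {
  cond <- hybridization_condition(temp_c = 46)
  rows <- tibble::tibble(
    probe_seq = c("AAAA", "CCCC", "GGGG", "TTTT"),
    min_mismatch_nontarget = c(2L, 4L, 4L, 4L),
    self_mfe = c(0, -1.5, 0, 0),
    tm_c = c(56, 56, 56, 60),
    start = c(1L, 5L, 9L, 2L)
  )
  ranked <- rank_candidates(rows, cond)
  # mismatch 4 beats 2; mfe 0 beats -1.5; Tm 56 (= 46+10) beats 60
  expect_equal(ranked$probe_seq, c("GGGG", "TTTT", "CCCC", "AAAA"))
  expect_equal(ranked$rank, 1:4)

  tied <- tibble::tibble(
    probe_seq = c("AAAA", "CCCC"), min_mismatch_nontarget = 3L,
    self_mfe = 0, tm_c = 56, start = c(9L, 2L)
  )
  expect_equal(rank_candidates(tied, cond)$start, c(2L, 9L))
  expect_error(
    rank_candidates(dplyr::mutate(rows, self_mfe = NA_real_), cond),
    "fully annotated"
  )
})

test_that("design recovers the planted region and every probe survives a naive re-screen", {
  sp <- community_spec(seed = 47)
  db <- simulate_community(sp)
  params <- design_params()
  rep1 <- design_probes("Synthcoccus sp02", db, params)
  r <- tidy(rep1)
  expect_gt(nrow(r), 0)
  planted <- default_planted_range()
  expect_true(any(r$start >= planted[1] & (r$start + r$length - 1) <= planted[2]))

  # post-hoc filter soundness
  expect_true(all(r$self_mfe >= params$mfe_floor))
  expect_true(all(r$min_mismatch_nontarget >= params$min_mismatch_nontarget))
  expect_true(all(r$target_coverage >= params$min_target_coverage))
  expect_true(all(r$gc >= 0.40 & r$gc <= 0.60))
  expect_true(all(r$tm_c >= 54 & r$tm_c <= 66))

  # independent naive re-screen of the top rows
  nt <- db[db$species != "Synthcoccus sp02", ]
  idx <- make_window_index(nt, 18:22)
  for (k in seq_len(min(5, nrow(r)))) {
    mm <- min(purrr::map_int(idx, function(recidx) {
      as.integer(naive_min_mm_indexed(r$probe_seq[k], recidx))
    }))
    expect_identical(mm, as.integer(r$min_mismatch_nontarget[k]))
    expect_gte(mm, params$min_mismatch_nontarget)
  }
})

test_that("a target identical to a non-target yields an empty report with a warning", {
  withr::local_seed(53)
  s <- random_seq(300)
  db <- tibble::tibble(
    id = c("t1", "n1"), family = "", genus = "",
    species = c("Sp target", "Sp twin"), seq = s, length = 300L
  )
  expect_warning(
    rep0 <- design_probes("Sp target", db),
    "no specific region"
  )
  expect_equal(nrow(rep0), 0L)
  expect_equal(nrow(glance(rep0)), 1L)
})

test_that("reports are deterministic and byte-identical across reruns", {
  sp <- community_spec(seed = 59, n_species = 3L, strains_per_species = 2L,
    gene_length = 600L,
    conserved_blocks = list(c(1L, 80L), c(450L, 80L)),
    planted_region = c(200L, 30L))
  db <- simulate_community(sp)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_report(design_probes(db$species[1], db), f1, probes_fasta = fa1)
  write_report(design_probes(db$species[1], db), f2, probes_fasta = fa2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(fa1)), unname(tools::md5sum(fa2)))
})

test_that("the result file round-trips its key fields and always carries the MFE column", {
  sp <- community_spec(seed = 59, n_species = 3L, strains_per_species = 2L,
    gene_length = 600L,
    conserved_blocks = list(c(1L, 80L), c(450L, 80L)),
    planted_region = c(200L, 30L))
  db <- simulate_community(sp)
  rep1 <- design_probes(db$species[1], db)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep1, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(rep1) + 1L)
  expect_identical(
    strsplit(lines[1], "\t")[[1]],
    c(
      "name", "target_species", "probe_seq", "start", "length", "gc_pct",
      "tm_c", "dg37_kcal_mol", "self_mfe_kcal_mol",
      "min_mismatch_nontarget", "target_coverage", "rank"
    )
  )
  back <- read_report(path)
  expect_equal(back$name, rep1$name)
  expect_equal(back$probe_seq, rep1$probe_seq)
  expect_equal(back$start, rep1$start)
  expect_equal(back$length, rep1$length)
  expect_equal(back$rank, rep1$rank)
  expect_equal(back$min_mismatch_nontarget, rep1$min_mismatch_nontarget)
  expect_false(any(is.na(back$self_mfe_kcal_mol)))
})

test_that("tidy and glance summarize a report", {
  sp <- community_spec(seed = 59, n_species = 3L, strains_per_species = 2L,
    gene_length = 600L,
    conserved_blocks = list(c(1L, 80L), c(450L, 80L)),
    planted_region = c(200L, 30L))
  db <- simulate_community(sp)
  rep1 <- design_probes(db$species[1], db)
  td <- tidy(rep1)
  expect_false(inherits(td, "probe_report"))
  gl <- glance(rep1)
  expect_equal(gl$n_passing, nrow(rep1))
  expect_equal(gl$best_probe, rep1$name[1])
  p <- autoplot(rep1)
  expect_s3_class(p, "ggplot")
})

test_that("YAML config mirrors the parameter constructors", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "design:",
    "  length_range: [18, 20]",
    "  gc_range: [0.45, 0.55]",
    "  min_mismatch_nontarget: 3",
    "hybridization:",
    "  na_molar: 0.9",
    "  formamide_pct: 20",
    "  temp_c: 46"
  ), path)
  cfg <- read_config(path)
  expect_equal(cfg$params$length_range, c(18L, 20L))
  expect_equal(cfg$params$min_mismatch_nontarget, 3L)
  expect_equal(cfg$params$mfe_floor, -2.0) # default preserved
  expect_equal(cfg$condition$formamide_pct, 20)
  writeLines(c("design:", "  bogus_key: 1"), path)
  expect_error(read_config(path), "unknown config key")
})
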