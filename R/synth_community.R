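# Synthetic 16S-like communities.
#
# Real 16S genes are a mosaic of blocks conserved across taxa and
# hypervariable regions carrying species-specific signal. The generator
# emulates exactly that architecture: a shared backbone, conserved blocks
# identical in every record, diverged variable blocks, and a planted
# species-specific region per species whose separation from every other
# species is *enforced* (rejection-resampled), not merely expected, so that
# downstream probe design has a guaranteed recoverable answer. All
# randomness flows from a single seed.

#' Specification of a synthetic 16S community
#'
#' @param seed Integer seed driving all randomness.
#' @param n_species Number of species.
#' @param strains_per_species Strains (records) per species; strain 1 is the
#'   species reference sequence.
#' @param gene_length Gene length in nt.
#' @param conserved_blocks List of `c(start, length)` blocks identical across
#'   all records (16S conserved stretches).
#' @param variable_blocks Optional list of `c(start, length)`; defaults to
#'   the complement of the conserved blocks.
#' @param within_species_divergence Per-site substitution rate between
#'   strains of one species, applied outside conserved blocks and outside
#'   the planted region; must be in \[0, 0.1\].
#' @param planted_region `c(start, length)` of the species-specific planted
#'   region (one locus, a different random variant per species), or NULL for
#'   none.
#' @param variable_divergence Per-site substitution rate of variable blocks
#'   from the backbone, between species.
#' @param d_min Minimum mismatch separation: every `window`-nt window of a
#'   species' planted region must be at least `d_min` mismatches from the
#'   best-matching window of every other species' gene.
#' @param window Window length used for the separation guarantee.
#' @param genus,family Taxonomy labels shared by all synthetic species
#'   (congeneric by default, mirroring the hardest specificity setting).
#' @return A list with class `community_spec`.
#' @export
community_spec <- function(seed = 1L,
                           n_species = 5L,
                           strains_per_species = 3L,
                           gene_length = 1500L,
                           conserved_blocks = list(
                             c(1L, 100L), c(350L, 120L), c(750L, 120L),
                             c(1150L, 100L), c(1401L, 100L)
                           ),
                           variable_blocks = NULL,
                           within_species_divergence = 0.01,
                           planted_region = c(520L, 30L),
                           variable_divergence = 0.05,
                           d_min = 4L,
                           window = 18L,
                           genus = "Synthcoccus",
                           family = "Synthetaceae") {
  stopifnot(
    n_species >= 1, strains_per_species >= 1, gene_length >= 100,
    within_species_divergence >= 0, within_species_divergence <= 0.1
  )
  blocks <- conserved_blocks
  if (!is.null(planted_region)) {
    if (planted_region[2] < window) {
      stop(
        "planted region shorter than the separation window (",
        window, " nt): separation cannot be guaranteed",
        call. = FALSE
      )
    }
    blocks <- c(blocks, list(planted_region))
  }
  ends <- purrr::map_int(blocks, ~ as.integer(.x[1] + .x[2] - 1L))
  starts <- purrr::map_int(blocks, ~ as.integer(.x[1]))
  if (any(ends > gene_length) || any(starts < 1)) {
    stop("blocks fall outside the gene", call. = FALSE)
  }
  ord <- order(starts)
  if (any(starts[ord][-1] <= ends[ord][-length(ord)])) {
    stop("blocks overlap", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), n_species = as.integer(n_species),
      strains_per_species = as.integer(strains_per_species),
      gene_length = as.integer(gene_length),
      conserved_blocks = conserved_blocks,
      variable_blocks = variable_blocks,
      within_species_divergence = within_species_divergence,
      planted_region = planted_region,
      variable_divergence = variable_divergence,
      d_min = as.integer(d_min), window = as.integer(window),
      genus = genus, family = family
    ),
    class = "community_spec"
  )
}

block_mask <- function(blocks, n) {
  m <- rep(FALSE, n)
  for (b in blocks) m[seq(b[1], b[1] + b[2] - 1)] <- TRUE
  m
}

mutate_positions <- function(chars, idx, rate) {
  hit <- idx[stats::runif(length(idx)) < rate]
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
  }
  chars
}

# balanced-composition random region (rRNA variable regions are not
# compositionally extreme); GC fraction drawn within [0.45, 0.55]
draw_planted <- function(len) {
  repeat {
    x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    gc <- mean(x %in% c("C", "G"))
    if (gc >= 0.45 && gc <= 0.55) {
      return(x)
    }
  }
}

min_mm_vs <- function(win_seqs, subject_seq) {
  min(purrr::map_int(win_seqs, function(w) {
    min(cpp_window_mismatches(revcomp(w), subject_seq))
  }))
}

# The planted region exists to be recoverable: require at least one window
# that would survive the default composition, Tm, and self-structure
# filters, so that probe design on the community has a guaranteed answer.
planted_designable <- function(region_chars,
                               params = design_params(),
                               condition = hybridization_condition()) {
  region <- paste(region_chars, collapse = "")
  lens <- seq(params$length_range[1], min(params$length_range[2], nchar(region)))
  for (L in lens) {
    wins <- substring(region, 1:(nchar(region) - L + 1), L:nchar(region))
    gc <- gc_content(wins)
    ok <- gc >= params$gc_range[1] & gc <= params$gc_range[2]
    if (!any(ok)) next
    probes <- revcomp(wins[ok])
    tm <- nn_thermo(probes, condition)$tm_c
    probes <- probes[tm >= params$tm_range[1] & tm <= params$tm_range[2]]
    for (p in probes) {
      if (fold_mfe(p, temp_c = condition$temp_c)$mfe >= params$mfe_floor) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Simulate a taxonomy-labelled synthetic 16S community
#'
#' Deterministic given the spec's seed. Conserved blocks are identical in
#' every record; each species carries its own variant of the planted region,
#' rejection-resampled until (i) every `window`-nt window of it is at least
#' `d_min` mismatches from the best-matching window of every other species'
#' full gene and (ii) the region admits at least one window that survives
#' the default composition, Tm, and self-structure design filters (the
#' planted region exists to be recoverable, so designability is enforced by
#' construction, like the separation guarantee, rather than merely
#' expected); strains within a species differ only by
#' `within_species_divergence` substitutions outside conserved blocks and
#' outside the planted region.
#'
#' @param spec A [community_spec()].
#' @param max_resample Resampling attempts before declaring the spec
#'   infeasible.
#' @return Tibble of records (`id`, `family`, `genus`, `species`, `seq`,
#'   `length`), `strains_per_species` rows per species.
#' @export
simulate_community <- function(spec, max_resample = 200L) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$gene_length
    backbone <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    cons <- block_mask(spec$conserved_blocks, n)
    planted_idx <- integer(0)
    if (!is.null(spec$planted_region)) {
      planted_idx <- seq(
        spec$planted_region[1],
        spec$planted_region[1] + spec$planted_region[2] - 1
      )
    }
    var_idx <- if (is.null(spec$variable_blocks)) {
      setdiff(which(!cons), planted_idx)
    } else {
      setdiff(which(block_mask(spec$variable_blocks, n)), planted_idx)
    }

    draw_planted_designable <- function(len) {
      attempts <- 0L
      repeat {
        x <- draw_planted(len)
        if (planted_designable(x)) {
          return(x)
        }
        attempts <- attempts + 1L
        if (attempts > max_resample) {
          stop("infeasible community spec: no designable planted region found",
            call. = FALSE
          )
        }
      }
    }

    refs <- vector("list", spec$n_species)
    for (k in seq_len(spec$n_species)) {
      chars <- backbone
      chars <- mutate_positions(chars, var_idx, spec$variable_divergence)
      if (length(planted_idx) > 0) {
        chars[planted_idx] <- draw_planted_designable(length(planted_idx))
      }
      refs[[k]] <- chars
    }

    # enforce planted-region separation by rejection resampling
    if (length(planted_idx) > 0 && spec$n_species > 1) {
      win <- spec$window
      windows_of <- function(chars) {
        reg <- paste(chars[planted_idx], collapse = "")
        substring(reg, 1:(nchar(reg) - win + 1), win:nchar(reg))
      }
      attempts <- 0L
      repeat {
        violation <- NULL
        for (a in seq_len(spec$n_species)) {
          for (b in seq_len(spec$n_species)) {
            if (a == b) next
            mm <- min_mm_vs(
              windows_of(refs[[a]]),
              paste(refs[[b]], collapse = "")
            )
            if (mm < spec$d_min) {
              violation <- a
              break
            }
          }
          if (!is.null(violation)) break
        }
        if (is.null(violation)) break
        attempts <- attempts + 1L
        if (attempts > max_resample) {
          stop("infeasible community spec: planted-region separation of ",
            spec$d_min, " mismatches could not be achieved",
            call. = FALSE
          )
        }
        refs[[violation]][planted_idx] <-
          draw_planted_designable(length(planted_idx))
      }
    }

    strain_idx <- var_idx # strains vary only in non-conserved, non-planted sites
    rows <- purrr::map(seq_len(spec$n_species), function(k) {
      species <- sprintf("%s sp%02d", spec$genus, k)
      purrr::map(seq_len(spec$strains_per_species), function(st) {
        chars <- refs[[k]]
        if (st > 1) {
          chars <- mutate_positions(chars, strain_idx, spec$within_species_divergence)
        }
        tibble::tibble(
          id = sprintf("sp%02d_st%d", k, st),
          family = spec$family, genus = spec$genus, species = species,
          seq = paste(chars, collapse = ""), length = n
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
}

#' Simulate FASTQ reads from a community
#'
#' Reads are drawn from random records and positions with per-base Phred
#' scores (normal around `q_mean`, clamped to \[2, 41\]) and ambiguous-base
#' substitutions at rate `n_rate`. Deterministic given `seed`.
#'
#' @param db Community tibble from [simulate_community()] or [read_fasta()].
#' @param n Number of reads.
#' @param length_range `c(min, max)` read length in bp.
#' @param q_mean,q_sd Mean and s.d. of the per-base Phred score.
#' @param n_rate Per-base probability of an N substitution.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `seq`, `qual` (list-column of integer
#'   Phred vectors).
#' @export
simulate_reads <- function(db, n, length_range = c(220L, 300L),
                           q_mean = 35, q_sd = 3, n_rate = 0.001,
                           seed = 1L) {
  stopifnot(n >= 1, length_range[1] <= length_range[2])
  if (length_range[2] > min(db$length)) {
    stop("length_range exceeds the shortest gene (", min(db$length), " nt)",
      call. = FALSE
    )
  }
  withr::with_seed(seed, {
    rec <- sample(nrow(db), n, replace = TRUE)
    len_choices <- seq.int(length_range[1], length_range[2])
    len <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
    start <- purrr::map2_int(rec, len, function(r, l) {
      sample(db$length[r] - l + 1L, 1L)
    })
    seqs <- substring(db$seq[rec], start, start + len - 1L)
    seqs <- purrr::map2_chr(seqs, len, function(s, l) {
      if (n_rate > 0) {
        hit <- which(stats::runif(l) < n_rate)
        if (length(hit) > 0) {
          ch <- strsplit(s, "", fixed = TRUE)[[1]]
          ch[hit] <- "N"
          s <- paste(ch, collapse = "")
        }
      }
      s
    })
    quals <- purrr::map(len, function(l) {
      pmin(pmax(as.integer(round(stats::rnorm(l, q_mean, q_sd))), 2L), 41L)
    })
    tibble::tibble(
      id = sprintf("read%06d", seq_len(n)),
      seq = seqs, qual = quals
    )
  })
}

#' Write reads to a FASTQ file (Sanger Phred+33)
#'
#' @param reads Tibble from [simulate_reads()] or [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual_str <- purrr::map_chr(reads$qual, function(q) {
    intToUtf8(q + 33L)
  })
  lines <- as.vector(rbind(
    paste0("@", reads$id), reads$seq, "+", qual_str
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (Sanger Phred+33)
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return Tibble with `id`, `seq`, `qual` (list-column of integer Phred).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own metadata columns here; benign
  set <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(set), "IntegerList")
  tibble::tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(as.character(set)),
    qual = unname(purrr::map(as.list(quals), function(q) unname(as.integer(q))))
  )
}
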