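---
title: "Designing species-specific 16S rRNA FISH probes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing species-specific 16S rRNA FISH probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fluorescence in situ hybridization (FISH) identifies bacterial taxa in fixed
cells with fluorophore-tagged oligonucleotides that bind ribosomal RNA. The
16S rRNA is a mosaic of stretches conserved across all bacteria and
hypervariable regions that differ between close relatives, which makes it
possible to design both universal probes (against conserved stretches) and
species-specific probes (against a variable window unique to the target).
`fishdesign` automates the species-specific case: given a target species and
a database of non-target 16S sequences, it proposes antisense oligos that

1. perfectly match every strain of the target species,
2. are separated by a minimum number of mismatches from every window of
   every non-target sequence,
3. have sensible composition and melting behavior under the hybridization
   buffer, and
4. do not fold on themselves into a stable secondary structure — the
   single most common mode of silent probe failure, and the reason the
   result file prints a free-energy column for every candidate.

## Pipeline and data model

Sequences are handled sense-strand (the 16S gene as sequenced); probes are
antisense and are always the reverse complement of a sense-strand window,
written 5'→3'. All containers are tibbles, so each stage is an ordinary
data-frame transformation:

```{r}
library(fishdesign)
db <- read_fasta("db.fasta")                      # id, taxonomy, seq
report <- design_probes("Bacteroides fragilis", db)
tidy(report)                                      # ranked candidate rows
glance(report)                                    # one-row run summary
autoplot(report)
```

`design_probes()` runs: window enumeration over the target's reference
record (the first record with the target label; the other strains enter
through target coverage) → GC filter → nearest-neighbor Tm filter →
self-structure filter → mismatch specificity screen → ranking and naming.
The stages are exported individually, so the pipeline can be re-assembled
or partially applied with ordinary pipes.

## Tunable parameters

`design_params()` holds the design thresholds. None of them are dictated
by theory; they encode common rRNA-FISH practice and are fully
configurable (also via the `design:` block of a YAML config):

| parameter | default | unit | why |
|---|---|---|---|
| `length_range` | 18–22 | nt | the practical span of rRNA FISH oligos: shorter probes lose specificity, longer ones lose mismatch discrimination |
| `gc_range` | 0.40–0.60 | fraction | avoids composition extremes with aberrant duplex stability |
| `min_mismatch_nontarget` | 2 | mismatches | a single central mismatch can be tolerated at hybridization stringency; two is the usual in-silico safety margin |
| `mfe_floor` | −2.0 | kcal/mol | candidates whose self-fold MFE is below the floor (more stable self-structure) are rejected; −2 kcal/mol separates incidental short stems from hairpins stable at hybridization temperature |
| `tm_range` | 54–66 | °C | brackets the canonical 46 °C hybridization so that stringency can be tuned with formamide rather than probe redesign |
| `min_target_coverage` | 1.0 | fraction | a species probe must label every strain of the species |
| `max_report` | 50 | probes | result-file cap; ranking makes the head of the file the useful part |

`hybridization_condition()` holds the buffer: 0.9 M monovalent salt, 0 %
formamide unless required, 46 °C, and a total strand concentration of
5×10⁻⁷ M for the two-state Tm.

## Nearest-neighbor thermodynamics

Duplex ΔH and ΔS are sums over adjacent base-pair stacks plus two terminal
initiation terms, using the unified DNA/DNA parameter set (shipped as a
plain-text table with its literature source in the header; `nn_table()` is
the hook where a DNA/RNA hybrid table could be swapped in — the probe
actually binds rRNA, but the DNA/DNA set is by far the best established,
so it is the reproducible default). Derived quantities:

* ΔG°37 = ΔH − 310.15·ΔS/1000, reported at the 1 M reference state, so the
  enthalpy–entropy identity holds to numerical precision by construction;
* Tm = 1000·ΔH / (ΔS + R·ln(C_T/4)) − 273.15, with the entropic salt
  correction ΔS → ΔS + 0.368·N_stacks·ln[Na⁺] applied first. One auditable
  correction path, not stacked heuristics. C_T/4 is the symmetric
  non-self-complementary assumption; we deliberately do not assume the
  probe is in excess over rRNA sites;
* formamide depresses Tm linearly at 0.65 °C per percent (configurable
  within 0.60–0.72, the empirical range for short duplexes).

## Self-structure: the MFE filter

A probe that folds on itself competes with probe–target hybridization, so
every candidate is folded at the hybridization temperature and its minimum
free energy printed in the result file. The folder is a self-contained
dynamic program over non-crossing structures with an intentionally compact
energy model ("Zuker-lite"):

* Watson–Crick pairs only by default; G·T wobble is available behind a
  flag. The wobble flag exists because a folder named for RNA was
  historically applied to these DNA probes; whether DNA probes should be
  folded with RNA-style pairing is genuinely ambiguous, so both modes are
  exposed and neither is asserted as canonical.
* stacking free energies from the same nearest-neighbor table, rescaled to
  temperature via ΔG(T) = ΔH − T·ΔS/1000;
* affine hairpin/bulge/internal loop penalties from a shipped table,
  treated as purely entropic (scaled by T/310.15), with
  Jacobson–Stockmayer extrapolation beyond the tabulated sizes;
* multiloops cost a + b·(branches) + c·(unpaired);
* hairpin loops hold at least 3 unpaired bases, and every helix has at
  least two consecutive pairs (no isolated pairs) — the minimal structure
  is therefore 7 nt, and these two constraints are stated explicitly
  because they change the MFE;
* no dangles, no coaxial stacking, no partition function. The filter only
  needs the MFE to threshold precision, and a compact model can be
  verified exhaustively.

That verification is the point: `brute_force_mfe()` enumerates *every*
admissible structure up to 22 nt with the identical energy function and
must agree with the dynamic program exactly. Ties between co-optimal
structures are broken deterministically on both sides — the leftmost
pairable position is paired with its smallest co-optimal partner, and a
structure extending a co-optimal prefix beats the bare prefix — so the test
can demand identical dot-bracket strings, not just equal energies.

## Specificity screening

Specificity is combinatorial, not thermodynamic: the probe's reverse
complement is compared against every length-matched sense-strand window of
every non-target record and the minimum Hamming distance decides the
screen. Degenerate IUPAC codes in the subject count as a match iff the
probe base is in the code's set (conservative: an N can always be the bad
base). Comparison is ungapped — over an 18–22 nt window an indel costs
several mismatches under the sliding scan, which is the desired behavior —
and all positions weigh equally; central-mismatch weighting is a config
extension point we deliberately did not default on, since there is no
calibration to anchor it. The threshold of 2 mismatches is a declared
reconstruction of standard practice.

`predict_staining()` turns the same comparator into an in-silico staining
matrix: a probe stains a taxon iff some record of the taxon has a site
with fewer than `rule` mismatches (default `rule = 1`: perfect-match-only
staining). This reproduces the bench control logic — a universal probe
against a conserved block must stain everything, its reverse-complement
nonsense probe must stain nothing, a probe whose species is absent from
the community must light no row, and congeneric panels must stain
diagonally.

## Ranking and nomenclature

The result file is sorted by (more mismatches to the nearest non-target,
self-MFE closest to zero, Tm closest to 10 °C above the hybridization
temperature, smaller start, sequence). The criterion is this package's own
deterministic default — the free-energy column exists precisely so users
can re-sort — and the Tm term simply prefers probes that survive a
stringency margin above the incubation temperature. Probes are named
`S-S-<Name>-<position 0-padded to 4>-<version>-A-<length>` (species level;
`S-D-` for domain-level controls), with the position being the probe's
5'-most sense coordinate and version letters assigned in rank order within
a position collision group. The 5'-fluorophore is recorded as report
metadata, not modeled thermodynamically.

## The synthetic community generator

Testing probe design requires communities where the right answer is known.
`simulate_community()` emulates the conserved/variable mosaic of real 16S
genes: a random backbone, conserved blocks byte-identical in every record,
variable blocks substituted at 5 % per site between species (the
within-genus figure for real 16S genes, whose congeneric identity is
typically ≥95 %), strains differing at 1 % per site outside conserved
blocks, and one planted 30-nt species-specific region per species at a
shared locus (like a hypervariable region, each species carrying its own
variant).

Two properties of the planted region are *enforced by rejection
resampling*, not merely expected, because downstream checks need a
guaranteed answer:

1. **separation** — every 18-nt window of a species' planted region is at
   least `d_min = 4` mismatches from the best-matching window of every
   other species' full gene (checking 18-nt windows suffices: any longer
   window contains one, so its distance can only be larger);
2. **designability** — the region admits at least one window that passes
   the default composition, Tm, and self-structure filters. Planted
   regions are drawn at 45–55 % GC (rRNA variable regions are not
   compositionally extreme), and a balanced random 30-mer occasionally has
   no window inside both the GC and the Tm windows; since the planted
   region exists to be recoverable, designability is part of its
   construction contract.

All randomness flows from the single seed in `community_spec()`; repeated
runs are byte-identical. What the generator does *not* emulate: indels,
rate heterogeneity across lineages, phylogenetic correlation between
species, chimeras, or realistic base composition gradients. Passing tests
therefore demonstrate the pipeline's logic and numerics, not performance
on real 16S databases, where paralogs and within-genus recombination make
specificity genuinely harder.

`simulate_reads()` produces seeded FASTQ with Gaussian per-base Phred
scores (clamped to [2, 41]) and Bernoulli N substitutions — enough
structure to exercise the QC filters, with no attempt at a realistic
sequencer error model.

## Read QC filters

Two profiles mirror standard amplicon/metagenomic practice:

* **tags**: keep iff 220 ≤ length ≤ 500 (both bounds inclusive — "between"
  is ambiguous, so inclusivity is declared), mean Phred ≥ 20, and ≤ 3 N.
  The mean-quality criterion is applied to the tag as given, with no prior
  trimming.
* **metagenomic**, in order: (1) drop reads with > 3 N; (2) trim the
  3'-terminal run of bases with Q < 20 — "trimmed" is read as 3'-suffix
  trimming, the common Illumina convention, with a `both-ends` mode
  available; internal low-quality bases are left in place and counted by
  (3): delete reads whose post-trim fraction of bases with Q ≥ 20 is
  below 60 %.

Every rejected read carries its full set of reason codes
({LEN, QUAL, AMBIG, HQFRAC}), kept + rejected partition the input exactly,
and both filters are idempotent on their own output.

## Numerical choices

* Energies are plain doubles; co-optimality in folding uses an absolute
  tolerance of 1e-7 kcal/mol (table entries are multiples of 0.1, so real
  near-ties below that tolerance do not occur).
* The enumeration oracle is capped at 22 nt (combinatorial blow-up), the
  dynamic program at 60 nt (probes only; the DP is O(n⁴) in the worst
  case, which is immaterial at probe lengths).
* Degenerate windows in the target are rejected rather than expanded:
  probes are synthesized concrete, and a degenerate template makes
  coverage unverifiable. `expand_degenerate()` exists for primers and has
  a hard cap on the expansion count.
* Ranking ties end at (start, sequence), so reports are total-ordered and
  byte-identical across reruns.
* An empty design result is a warning plus an empty report, not an error:
  a target with no specific region is a legitimate scientific answer.

## Verification sizes

The shipped checks run the folding oracle equivalence on 500 random
sequences of length ≤ 12 plus 50 random 18-mers; planted-probe recovery on
20 seeded communities × 5 species (100 design runs, every emitted probe
re-screened by an independent naive scan); an 8-species congeneric
staining panel; salt/formamide monotonicity on 100 random 18–22-mers; and
QC partition/idempotence on 10,000 simulated reads. These sizes were
chosen to exercise every code path at desk scale; all are re-run from
scratch by `scripts/acceptance.R`.

## Known limitations

* No mismatch-duplex thermodynamics: specificity is a Hamming count, so a
  G·T-rich near-match and a transversion-rich one are treated alike.
* No probe–probe dimer prediction and no helper/competitor probe design.
* One probe per taxon: no set-cover design over strain panels.
* The DNA/DNA thermodynamic table is an approximation to the actual
  DNA/RNA hybrid; per-probe wet-lab hybridization/washing temperatures
  remain user inputs.
* The staining predictor is the in-silico ceiling of scope: it forecasts
  which taxa carry a binding site, not hybridization kinetics, rRNA
  accessibility, or fluorophore behavior in fixed cells.
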