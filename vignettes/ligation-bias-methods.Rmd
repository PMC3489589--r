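---
title: "Modelling ligation bias in small RNA sequencing libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ligation bias in small RNA sequencing libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligbias)
library(dplyr)
```

## The problem

Small RNA sequencing libraries are built by two enzymatic ligations: a
truncated T4 RNA ligase 2 (Rnl2) joins a pre-adenylated 3' adapter to the
RNA, then T4 RNA ligase 1 (Rnl1) adds the 5' adapter.  Both ligases care
about the secondary structure around the junction they seal: Rnl2 favours a
double-stranded context immediately *upstream* of its junction, while Rnl1
strongly prefers *single-stranded* ligation sites.  Because a small RNA and
an adapter co-fold into a structure that depends on both sequences, the
efficiency of each ligation — and therefore the read count of each molecule
— is sequence dependent.  Read counts from such libraries are biased
measures of abundance, some sequences are never captured at all, and the
bias propagates into which miRNAs get annotated, ranked and studied.

`ligbias` packages the analytical machinery for studying this problem:

* a **Poisson count model** for degenerate (fully randomised) oligo pools,
  with a chi-squared goodness-of-fit test of the equimolar null;
* **secondary-structure profiling** of insert/adapter constructs around the
  ligation junctions;
* **HD (high definition) adapter** combinatorics — adapters carrying fully
  degenerate tags at their ligation ends, which spread each insert over
  many co-folding contexts and average the bias out;
* **miRNA quantification** utilities (RPM normalisation, detection curves,
  fold-change concordance, arm-switch detection, candidate filtering);
* a **platform-bias comparison** of MFE distributions between miRNA sets;
* a seeded **synthetic library simulator** with a structure-dependent
  two-step ligation bias model, so every stage of the pipeline can be
  exercised with known ground truth.

## The count model

Sequencing a degenerate pool of `p` equimolar molecules to depth `n` is
sampling with very low per-molecule probability, so each molecule's read
count is approximately Poisson with rate `lambda = n / p` (for an N9 pool,
`p = 4^9 = 262,144`; for N21, `p = 4^21`).  `poisson_gof()` compares the
observed multiplicity histogram (how many distinct sequences were read
exactly `k` times, including the unseen zero class) with this expectation
using a Pearson chi-squared test.  Expected bins below 5 are pooled — from
the tail inward, and symmetrically at the head for large `lambda` where the
low-count classes become vanishingly rare; degrees of freedom are the
pooled bin count minus one.  Under equimolarity the capture fraction (the
share of the `p` possible sequences seen at least once) should approach
`1 - exp(-n/p)`; a biased library falls far short of it.

```{r count-model}
sim <- simulate_library(
  simulation_config(insert_length = 6, pool_size = 4096, depth = 2e4, seed = 1)
)
glance(poisson_gof(sim$counts, p = 4096))
capture_fraction(sim$counts, 4096)
1 - exp(-2e4 / 4096) # Poisson prediction
```

## Structure prediction

All structure-dependent analyses go through a single folding contract:
`fold()` / `fold_sequences()` return one minimum-free-energy structure in
dot-bracket notation plus its energy.  Two engines satisfy the contract:

* **Built-in** (`engine = "nussinov"`, the default): a stacking-weighted
  Nussinov-style dynamic program.  Pair scores are GC = 3, AU = 2,
  G·U = 1, with +1 for each pair stacked directly on another; hairpin
  loops need at least 3 unpaired bases; the traceback is deterministic
  (pairing beats bifurcation, the 3'-most partner wins ties).  The energy
  is the negated score in kcal/mol-like units.  Temperature only rescales
  the energy — the structure choice is temperature independent — which is
  a documented limitation of the simplified model.  The test suite proves
  this engine optimal against exhaustive structure enumeration for all
  tested sequences up to 12 nt.
* **External** (`engine = "rnafold"`): delegates to ViennaRNA's `RNAfold`
  (full Turner model) when the executable is on the `PATH`, and returns
  its MFE verbatim.  The default temperature everywhere is 22 °C, the
  convention for this analysis.

The built-in engine keeps the package hermetic and deterministic; figures
tied to a specific thermodynamic parameter set (exact MFE values, exact
distinct-structure counts for an insert across HD tag combinations) are
engine dependent and should be computed with the external engine when
parity with a particular RNAfold version matters.

## Junction-anchored profiles

`build_construct()` concatenates adapter5 + tag5 + insert + tag3 +
adapter3 (segments as the mode requires) and records each ligation
junction, 0-based, at the first base of its downstream segment.
`pairing_profile()` folds a set of equal-length constructs and reports the
fraction of molecules pairing each position; `junction_pairing_fraction()`
reads the single base adjacent to a junction.  "Base paired at the
ligation site" means that one adjacent base — the quoted percentages in
junction analyses are single-base frequencies, with any wider window left
to the caller (the profile contains every position).

```{r profile}
ad <- example_adapters(0)
biased <- simulate_library(
  simulation_config(insert_length = 21, pool_size = 300, depth = 2e4,
                    beta3 = 3, beta5 = 3, seed = 5)
)
tops <- abundance_curve(biased$counts, 100)$sequence
prof <- pairing_profile(lapply(tops, build_construct, adapters = ad,
                               mode = "full_construct"))
junction_pairing_fraction(prof, side = "upstream")   # 3' junction, Rnl2 side
junction_pairing_fraction(prof, attr(prof, "junction5"), "downstream")
```

An unbiased control profile is built from uniform random inserts of the
same length (folded in the same adapter context); `profile_similarity()`
(squared Pearson correlation of the frequency vectors) quantifies how
closely a library's profile matches that control.

## The simulator

`simulate_library()` draws `pool_size` distinct inserts uniformly from the
`4^insert_length` space, folds each molecule's full adapter construct, and
assigns the Boltzmann-like ligation weight

```
w  =  exp( beta3 * s3  +  beta5 * s5  -  gamma * MFE )
```

where `s3 = +1` when the base upstream of the 3' junction is paired (else
-1), and `s5 = +1` when the base downstream of the 5' junction is unpaired
(else -1) — the two ligase rules with tunable strengths.  `depth` reads
are then drawn multinomially from the normalised weights.  Both indicators
are read from a single fold of the full construct; the model does not
re-fold the intermediate (insert + 3' adapter) molecule separately, a
deliberate simplification that keeps the simulator at desk scale.  With
`beta3 = beta5 = gamma = 0` the sampling is exactly uniform-multinomial,
which is the calibration null for the goodness-of-fit test.  For HD
adapters (`tag_length > 0`) each molecule is spread over
`tags_per_molecule` uniformly sampled tag pairs and every
(insert, tag pair) combination is weighted and sampled as its own entity —
this is precisely the mechanism by which degenerate tags flatten the
insert-level bias.

The `gamma` term makes overall co-structure stability, not just the two
junction bases, drive ligation success.  It exists because the
junction-indicator terms alone act through two binary classes: they
distort counts strongly (the goodness-of-fit test rejects essentially
always at `beta = 3`) but produce only a diluted correlation between MFE
and abundance within the observed sequences.  The package's
MFE-versus-abundance power analyses therefore drive that property with
`gamma > 0` (typically 0.1), under which the squared correlation between
MFE and log10 count reaches ~0.35-0.40 on synthetic N21-style pools —
the regime the real-data analyses report.

What the simulator does *not* model, and what passing tests therefore do
not establish about real libraries: sequencing error, PCR amplification
bias, adapter-dimer artefacts, real ligase kinetics beyond the two
structure rules, and non-equimolar synthesis of "degenerate" pools.  It is
a generative model of the ligation-bias mechanism, not of a sequencer.

## Problem sizes

The package's standard study conditions are those of the degenerate-pool
experiments: 9-nt inserts over the full `4^9` pool at one million reads
(`simulation_config()` defaults), and N21-style analyses on 21-nt inserts.
The test-suite and acceptance analyses run the same models on reduced
instances chosen to keep every property estimable in minutes on a single
core: goodness-of-fit calibration on `4^6`-pools at depth 20,000 over 500
seeds; power and correlation analyses on pools of 120-300 molecules at
depths of 6,000-30,000 over 6-100 seeds; HD-versus-standard comparisons
with 4N tags and 8 sampled tag pairs per molecule; arm-switch recovery at
the full reference scale of 122 duplex pairs.  These sizes are stated in
the scripts themselves; scaling them up only sharpens the estimates.

## Numerical and design choices

* **Alphabet.** Everything internal is RNA (`T` normalised to `U` on
  input).  Reads containing `N` are dropped and counted, never corrected.
* **Adapter trimming.** The 3' adapter is located by an exact match of
  the first 8 nt of its core (configurable); no mismatch rescue is
  attempted, and HD reads whose tags carry sequencing errors are not
  recovered.  Rejections are typed (`no_adapter`, `too_short`) rather
  than silent.  The default minimum insert of 16 nt sits below the
  20-32 nt small-RNA range so that toy tests have margin.
* **Ties.** Abundance rankings break count ties alphabetically by
  sequence; equal strand counts in arm-switch calls yield "no call" (`NA`)
  rather than an arbitrary winner; the folder's traceback prefers pairing
  over bifurcation and the 3'-most partner, so every structure is
  reproducible.
* **Pseudocounts.** All ratio statistics (fold changes, 5p/3p log
  ratios) add 1 raw read to numerator and denominator.
* **RPM denominators.** `rpm_normalize()` defaults to the sum of the
  supplied counts (reads assigned to known miRNAs); a total-trimmed-reads
  denominator can be passed explicitly.  The choice is recorded in the
  output contract rather than hidden.
* **Arm-switch threshold.** Duplexes qualify when either strand exceeds
  10 RPM in either protocol; replicates are summed within protocol first.
  The two protocols are ordered by sorted label, so relabelling them
  exchanges the output columns exactly.
* **Wilcoxon comparisons.** `compare_platform_mfe()` uses the two-sided
  rank-sum (Mann-Whitney) form with normal approximation and tie
  correction; fully tied inputs degrade to `p = 1` with a warning rather
  than an error.  Whether a miRNA discovered by both platforms belongs in
  both sets is the caller's labelling decision; the function compares the
  sets exactly as given.
* **Candidate filter.** Fold change is strict (`> 1.4`): a candidate at
  exactly 1.4 is rejected, and a star-strand observation is required.
* **Seeds.** A single integer seed drives each simulation; sub-analyses
  derive fixed offsets from it.  Identical seeds give bitwise-identical
  libraries.
* **Structure identity for HD diversity.** `structural_diversity()`
  counts distinct insert-restricted dot-brackets (the biologically
  relevant portion) and reports the full-construct count alongside, since
  either convention is defensible; enumerating more than the 256 pairs of
  a 2N tag requires an explicit subset or an override flag.

## Known limitations

The built-in folder is a maximum-score model, not a thermodynamic one: its
energies are comparable between sequences folded by the same engine but
are not kcal/mol in the Turner sense, and its temperature dependence is a
pure rescaling.  Pairing profiles require fixed-length inserts; variable
length profiling is out of scope.  Ensemble (partition-function) pairing
probabilities, pseudoknots, genome mapping and hairpin discovery are not
implemented — the candidate filter consumes the output of an external
discovery tool.  Platform labels for the MFE comparison are user-supplied;
the package performs no repository retrieval.
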