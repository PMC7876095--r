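---
title: "Modelling replication dynamics of HR-restarted forks at programmed barriers"
author: "replifork"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling replication dynamics of HR-restarted forks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

## The biological problem

Replication forks in fission yeast can be arrested at programmed,
polar barriers. At *RTS1*, an Rtf1-dependent barrier, the arrested fork
collapses and is restarted by homologous recombination (HR); the
restarted machine synthesises **both** strands with Pol delta (the
"delta/delta configuration"), uses essentially no Pol alpha, and is
insensitive to further *RTS1* copies. At the ribosomal-DNA barrier
(rRFB, the Ter2--Ter3 repeats), forks pause transiently and resume
without restart. Polymerase usage sequencing (Pu-seq) measures, per
genomic window and strand, the fraction of synthesis performed by Pol
delta versus Pol epsilon, and so makes the switch from canonical
(epsilon/delta) to restarted (delta/delta) synthesis directly visible.

Quantities such as the fraction of forks arrested at the barrier, the
time a collapsed fork takes to restart, and the position at which the
restarted leading strand initiates cannot be read directly from a
Pu-seq trace: they are parameters of the underlying per-cell dynamics.
`replifork` estimates them by simulating an ensemble of cells,
converting the ensemble into trace space, and minimising the Euclidean
distance to the observed trace over a one-parameter grid (a line
search). A synthetic-data generator closes the loop so that every stage
of the pipeline can be exercised, and its estimators validated, without
any external download.

## The per-cell model

Each simulated cell replicates a one-dimensional locus:

* **Origins.** An unsuppressed origin is *competent* in a given cell
  with probability equal to its efficiency. Competent origins draw a
  firing time from a Normal distribution truncated at 0 (parameters per
  origin, in minutes). An origin whose position is replicated before
  its firing time never fires (passive replication). Cells in which no
  origin is competent are redrawn, with a counter; the flanking origins
  of the preset loci make this vanishingly rare. The upstream model
  this package varies placed origins genome-wide from sequence
  features; here origin position, efficiency and timing are explicit
  configuration, which is what the locus-scale analyses require.
* **Forks.** Firing spawns two diverging canonical forks moving at a
  constant velocity, 1.8 kb/min by default. Two converging forks
  terminate where their trajectories meet; forks stop at the domain
  edges.
* **Barriers.** A barrier blocks forks travelling in one direction
  only. On encounter, a susceptible fork arrests with probability
  `arrestProbability` (one independent draw per fork lineage per
  barrier). A *pause* barrier (rRFB-like) holds the fork for `delay`
  minutes and releases it unchanged. A *restart* barrier (RTS1-like)
  holds it for `delay` minutes and releases it as an HR-restarted fork
  at `position + restartOffset` (the offset is never positive: restart
  can only move into the fork's own replicated wake, re-replicating the
  offset window). Restarted forks are permanently restarted, synthesise
  both strands with Pol delta, and pass `canonicalOnly` barriers
  without any delay. If a converging fork reaches an arrested fork
  before its restart time, the arrested fork is cancelled (rescue).
* **Polymerase usage.** Per bin and cell: a canonical rightward fork
  assigns Pol epsilon to the Watson strand (leading) and Pol delta to
  the Crick strand (lagging), of which a fixed fraction
  `alphaFraction` (default 0.1) is attributed to Pol alpha; a canonical
  leftward fork is the mirror image; a restarted fork assigns Pol delta
  to both strands and no Pol alpha. Pol alpha is deliberately modelled
  as a fixed fraction of canonical lagging-strand synthesis rather than
  spatially resolved primers, because the relative ribonucleotide
  incorporation rates of the three polymerases are unknown and the
  alpha track is only ever displayed as a not-to-scale overlay
  (conventionally multiplied by 10).

Ensembles (default 1000 cells; 10,000 for validating a fitted optimum)
average per-bin direction, fork type, replication time and usage.

## Two engines, one semantics

The production engine (`simulateCell`, in C++) is event-driven and
continuous in time: firing, barrier encounters, resumptions, meetings,
rescues and edge arrivals are processed in exact chronological order,
so there are no timestep artifacts under the piecewise-constant
velocities of this model. Its correctness is guarded by a second,
independent engine (`simulateCellFixedStep`, in R) that advances the
state in explicit increments of `dt` minutes and resolves events it
detects within a step by linear interpolation. Both engines consume the
same pre-drawn randomness for a given cell seed — origin competence,
truncated-normal firing times, and one arrest uniform per origin
lineage per barrier, drawn before simulation starts — so their outputs
can be compared cell by cell; the suite checks agreement of direction
and fork type at every bin, and of replication times within `dt`, on a
hundred random loci.

Pre-drawing the randomness has a second benefit: a barrier that never
acts (arrest probability 0, or a zero-delay pause) consumes the same
draws as an active one, so null barriers reproduce barrier-free
ensembles bit-exactly under a shared seed, which the suite asserts.

### Numerical conventions

* Bins are 0-based and half-open; bin `k` covers
  `[start + k*binSize, start + (k+1)*binSize)`. Origin and barrier
  positions are snapped to the nearest bin boundary at simulation time
  so that bin attribution is unambiguous.
* A bin takes the direction, fork type and time of the fork that last
  crossed its **midpoint**; at an exact midpoint tie the rightward fork
  wins (the left-mover's segment is assigned first and overwritten).
  Re-replication after an offset restart overwrites both the fork type
  and the time of the affected bins.
* Midpoint attribution quantises positions to the bin size. A shift of
  the restart point smaller than the distance to the next midpoint is
  therefore invisible at that bin size, which is why the
  offset-detectability analysis below runs on 100 bp windows.
* Per-cell seeds are derived from the master seed by a fixed affine
  map modulo 2^31 - 1, so ensembles are reproducible and independent of
  evaluation order.
* Ties in the line search are broken toward the smallest grid value and
  flagged in the result.

## From counts to traces

`computeUsage` reproduces the published Pu-seq computation: per strand,
the delta-strain and epsilon-strain counts are divided by their library
totals and the Pol delta usage is the normalised delta density over the
summed normalised densities, so `usage_delta + usage_epsilon = 1` on
every unmasked bin. Bins with fewer than `minDepth` (default 10) raw
delta + epsilon counts are masked; masked bins are linearly
interpolated before Savitzky--Golay smoothing (default window 9 bins,
order 3 — the source analyses smooth but state neither parameter) and
re-masked afterwards. The filter's native edge handling fits full
polynomials to the first and last half-windows, so polynomials up to
the filter order are reproduced exactly, edges included.

One subtlety deserves emphasis. Library-size normalisation is a
genome-wide operation: over a whole genome the delta and epsilon
strains sequence comparable total material, so dividing by library
totals cancels depth differences without distorting the ratio. Over a
locus **window** in which delta/delta restart synthesis makes the two
strains' local shares unequal, normalising by window sums would bias
`usage_delta` (by roughly 10 percentage points on the wild-type locus
here, enough to drag a fitted arrest efficiency from 0.7 to 0.55-0.6).
The synthetic generator therefore records the *design* library totals
of a depth-matched genome-scale experiment in a
`counts_library_totals.json` sidecar next to the bedGraph tracks, and
`readCounts` accepts these totals explicitly; with real genome-wide
tracks the default (per-file sums) is the classic behaviour.

## The synthetic generator and what it does not emulate

`generateCounts` draws, independently per strain, strand and bin,
`Poisson(depth * usage + background)` counts, where the alpha strain's
usage channel is the un-scaled alpha fraction. Defaults: `depth = 100`
expected counts per bin at usage 1, `background = 1` stray count per
bin. Poisson noise is the simplest model consistent with count data;
overdispersion (a negative-binomial option) is a documented extension
hook, not implemented. The generator emulates sampling noise, strand
assignment and sequencing depth. It does **not** emulate read-level
artifacts: mappability bias, alignment errors, library-preparation
biases, ribonucleotide-excision variability between strains, or
chromatin effects on incorporation rates. Passing tests therefore show
that the estimators invert the package's own generative model at
realistic depths — a necessary condition — not that they are robust to
every artifact of real sequencing data.

`makeScenarioDataset` wires the generator to preset loci whose
generating parameters are the fitted values of the matching
experiments: wild type (arrest probability 0.7, restart delay 11 min),
adh-driven Rtf1 (0.9), pku70 deletion (delay 14 min), the tandem and
inverted double-barrier constructs, a barrier-off control, and the rRFB
calibration construct (pause delay 6 min). Every generating parameter
and seed goes into `truth.json`; the suite regenerates a dataset
bit-exactly from the truth file alone.

## Fitting

`modelError` is the Euclidean norm of the predicted-minus-observed
difference over the region of interest, masked bins excluded. The
channels entering the norm default to Pol delta usage on both strands:
epsilon is redundant under the closure, and which trace entered the
original objective is not recorded, so the choice is exposed as an
option. `lineSearch` simulates every candidate value with **common
random numbers** (one master seed across the grid) so that objective
differences reflect the parameter rather than Monte Carlo noise, then
revalidates the arg-min with a 10x larger ensemble and a fresh seed.
Grids are pre-registered per scenario (`scenarioFits`) and echoed into
the result object for provenance.

Two scenario-design notes. The rRFB delay is fitted on the dedicated
calibration construct because on the full locus the converging fork
usually terminates before its pause matters, leaving the objective
flat. The hypothetical delay of restarted forks at a second *RTS1* copy
is modelled by adding a co-located pause barrier that applies to
restarted forks only — forks that arrest and restart *at* the second
barrier are already delayed there and are not paused twice.

Problem sizes throughout (1000-cell searches, 10,000-cell validations,
depth-100 datasets, and a 100 bp-window analysis at depth 300 for the
offset-detectability check) are the study conditions stated above;
they run in a few minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile()
ds <- makeScenarioDataset("rts1_rrfb_wt", dir, depth = 100,
                          nCells = 1000, seed = 101)
counts <- readCounts(puseqFileSet(dir), binGrid(ds$config),
                     readLibraryTotals(dir))
obs <- computeUsage(counts)
fitD <- scenarioFits("rts1_delay", obs, masterSeed = 7)
bestValue(fitD)    # 11 (minutes): the generating restart delay
fitP <- scenarioFits("rts1_efficiency", obs, masterSeed = 7)
bestValue(fitP)    # 0.7: the generating arrest probability
```

## Known limitations

* Origin firing is an explicit parametric stand-in (Bernoulli
  competence plus truncated-Normal timing); inferring origin programs
  from sequence is out of scope.
* One parameter is searched at a time, as in the analyses this package
  reproduces; joint optimisation and uncertainty intervals on fitted
  parameters are not provided.
* The Pol alpha model is a fixed lagging-strand fraction, not resolved
  Okazaki-primer placement.
* Restart positions are deterministic given the offset; cell-to-cell
  variability of the strand-invasion point is not modelled.
* Coordinates are synthetic. Preset loci reproduce the engineered
  constructs' relative geometry (barrier spacings, origin distances),
  not real chromosome II coordinates.
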