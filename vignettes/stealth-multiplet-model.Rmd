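---
title: "The stealth-multiplet model: probabilities, inference, and auditing"
author: "stealthmx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stealth-multiplet model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stealthmx)
```

## The model and its assumptions

A multiplexed droplet run pools `s` samples in fractions $r_i$
($\sum r_i = 1$), each cell of sample $i$ carrying a detectable sample
barcode with probability $a_i$ (the labelling efficiency — set jointly
by the wet-lab labelling step and by how aggressively the
demultiplexer thresholds the barcode counts). Droplet occupancy is
Poisson: a droplet captures $k \sim \mathrm{Poisson}(\lambda)$ cells,
where $\lambda$ (dimensionless, cells per droplet) tracks the cell
loading rate of the chip. Cells are assigned to droplets independently
— the model assumes complete dissociation (no cell clumps) and a
loading rate low enough that the Poisson description of encapsulation
holds; aggressively "super-loaded" runs and bead-occupancy effects are
outside it.

Under these assumptions each cell of a droplet independently falls
into one of $2s$ label channels (sample $i$, labelled or unlabelled),
so the channel counts are independent Poissons
($r_i a_i \lambda$ labelled, $(1-\bar a)\lambda$ pooled unlabelled,
with $\bar a = \sum r_i a_i$), and the probabilities of the droplet
classes have the closed forms implemented in
`multipletProbabilities()`. The four multiplet classes — homogeneous
stealth, partial stealth, multilabelled, unlabelled — partition the
total multiplet mass $1 - e^{-\lambda} - \lambda e^{-\lambda}$, and
together with empty droplets and the two singlet classes they sum to
one; both identities are enforced by the class validity check at
construction and verified to $10^{-12}$ across random designs in the
test suite.

One classification boundary deserves emphasis, because it is forced by
the algebra rather than by intuition: a droplet whose labelled cells
all come from sample $i$ plus an unlabelled cell *also from sample
$i$* is a **partial** stealth multiplet, not a homogeneous one. Label
status, not sample of origin, drives the classification — the origin
of an unlabelled cell is unobservable downstream, and only with this
convention do the per-class probabilities reproduce the closed forms.
`classifyDroplet()` implements exactly this rule and is checked
exhaustively against a cell-record enumeration oracle for all
compositions with up to four cells and three samples.

## Reporting conventions

The closed forms are **per droplet** (empty droplets included); that
is the canonical storage form because it is the convention under which
the seven classes sum to exactly 1. Observed class fractions from a
real run are **per cell-droplet** (divide by $1 - e^{-\lambda}$), and
stealth burdens are most interpretable **per monolabelled droplet**
(divide by $P(1)\bar a + p_{HS} + p_{PS}$). Class-composition design
curves use a fourth scale, fractions **among multiplets**. Rather than
guessing a single convention, `classProbabilities()` and
`multipletFractions()` expose all of them explicitly; every consumer
in the package names the convention it uses.

## Numerical choices

$\sum_i e^{r_i a_i \lambda} - s$ is evaluated as
$\sum_i \mathrm{expm1}(r_i a_i \lambda)$ and
$e^{-\bar a \lambda} - e^{-\lambda}$ as
$e^{-\lambda}\,\mathrm{expm1}((1-\bar a)\lambda)$, avoiding
cancellation at small $\lambda$; residual negative zeros below
$10^{-12}$ are clamped to zero. Design validity tolerates $10^{-9}$ on
$\sum r_i = 1$. Both root solves (`estimateLambda()` on
$\lambda \in [10^{-9}, 10]$, the model-consistent labelling-efficiency
solve on $[0,1]$) use `uniroot` at tolerance $10^{-12}$ on a bracket
where the objective is strictly monotone, so the root is unique;
estimates are reported in full precision and conventionally rounded to
three decimals for display.

## Inverse estimation

Two parameters are estimated from a demultiplexing count table:

* **Labelling efficiency.** The default estimator is the ratio
  $\hat{\bar a} = n_{mono}/(n_{mono}+n_{unlab})$, chosen as the
  default because it needs no $\lambda$ and reproduces published
  estimates from printed count tables. It carries a deterministic
  positive bias of about $0.13\,\lambda(1-\bar a)$ — stealth
  multiplets inflate the monolabelled class — which is negligible in
  well-labelled runs ($\lambda(1-\bar a) \le 0.03$) but material below
  $\bar a \approx 0.9$. The `model_consistent` option removes the bias
  by solving the model's monolabelled-to-unlabelled ratio for
  $\bar a$ at a known $\lambda$; it is exactly unbiased at the closed
  form. Zero unlabelled droplets yield the boundary estimate
  $\hat{\bar a} = 1$ with a diagnostic flag rather than an error.
* **Loading rate.** $\lambda$ is recovered from the one multiplet
  class a demultiplexer reports reliably: the multilabelled fraction
  among cell-droplets, solving
  $p_{Mu}(\lambda)/(1-e^{-\lambda}) = n_{multi}/n_{total}$. This
  equation was adopted because, applied to the printed count tables of
  the two public datasets shipped under `inst/extdata/` (an 8-donor
  cell-hashing PBMC run and a 7-donor NSCLC CMO run), it reproduces
  the published loading rates (0.369 and 0.608) to three decimals.
  With $s=1$ or zero multilabelled droplets $\lambda$ is
  unidentifiable and the function says so.

The 8-donor dataset is treated as $s = 8$ equal-design by default (the
ninth spiked-in cell population is essentially removed upstream of the
count table); the sample count is always an explicit argument.

## The simulator: what it emulates and what it does not

`simulatePool()` draws the generative model directly — per droplet,
independent Poisson channel counts, which is distributionally
identical to drawing $k \sim \mathrm{Poisson}(\lambda)$ cells and
assigning each to a sample and label status — classifies with
`classifyDroplet()`, and tallies. The generator is seeded with a
named, fixed algorithm (Mersenne-Twister with inversion sampling,
restored to the caller's RNG state afterwards), so a tally is
reproducible from its recorded seed. It serves two roles: the
independent oracle for every closed form (3-standard-error agreement
at $10^6$ droplets over random designs), and the fixture factory for
the concordance auditor via `degradeCalls()`, which converts
per-droplet records into a truth call table and a degraded one with
planted unassignment and misassignment rates.

What the simulator deliberately does not emulate: barcode *count*
matrices (no UMI counts, no ambient contamination, no signal-to-noise
structure), transcriptomes, or any demultiplexer's decision rule. The
degradation channel is an idealised error model — independent,
class-blind unassignment and uniform misassignment. Passing tests
therefore demonstrate that the closed forms, the inverse estimators
and the audit logic are internally correct under the stated model;
they do not certify the Poisson assumption, or any particular
demultiplexer, on real data — deviations such as cell clumping,
super-loading (where negative-binomial occupancy fits better) and
demultiplexer-specific biases are documented limitations.

## The concordance audit

`classifyConcordance()` compares a reference call set (the
better-validated one, typically oligo-barcode based) with a test set
(e.g. SNP based) over their common barcodes into five classes:
singlet (identical sample call), partial stealth multiplet (test
singlet, reference multiplet — the class of interest), multiplet
(both), unassigned (test unassigned), and a discordant catch-all.
"Discordant/Others" is deliberately a catch-all — sample-mismatched
singlets and reference-unlabelled rows land there — with a per-subtype
breakdown retained in the result, since the five-way scheme does not
enumerate subtypes. Reserved call tokens are `MULTIPLET`,
`UNLABELLED`, `UNASSIGNED`; the reader maps common demultiplexer
dialects (`Doublet`, `Negative`, `A+B` multiplet calls, ...) onto
them, and unknown tokens are an error naming the offending row rather
than a silent reclassification. `summariseConcordance()` reports the
partial-stealth burden among monolabelled droplets
$PS/(S+PS)$ and its complement the singlet-to-monolabelled ratio —
which intentionally differs from the model's TSR, since homogeneous
stealth multiplets are invisible to *both* call sets and still count
as "singlets" in any observable audit.

## Two-Gaussian score thresholding

Marker-score based double-positive calling fits a two-component
Gaussian mixture to a per-droplet score distribution by EM and
thresholds on the upper tail of the lower-mean (null) component.
Initialisation is a split at the median plus ten random restarts
(seeded, so deterministic), convergence at $10^{-8}$ on the
log-likelihood, and degenerate fits (vanishing component variance or
weight) are rejected; the best converged restart wins, and the test
suite cross-checks the fit against an independent mixture
implementation. The threshold is the smallest score whose
null-component upper-tail probability is at most `p` (default
$10^{-4}$): unadjusted, that is the closed-form quantile
$\mu_0 + z_{1-p}\sigma_0$; a Benjamini–Yekutieli-adjusted variant over
the observed scores is provided as the conservative option, since
published analyses of this kind differ in their adjustment path and
neither mode is asserted to reproduce any one of them bit for bit.
Droplets above threshold for two or more lineages are multiplets;
those the labelling called a single sample are partial-stealth
candidates (`callDoublePositives()`).

## Problem sizes

The default verification runs use $10^6$ droplets per design for
oracle-equivalence and parameter-recovery checks (binomial 3-SE bands
at that size resolve the class probabilities to a few times
$10^{-3}$), 1,000 random designs for the conservation identities, and
$10^4$-row tables for the audit oracles; these sizes make the checks
sharp while keeping a full suite run in well under a minute.

## Known limitations

* Poisson occupancy only; no negative-binomial alternative for
  super-loaded chips and no bead co-occupancy correction.
* No joint maximum-likelihood over all class counts and no interval
  estimates — the estimators are the one-equation inversions described
  above, checked by Monte-Carlo.
* The auditor consumes call tables and precomputed marker scores; it
  neither demultiplexes barcode counts nor scores transcriptomes.
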