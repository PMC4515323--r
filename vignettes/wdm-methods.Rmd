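---
title: "The windowed discrete model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The windowed discrete model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wdmnet)
```

## The model class

`wdmnet` simulates multi-valued logical networks: $N$ nodes
$\sigma_1,\dots,\sigma_N$, each taking integer activity levels
$\sigma_i \in \{0,\dots,m_i\}$, updated synchronously by

$$\sigma_n(t+1) = F_n\!\left(\sigma_n^1(t),\dots,\sigma_n^{k_n}(t)\right),$$

where the $F_n$ are total lookup tables over the $k_n$ regulators of node
$n$. Because the state space is finite (size
$\Omega = \prod_i (m_i + 1)$) and the synchronous map is deterministic,
every trajectory ends in a periodic attractor of some period $L_a$; the set
of initial conditions reaching attractor $a$ is its basin, with fractional
size $\omega_a$ ($\sum_a \omega_a = 1$).

The *windowed discrete model* (WDM) turns this single-cell formalism into a
population-level prediction. Batch-culture expression measurements average
over cells that sit at different phases of different stable programmes, so
the WDM (i) averages each node over exactly one attractor period, giving a
continuous value $A_{ia}$ per node and attractor, and (ii) averages the
$A_{ia}$ over all attractors weighted by basin size:

$$\bar\sigma_n = \sum_{a=1}^{N_\mathrm{att}} \omega_a
  \left(\frac{1}{L_a}\sum_{\tau=1}^{L_a}\sigma_n(t_0+\tau)\right)_a .$$

No attractor is discarded. Two implementation choices make the inner
average exact rather than approximate:

* **Window length.** The window is exactly one attractor period $L_a$.
  Any integer multiple $cL_a$ gives the same mean (a property the test
  suite checks); windows that are *not* multiples of the period flatten
  cyclic dynamics and are avoided.
* **Transient handling.** Rather than discarding a fixed burn-in $t_0$,
  `find_attractor()` detects the exact transient by hashing visited states
  until the first repeat, so averages start precisely at attractor entry.

## Estimating basin fractions

`enumerate_attractors_exhaustive()` computes exact basins by sweeping the
complete state space (refusing beyond a configurable cap, default $10^6$
states). For the bundled 15-node network, $\Omega = 4{,}299{,}816{,}960$,
so basins are estimated by `sample_attractors()`: initial conditions are
drawn uniformly *with replacement* (per-node uniform digits, the mixed-radix
equivalent of a uniform state index), each is iterated to its attractor,
and $\hat\omega_a = \text{hits}/n$ with binomial standard error
$\sqrt{\hat\omega_a(1-\hat\omega_a)/n}$. Attractors found from different
starting points are merged by a canonical key, the minimal encoded state of
the cycle — well defined because attractors are disjoint state sets. The
default is $n = 10^5$ samples per strain and condition; at that size the
standard error of any basin fraction is at most $1.6\times10^{-3}$, well
below every contrast the calibration suite tests. Fractions are normalised
over sampled initial conditions, so they sum to one exactly.

State indices follow a little-endian mixed-radix convention (first declared
node varies fastest), chosen for trivial invertibility; it is a convention
of this package, not a reconstruction of any published ordering. Indices
are held in doubles (exact up to $2^{53}$), and the C++ kernels use 64-bit
integers.

## Update schemes

Synchronous updating is the reference scheme. Three asynchronous schemes
are provided: single random node per step, random permutation rounds, and
fixed-order rounds. Asynchronous attractors are scheme-dependent, so no
exact attractor identification is attempted there; instead
`async_long_run()` reports per-node means over a window after a burn-in
(defaults: 1,000 and 2,000 rounds — roughly two orders of magnitude beyond
the longest synchronous transients we observe on the bundled model — and
100 independent seeds). `compare_update_schemes()` checks the claim that
population-level averages are insensitive to the update scheme: it requires
the strain ordering by reporter average to agree between schemes for every
pair of strains whose synchronous averages differ by more than a tie margin
of 0.1 activity levels, the resolution below which Monte-Carlo noise makes
an ordering claim meaningless; the margin is an upfront parameter of the
comparison, and the maximum per-node discrepancy is always reported
alongside the verdict.

## The bundled PKA network

The showcase model is the cAMP/PKA regulatory network of *S. cerevisiae*
controlling HSE-dependent gene expression: 15 nodes (two binary, one
ternary, four four-valued, one five-valued, seven six-valued). The wiring
follows the published interaction scheme:

* a positive-feedback backbone Ssa1/Ssa2 → Cdc25 → Ras2 → Cyr1 → cAMP,
  with cAMP relieving Bcy1's inhibition of the catalytic subunits
  Tpk1/Tpk2/Tpk3;
* catalytic-subunit antagonism: Tpk2, when present, is the effective
  activator of the chaperones; only in its absence do Tpk1/Tpk3 take over,
  and then they additionally activate Repressor X;
* Ssa1/Ssa2 and Repressor X repress Hsf1 and Skn7; the HSE reporter
  follows Hsf1 with a minor (single-increment) Skn7 contribution;
* heat shock is a positively auto-regulating environment node that lowers
  the effective chaperone output by one level (competition for Hsp70 by
  heat-denatured substrates).

The exact rule tables of the original model are not publicly recoverable,
so the shipped tables are this package's reconstruction, constrained by the
published level-count multiset, the interaction signs, and the qualitative
strain phenotypes encoded in the 15-constraint calibration suite
(`pka_constraints()`). Choices a maintainer should know about:

* **Level assignment.** Only the multiset of level counts is fixed by the
  source; the assignment (e.g. which nodes are binary) is a documented
  model-file field. $\Omega$ is invariant to it. We give the six levels to
  the nodes whose graded activity the genetics resolves most finely
  (Cdc25, cAMP, the three Tpks, Hsf1, the reporter).
* **Chaperone asymmetry.** The Hsf1-repression weight of Ssa2 exceeds that
  of Ssa1 (`pka_hsf1_repression()`), because deleting *SSA2* derepresses
  the reporter while deleting *SSA1* does not.
* **Gradual chaperone decay.** The Ssa rules take their own state as an
  input and decay by at most one level per step. Chaperones are stable
  proteins; instantaneous loss is unphysical, and the graded decay keeps
  the basin structure of the feedback loop consistent between synchronous
  and asynchronous updating.
* **Bistability.** The wild-type network at 25&nbsp;°C has a dominant
  active-cascade fixed point (basin fraction ≈ 0.998) plus a low-PKA fixed
  point with derepressed reporter expression. This bistability is not an
  accident: the repression of the reporter in the *bcy1* deletion
  (constitutively active PKA) relative to wild type arises *only* from the
  redistribution of this basin mass, not from any fixed-point difference —
  a genuinely population-level effect that single-attractor analyses would
  miss.
* **hsf1-ΔCTA.** The C-terminal truncation is a level cap, not a deletion:
  Hsf1 output (and sampled initial conditions) are truncated at level 1,
  the wild-type 25&nbsp;°C steady-state level, removing exactly the
  heat-inducible increment.
* **Deletions** clamp a node to 0 for the entire dynamics, including
  initial conditions; basin fractions for a strain are taken over its
  admissible (clamped) state space.
* **"Similar to" tolerance.** The calibration suite's ≈ comparisons use a
  ±15% relative band, wide enough that replicate sampling noise at
  $n = 10^5$ (relative SE < 1%) can never trip it, and narrow enough to
  separate every directional contrast in the panel. "Strongly repressed"
  means below half the comparator (and its reciprocal bounds "far above").

A level-collapsed binary variant (`pka_reduced_model()`, $2^{15}$ states)
supports *exhaustive* cross-checks of the deletion contrasts; graded
phenomena — heat induction, the Tpk2-specific repression — collapse with
the levels and are meaningful only in the full model.

## What the synthetic fixtures do and do not show

`generate_random_network()` draws fixtures with uniformly random total rule
tables; the test suite verifies the simulation kernels against an
independent brute-force oracle (full transition map, pointer-doubling cycle
extraction) on 100 such fixtures with up to 20,000 states, and verifies
sampling estimates against exhaustive basins at $n = 10^5$. These fixtures
exercise the algorithms, not the biology: they have no signalling
structure, so agreement there validates the machinery (encoding, cycle
detection, basin accounting), while the PKA constraint suite validates the
bundled model's substance. Passing both does not certify quantitative
agreement with any particular wet-lab measurement — the published
normalized ratio values for the strain panel are not available in numeric
form, which is why calibration targets qualitative, figure-anchored
contrasts rather than numbers.

## Numerical and degenerate-input choices

* Rule tables are validated for totality and output range at construction;
  every error names the offending node.
* `expression_ratio()` refuses a zero reference average by default (the
  ratio is undefined); an additive pseudo-floor is available but off by
  default and documented as a convenience, not part of the model.
* Ties in attractor ordering are broken by encoded cycle start, making all
  outputs deterministic given a seed.
* Seeds: every stochastic entry point takes one; panels derive per-strain
  sub-seeds linearly from the base seed so that single entries can be
  reproduced in isolation.

## Problem sizes used in the shipped checks

The calibration panel runs 21 strains × 2 conditions at $n = 10^5$ samples
(about two minutes on one core). The scheme-agreement comparison uses 100
asynchronous seeds per strain and condition with burn-in 1,000 and window
2,000 rounds. Oracle cross-checks use 100 random fixtures capped at 20,000
states, with sampling consistency verified on 20 of them. These sizes give
basin-fraction standard errors at least an order of magnitude below every
tested contrast while keeping a full run of the suite on a laptop scale.

## Known limitations

* The rule tables are constraint-equivalent reconstructions; recovering the
  original tables would let users substitute them via the model-file
  interface without code changes (tables are data).
* Continuous-time (rate-based) semantics, stochastic rule noise, and rule
  inference from data are out of scope.
* Asynchronous analysis reports long-run means only; asynchronous
  attractor landscapes are scheme-dependent and not enumerated.
* The identity of Repressor X is left open, as in the source model; the
  node encodes its regulatory logic, not a molecular assignment.
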