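---
title: "Quantifying Cas9 cutting from transient-editing qPCR: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cas9 cutting from transient-editing qPCR: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcep)
```

## The measurement model

After transient delivery of Cas9 and a guide RNA, the target locus in a
piece of tissue is a mixture of three molecular states: intact wild-type
DNA (never cut, or cut and repaired faithfully — still cuttable), intact
mutated DNA (repaired with an indel — no longer recognised by the guide),
and broken DNA awaiting repair. Only the first two amplify in qPCR, so an
amplicon spanning the cut site reports the *amplifiable* fraction
$q = f_{wt} + f_{mut}$, and the broken fraction is $1 - q$.

Double-referencing removes everything else that moves Ct values. With an
internal single-copy reference amplicon in the same reaction plate and
untreated wild-type plants as the calibrator,

$$\Delta\Delta Ct \;=\; Ct(T) - Ct(T\text{-inter}) - Ct(C) + Ct(C\text{-inter}),
\qquad q = 2^{-\Delta\Delta Ct},$$

assuming perfect amplification (one cycle = one doubling). Every estimator
in the package is a power of two in a Ct difference for that reason; the
simulator's `amp_efficiency` lets you generate data where that assumption
is broken, precisely so you can measure what it costs.

Cutting depends on how much Cas9 a sample happened to receive, so the
broken fraction is divided by the Cas9 transcript abundance
$2^{-(Ct(Cas) - Ct(inter))}$ measured by RT-qPCR, giving the **relative
cutting efficiency**. Efficiencies are then fold-normalised to the weakest
target in the experiment, which cancels all remaining shared scale factors
and is how results are compared across targets.

### Canonical versus literal mode

Two conversions of $\Delta\Delta Ct$ to an abundance are in circulation.
The raw relative-quantification value $2^{-\Delta\Delta Ct}$ is the
*surviving intact* fraction: it goes *down* as cutting goes up. The broken
fraction $1 - 2^{-\Delta\Delta Ct}$ goes up with cutting, agrees with the
in vitro digestion estimator $1 - 2^{-(Ct(a) - Ct(inter))}$ (identical
closed form, so the two assays are directly comparable), and makes
$\Delta\Delta Ct = 2$ correspond to 75% broken DNA. The package defaults to
the broken-fraction reading (`mode = "canonical"`) and keeps
`mode = "literal"` available; both the intact and broken fractions are
always present in the results table, so nothing is hidden by the choice.

### Replicate aggregation and pairing

Biological replicates can be combined before or after the exponential.
Because $\Delta\Delta Ct$ is linear in the Ct values, averaging Ct across
replicates and averaging per-replicate $\Delta\Delta Ct$ are the same
thing, and converting that mean once avoids most of the convexity (Jensen)
bias that averaging $2^{-\Delta\Delta Ct}$ values would add under noise. The
package therefore reports point estimates of `ddct`, the intact/broken
fractions and `cas9_abundance` from replicate-mean Ct, while
`relative_efficiency`, its SD and all t-tests use the per-replicate
efficiencies, which carry the biological spread. Both layers are exposed
(`$results`, `$replicates`).

Untreated wild-type controls have no natural one-to-one pairing with test
plants, so the default pairing is `mean_control` (each test replicate
against the control-group mean Ct); `per_replicate` index-matching is
available for designs where wells are genuinely paired.

### Non-positive efficiencies and fold-normalisation

Noise can push $\Delta\Delta Ct$ below zero and hence the broken fraction
(and efficiency) negative. Raw values are retained everywhere statistics
are computed — discarding them would bias upward — but fold-normalisation
needs strictly positive values, so non-positive *mean* efficiencies are
clamped to `clamp_floor` (default $10^{-6}$) and flagged just for the fold
computation. If *no* target is positive the experiment carries no cutting
signal and the fold column is `NA` with a warning rather than a fold table
over pure noise. Exact ties for the minimum all map to 1; the first-seen
minimum is labelled the reference.

### Significance testing

Condition contrasts (heat versus control, and so on) use a two-sample,
two-sided, equal-variance Student's t-test on per-replicate efficiencies at
$\alpha = 0.05$, with no multiple-testing correction — one test per target,
reported per target. `tcep_compare()` computes the identical test from
mean/SD/n summary statistics so that two results files can be contrasted
without re-reading raw wells; the equivalence with `t.test(var.equal =
TRUE)` on raw values is asserted in the test suite.

## The simulator

### Cut/repair kinetics

`simulate_cut_repair()` integrates the three-state system from an
all-wild-type start:

$$\dot f_{wt} = -k f_{wt} + \rho (1 - \mu) f_{br}, \qquad
\dot f_{mut} = \rho \mu f_{br}, \qquad
\dot f_{br} = k f_{wt} - \rho f_{br}.$$

Faithfully repaired DNA re-enters the cuttable pool; mutated DNA is
absorbing (its protospacer no longer matches the guide). Parameters are
per-hour rates. No measured rate constants exist for this system, so the
defaults — `k_cut = 0.1`, `rho_repair = 0.2`, `mu_mut = 0.3`, `t_end = 48`
(the post-transformation harvest time at which transient Cas9 expression
peaks) — were chosen once to keep the broken fraction in the
experimentally observed range (roughly 0.1–0.75) and are configuration,
not biology. Integration is `deSolve::lsoda` at `rtol = 1e-10`,
`atol = 1e-12` on a fixed output grid; mass conservation is checked to
$10^{-8}$ after integration, and a grid step coarser than the fastest
timescale $1/(k+\rho)$ is refused.

One consequence of the absorbing mutant state is worth knowing: raising
`k_cut` (e.g. to mimic heat treatment) strictly increases the broken
fraction throughout the early transient, but the faster cutter also
exhausts its cuttable pool sooner, so broken-DNA curves for two `k_cut`
values cross at late times (about 36 h for the defaults). With
non-mutagenic repair (`mu_mut = 0`) the increase is strict at every time,
and that is the regime in which the package asserts the property.

### The qPCR readout and `delivery_scale`

`simulate_ct_table()` converts population states to wells: the test-sample
cut-site amplicon sits at `ct_baseline - log(q)/log(1 + E)` cycles (mutant
DNA amplifies — a small indel does not abolish primer binding), reference
assays and wild-type controls sit at `ct_baseline`, the Cas9 cDNA assay at
`ct_baseline - log2(cas9_level * delivery_scale)`, and independent Gaussian
noise of `ct_noise_sd` (default 0.2 cycles, a typical well-to-well SD for
SYBR assays) is added to every well under a single integer seed.

`delivery_scale` models a transformation-boosting treatment such as
sonication as a *population* multiplier: the machinery reaches
proportionally more cells, so the tissue-level broken-DNA abundance
(`delivery_scale * f_broken`) and the Cas9 transcript abundance rise
together while within-cell kinetics are untouched. This is the design
choice that makes the relative cutting efficiency exactly invariant under
delivery scaling — the pattern that distinguishes "more delivery" from
"better cutting" — which is the scientific point of normalising by Cas9.
Had `delivery_scale` instead multiplied the cutting rate inside the ODE,
the broken fraction would not scale proportionally and the invariance
would fail; that alternative is what `k_cut` itself is for.
`simulate_tcep_experiment()` bypasses the kinetics entirely and emits a
table whose noiseless canonical quantification returns exactly the
prescribed broken fractions — the workhorse for estimator validation.

### What the generator does and does not emulate

It reproduces the features the estimators rely on: template-loss Ct
shifts, shared references, replicate structure, well-level Gaussian noise,
delivery scaling. It does not emulate per-assay amplification-efficiency
differences between amplicons (only one global `E`), pipetting or
plate-position effects, non-Gaussian dropout near the detection limit,
primer-binding loss from large deletions, cell-to-cell delivery
heterogeneity, or off-target cutting. Passing the parameter-recovery
suites therefore shows the estimators are correct *given* the ΔΔCt
measurement model, not that real plates satisfy that model.

## Target-site scanning

`scan_pam_sites()` reports every position where `spacer_len` bases (default
20, minimum 17) are followed on the same strand by a PAM matching an IUPAC
pattern (default `NGG`). Coordinates are 0-based, half-open, forward-strand;
`cut_pos` is an inter-base index (a cut between bases $i-1$ and $i$ is
$i$), placed exactly 3 bp 5′ of the PAM: `pam_start - 3` on the forward
strand, `pam_start + 6` for a reverse site whose PAM occupies
`[pam_start, pam_start + 3)`. This convention makes the amplicon test
unambiguous: an amplicon `[start, end)` spans the cut iff
`start < cut_pos < end`, so an amplicon ending exactly at the cut does not
span it and is a valid reference. `N` is tolerated in input but never in a
reported spacer or PAM (primers cannot target ambiguous bases); sites are
reported even when they overlap, since ranking and filtering are the
user's concern. The scanner is validated against a brute-force double-loop
oracle and a strand-reflection identity in the test suite.

## Validation problem sizes

The suites validate the pipeline end to end at desk scale: exact recovery
of prescribed broken fractions from noiseless tables (machine precision);
parameter recovery within 0.02 of truths 0.1/0.25/0.5/0.75 averaged over
200 seeded noisy triplicate experiments at 0.2 cycles of Ct noise; a
five-target experiment spanning a 6.5-fold true range recovered as at
least 6-fold; scanner oracle equivalence on random sequences up to 200 nt;
and kinetics conservation to $10^{-8}$. These sizes were chosen as the
smallest at which the stochastic checks are stable.

## Known limitations

Ct values are treated as given — no amplification-curve fitting, melt-curve
QC, standard-curve calibration or multi-reference normalisation. The
estimators assume perfect amplification efficiency; with $E < 1$ the
broken fraction is over-estimated by a factor the simulator can quantify.
Cutting efficiency is not editing efficiency: the mutation yield also
depends on repair outcomes, which the kinetics model only summarises
through a single mutation probability `mu_mut`. The t-tests assume equal
variances and independent replicates, and with three replicates per group
they have limited power.
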