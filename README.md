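# tcep: Cas9 cutting efficiency from transient-editing qPCR assays

Choosing a guide RNA that Cas9 actually cuts well is a recurring bottleneck
in plant genome editing: stable transformation takes months, and the
classical in vitro digestion assay needs purified Cas9 protein and
synthesised gRNA. `tcep` implements the quantification side of a much
faster route: transiently transform tissue with a standard CRISPR/Cas9
vector, let Cas9 cut for ~48 h, and read the damage out with qPCR.

The measurement principle: at any moment the target locus is a mixture of
intact wild-type DNA, intact mutated DNA (repaired with an indel), and
broken DNA. Broken molecules cannot serve as a qPCR template, so an
amplicon spanning the predicted cut site amplifies late in proportion to
how much of the locus is broken. For who this is for: anyone ranking
candidate guide sequences, or testing treatments (heat, sonication, ...)
that might change cutting, without making stable lines.

## The estimators

With `Ct(T)`/`Ct(T-inter)` the cut-site and internal-reference amplicons in
the edited ("test") sample, and `Ct(C)`/`Ct(C-inter)` the same assays in
untreated wild-type plants:

    ΔΔCt    = Ct(T) − Ct(T-inter) − Ct(C) + Ct(C-inter)
    intact  = 2^−ΔΔCt            # surviving amplifiable fraction
    broken  = 1 − 2^−ΔΔCt        # broken-DNA fraction ("canonical" mode)

Cas9 expression is measured by RT-qPCR, `cas9 = 2^−(Ct(Cas) − Ct(inter))`,
and the **relative cutting efficiency** is `broken / cas9`, which corrects
for how much editing machinery each sample actually received. Efficiencies
are fold-normalised so the weakest target reads 1. The companion in vitro
estimator for digests of purified amplicons is `1 − 2^−(Ct(a) − Ct(inter))`
— the same closed form, so a ΔΔCt of 2 means 75% broken DNA in both.

A `"literal"` mode reporting the raw relative quantity `2^−ΔΔCt` instead of
the broken fraction is available for cross-checking; see the methods
vignette for why `"canonical"` is the default.

The package also ships an NGG PAM scanner (`scan_pam_sites()`, blunt cut
placed exactly 3 bp 5′ of the PAM, BED6 output), amplicon validity checks
(`validate_amplicon()`: the assay amplicon must span the cut, the reference
must not), a three-state cut/repair kinetics simulator with a noisy qPCR
readout (`simulate_cut_repair()`, `simulate_ct_table()`,
`simulate_tcep_experiment()`), treatment comparison with Student's t-tests
(`tcep_compare()`), and a command-line pipeline
(`inst/cli/tcep.R`: `scan`, `simulate`, `quantify`, `invitro`, `compare`).

## Worked example

Simulate a triplicate experiment for three target sites whose true broken
fractions are 0.08, 0.25 and 0.52, with 0.1 cycles of Gaussian Ct noise,
then quantify it:

```r
library(tcep)
rec <- simulate_tcep_experiment(c(site1 = 0.08, site2 = 0.25, site3 = 0.52),
                                readout = readout_params(ct_noise_sd = 0.1, seed = 42))
fit <- tcep_quantify(rec)
fit
#> Cas9 cutting efficiency quantification (canonical mode, pairing: mean_control)
#>  target condition  ddct broken   cas9 efficiency  fold n sig
#>   site1   control 0.138 0.0912 0.9762    0.09398 1.000 3
#>   site2   control 0.294 0.1846 0.8987    0.19190 2.042 3
#>   site3   control 1.100 0.5333 1.0750    0.49510 5.268 3
#> reference (lowest efficiency, fold = 1): site1
```

`ddct` is the double Ct difference per target (replicate-mean Ct), `broken`
the estimated broken-DNA fraction (close to the simulated truths), `cas9`
the relative Cas9 expression, `efficiency` their ratio, and `fold` the
efficiency relative to the weakest target — here site3 cuts ~5.3× better
than site1. A `*` in `sig` would mark a p < 0.05 Student's t-test between
two treatment conditions, had the table contained them.

Scanning a sequence for candidate sites:

```r
scan_pam_sites("TTGCAGGTACTGATCCAAGGCTGGAATTCGG")
#> 2 Cas9 target site(s)
#>   seq_id strand               spacer pam pam_start cut_pos spacer_start spacer_end
#> 1    seq      + TGCAGGTACTGATCCAAGGC TGG        21      18            1         21
#> 2    seq      + ACTGATCCAAGGCTGGAATT CGG        28      25            8         28
```

`cut_pos` is a 0-based inter-base coordinate, always 3 bp 5′ of the PAM.

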