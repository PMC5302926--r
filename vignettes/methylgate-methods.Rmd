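---
title: "Input-template gating for PCR methylation assays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Input-template gating for PCR methylation assays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylgate)
```

## The problem

Bisulfite-PCR methylation assays (MethyLight, MSP, DHPLC-based readouts)
call a sample methylation-negative when the methylated target fails to
amplify. At low amounts of input template (TAIT), that failure is often a
sampling artefact: bisulfite conversion degrades DNA, leaves fragile
single strands, and only one strand is amplifiable, so a reaction loaded
with a few nanograms of converted DNA may simply not contain an intact
methylated molecule. Negative calls on such reactions are false negatives
waiting to happen — a serious issue for FFPE material and body-fluid DNA,
where input is scarce and degraded.

methylgate implements the complete countermeasure: characterise the
assay's methylated-template detection limit on a dilution array, convert
it into a minimum-TAIT policy with an operational reference-gene Ct gate,
apply the gate to cohorts, and re-analyse gated-out samples at boosted
input. A stochastic single-molecule simulator stands in for patient
cohorts, whose per-sample data are not publicly available.

## The dilution array and its arithmetic

The detection limit is measured on a two-axis array: fully methylated
bisulfite DNA (RKO cells) is serially diluted 1, 1/2, ..., 1/64 with
unmethylated bisulfite DNA (GES1 cells) at equal concentration — this
scales the *methylated fraction* while leaving total DNA unchanged — and
each mixture is further diluted 1, 1/2, 1/4, 1/8 with TE buffer, which
scales total and methylated DNA together and leaves the percentage
unchanged. `build_array()` generates the 28 conditions and maintains the
identity `net = total x pct / 100` exactly at full precision.

Two numerical choices deserve a note:

* **Base amounts.** The bundled reference design starts at 18.78 ng total
  and 1.18 ng methylated DNA per reaction (6.3%). The prose-level stock
  concentrations that surround such bench tables (10 ng/uL stocks,
  0.7 ng/uL working solution, 1.7 uL aliquots) are mutually inconsistent
  with these amounts at the 0.01 ng level (0.7 x 1.7 = 1.19 ng); the
  tabulated amounts are treated as authoritative and no reconciliation is
  attempted.
* **Rounding.** Printed amounts are reproduced by decimal rounding of the
  exact binary value (`sprintf` semantics), not by `base::round()`. The
  distinction matters only for apparent ties: 1.18/4 = 0.295 is stored
  fractionally below the tie and prints 0.29, while 1.18/8 = 0.1475 is
  stored with a remainder above half a hundredth and prints 0.15. Both
  match the reference table; a half-away-from-zero rule on exact decimals
  cannot match both. Amounts print to 2 decimals, falling back to 3
  decimals below 0.01 ng; percentages print to 1 decimal.

## The detection limit: a deterministic full-replicate rule

`estimate_detection_limit()` returns the smallest net methylated amount
present in the array such that *every* condition at or above it — across
all carrier-DNA and buffer backgrounds — was detected in the entire
replicate set. This is deliberately not a probabilistic LOD95: the rule
is the field's operational "consistently detected in triplicate"
criterion, constrained to amounts actually tested (no interpolation
between dilution steps). On the bundled array both GFRA1 and P16 give
0.15 ng. Cells of the reference table that are printed neither as
fully detected nor with a dropout footnote are encoded as `PARTIAL`;
the estimated limits are insensitive to that choice because a `PARTIAL`
cell at 0.07 ng blocks any lower limit regardless.

If even the largest tested amount has replicate dropout, there is no
reliable limit and the estimator raises a typed error carrying the
offending conditions rather than guessing.

## From limit to policy

With a methylated-proportion cutoff `c` defining a positive sample
(1.6% is the bundled default: a sample at the cutoff still carries the
limit amount of methylated DNA), the minimum TAIT is

    min_tait = detection_limit / c        # 0.15 / 0.016 = 9.375 -> 9.4 ng

The reference-gene Ct threshold equivalent to the minimum TAIT is read
from a standard series of (total ng, mean reference Ct) points. The
nearest point within 5% relative distance is used directly — matching
the bench practice of reading the threshold off the closest dilution row
(the 9.39 ng row, Ct 29.34, hence the printed 29.3); only when no point
is that close does the package interpolate linearly in Ct versus
log2(amount), which on the bundled points would give about 29.4 instead.
The total DNA requirement is `ceiling(min_tait x n_reactions)`: 38 ng
for four reactions (two targets, duplicate reference).

The gate itself is boundary-inclusive (`Ct <= threshold` is
informative), and a reference that never amplified is a distinct
`NO_REFERENCE` assay failure, not a non-informative sample.

## Calling and re-analysis

A target is called positive only on full-replicate detection; partial
detection folds into negative by default (an `indeterminate` tri-state is
available behind a flag). Externally called binary assays (MSP, DHPLC)
are gated by the same reference-Ct rule, with the assay kind recorded.
`reanalyze()` checks that the re-assay covers every pass-1
non-informative sample, rescored with identical rules; samples still
above the threshold after boosting are flagged and excluded from the
pass-2 positive rate, since their negative calls remain unreliable.

## Cohort statistics

Positive-rate comparisons use the Pearson chi-square on 2x2 tables (no
continuity correction by default; Yates behind a flag), with an error —
not a silent fallback — on zero expected counts. Ct group comparisons
report the Mann-Whitney U (midranks, tie-corrected normal-approximation
two-sided p, appropriate at cohort sizes of 40+) alongside a Welch t
test, medians, means, and `delta_ct = median(b) - median(a)` (positive
means group b has less input template). Exact rank enumeration appears
only as a test oracle. Note one boundary case surfaced by the acceptance
suite: the informative-versus-non-informative 2x2 table reconstructed
from published rates (64/18 vs 16/18) has Pearson p = 0.0010235, which
rounds to the printed 0.001 but is not strictly below it; the package
reports the exact value.

## The simulator: what it emulates, and what it does not

`simulate_reaction()` draws the number of amplifiable template copies as
Poisson with mean `total_ng / ng_per_copy` (times the methylated
fraction for a target amplicon); each copy independently survives
bisulfite damage, strand loss and priming with probability `p_amp`; zero
survivors give an undetermined well, otherwise
`Ct = ct_at_one_copy - log(K)/log(efficiency) + N(0, sigma_ct)`,
censored at `max_cycles`. The analytic companion
`detection_probability(lambda, p) = 1 - exp(-lambda p)` is the oracle
the stochastic path is tested against.

Defaults were calibrated once against the bundled array and are part of
the stated world, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `ng_per_copy` | 0.0066 ng | one haploid genome ~3.3 pg; one strand amplifiable after conversion |
| `efficiency` | 1.74 | the reference-Ct column spans ~1.25 cycles per 2-fold dilution |
| `p_amp` | 0.22 | places the ~5-effective-copy reliable-detection point at 0.15 ng |
| `ct_at_one_copy` | 39.7 | intercept fit to the reference column (27.9 at 18.78 ng); also reproduces the target Ct ~32.9 at 1.18 ng |
| `sigma_ct` | 0.25 | replicate scatter of the reference column |
| `max_cycles` | 40 | standard run length |

Degradation, conversion failure and strand loss are collapsed into the
single `p_amp`; there is no sequence-level model, no amplification-curve
simulation, and deliberately no false-positive mechanism (unmethylated
templates never produce target signal, consistent with the observed lack
of interference from the carrier DNA). Cohort generation draws FFPE
samples from a lower-DNA log-normal regime than frozen samples (median
available extract 50 vs 300 ng, log-sd 1.0 vs 0.8; 1/20 of the extract
loaded per reaction in the unadjusted first pass — values chosen once to
put unadjusted FFPE reference Ct mostly above the 29.3 gate and frozen
mostly below, the situation the policy exists to detect) and, by
default, makes 70% of samples truly methylated with log-normal fractions
of median 10%. One master seed drives deterministic per-sample and
per-condition substreams, so plates are reproducible independently of
generation order.

A green simulator test therefore establishes that the *estimator and
workflow* behave correctly under the single-molecule sampling model — it
does not establish anything about real bisulfite chemistry, pipetting
error (subsumed into `sigma_ct`), inhibitors, or between-run drift,
none of which are modelled.

## Known limitations

* The detection limit is quantised to tested amounts; arrays with coarse
  axes give coarse limits by design.
* The Mann-Whitney p uses the normal approximation; below ~8 samples per
  group prefer an exact test.
* Published cohort-level differences (group medians, delta-Ct values)
  require per-sample data that are not public; the simulator reproduces
  the qualitative phenomena (positive samples carry more template;
  boosted re-analysis raises the positive rate) rather than those
  numbers.
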