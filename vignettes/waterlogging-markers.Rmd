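---
title: "Selecting waterlogging damage-severity marker genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting waterlogging damage-severity marker genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodmark)
```

Waterlogged soil starves roots of oxygen. A grapevine can survive a short
flood if drained in time, but past a critical stress duration the damage
becomes irreversible even though the plant still looks viable. floodmark
implements a complete screen for *damage-severity marker genes*: genes
whose expression breaks abruptly right after that critical duration, so
that a one-off qPCR measurement can tell a recoverable plant from a doomed
one. This vignette explains each stage's model, its tunable parameters,
the synthetic data the package tests itself on, and the design decisions
behind the defaults.

## 1. Replicate-free two-library differential expression

The transcriptome design is one composite control (CK) library against one
composite waterlogged (CT) library — no biological replicates, so
dispersion cannot be estimated. The appropriate model is random sampling:
each gene's count $k_i$ in library $i$ is Binomial$(n_i, p)$ with $n_i$
the mapped total and $p$ the gene's (unknown) expression proportion,
shared under the null.

On the MA plane, $M = \log_2 k_1 - \log_2 k_2$ and
$A = (\log_2 k_1 + \log_2 k_2)/2$. Under the null, $p$ is estimated from
$A$ as $\hat p = 2^A/\sqrt{n_1 n_2}$, and the normal approximation of
$\log_2$ of a Binomial gives

$$E[M \mid A] = \log_2(n_1/n_2), \qquad
\mathrm{Var}[M \mid A] = \frac{4\,\sigma_1^2 \sigma_2^2}{\sigma_1^2 + \sigma_2^2},
\quad \sigma_i^2 = \frac{1-\hat p}{n_i\,\hat p\,\ln^2 2}.$$

`mars_test()` standardizes $M$ against these moments and returns a
two-sided normal p-value. The approximation is validated against an exact
oracle, `exact_cond_test()`: conditional on $T = k_1 + k_2$,
$k_1 \sim \mathrm{Binomial}(T, n_1/(n_1+n_2))$, and the two-sided p-value
sums all outcomes no more likely than the observed one
(minimum-likelihood rule). Over the full grid $k_1,k_2 \in 1..50$ the two
p-value sets agree with Spearman correlation above 0.99, and for counts
at or above 100 the log p-values agree within a few percent.

Genes with a zero count in exactly one library get no finite log2 fold
change; they are reported as library-specific transcripts
(`classify_presence()`) and their p-value comes from the exact test.
`bh_adjust()` applies Benjamini–Hochberg step-up adjustment (the standard
reading of an FDR threshold; backed by `stats::p.adjust`). A gene is a
DEG when $|\log_2 \mathrm{FC}| \ge 1$ **and** $q < 0.001$; both
thresholds are exposed (`fc_threshold`, `q_threshold`) because stricter
and looser variants of the q cut-off are in circulation for this design.
The fold change is treated over control,
$\log_2\!\big((k_{CT}/n_{CT})/(k_{CK}/n_{CK})\big)$, so stress-induced
genes come out positive. RPKM ($10^9 k /(n\,L)$) is computed per library
for reporting.

One subtlety worth stating: with realized library totals in the
denominator, fold changes are *relative to library composition*. Planting
many strong effects shifts the total mass of the treated library, which
offsets every gene's observed fold change by a common constant. This is a
property of the design, not of the test; the package's round-trip tests
therefore compare planted effects after removing the offset estimated
from null genes, and false-discovery rates are assessed on DEG calls
(which require the fold-change criterion), where the small offset is
immaterial.

## 2. qPCR quantification

`relative_expression()` implements $2^{-\Delta\Delta C_t}$:
$\Delta C_t = C_t^{target} - C_t^{reference}$ per well,
$\Delta\Delta C_t$ against the mean $\Delta C_t$ of the calibrator
sample, assuming 100% amplification efficiency (base 2). The calibrator
defaults to the **treated sample at 0 h** (stress onset), so the series
starts at 1 and trends read directly as change under stress; calibrating
to time-matched CK is available through the `calibrator_*` arguments
since either convention is defensible. Uniform Ct offsets cancel exactly
(shift invariance), which the tests verify.

`fit_standard_curve()` supports efficiency-corrected absolute
quantification: a least-squares line of Ct on $\log_{10}$(copies) with
$E = 10^{-1/\mathrm{slope}} - 1$ (slope $-3.32$ ⇒ 100%). Slope recovery
is checked on triplicate 6-point 10-fold dilution series at Ct noise
sd 0.1 — the realistic assay layout; with single wells the slope's own
standard error (≈0.024 cycles per decade) exceeds the recovery tolerance,
so replication is part of the stated design.

`build_series()` aggregates technical replicates into mean ± SE per time
point (SE across replicate $2^{-\Delta\Delta C_t}$ values, not across
Cts, matching the mean ± s.e. reporting convention). Missing time points
shorten the series; nothing is imputed, and no outlier rejection is
applied because none is described for the assay.

## 3. Trend screen

"Continual" expression — one monotone move across the whole treatment
window — is formalized as a Mann–Kendall-style concordance criterion:
$S = \sum_{i<j} \mathrm{sign}(x_j - x_i)$ (ties count 0),
$\tau = S/\binom{T}{2}$, plus a reversal veto: no adjacent *decrease*
(for an up call) may exceed its noise,
$|x_{t+1}-x_t| > z_{adj}\sqrt{se_t^2 + se_{t+1}^2}$. Defaults:
$\tau_{min} = 0.8$, minimum overall swing $a_{min} = 1$ log2 (2-fold),
$z_{adj} = 2$. A series below $a_{min}$ is `flat`; everything else that
is neither monotone class is `non_continual`. These defaults were
calibrated on the synthetic panels only — the original screen is verbal,
so the quantitative rule is this package's formalization.

`discriminability()` handles a failure mode specific to marker hunting:
genes that crash to their floor immediately and then sit there. Such
profiles are monotone but carry no information about *how long* the
stress lasted, because no two later time points can be told apart. A
series is `saturating` when its whole significant movement happens within
the first `k_sat = 2` points, in one direction, with nothing
distinguishable afterwards; `screen_panel()` demotes these genes from the
continual classes. On the default 30-gene panel mix (6 continual-up, 3
continual-down, 5 saturating decliners, 10 transient, 6 flat) at Ct noise
0.15 and 3-log2 amplitude, the modal screen outcome is 9 continual genes
(6 up, 3 down), and per-gene accuracy on the monotone classes exceeds
95%.

## 4. Critical time from the recovery assay

The recovery assay drains 10 plants per waterlogging duration
(0–144 h by 24) and records survival. `critical_time()` takes the
survival fractions, projects them onto the nearest non-increasing
sequence when sampling noise makes them wiggle (isotonic regression;
survival cannot genuinely improve with longer stress), and returns the
largest duration whose smoothed fraction still reaches the majority
threshold (default 0.5). The value stays on the sampled grid — the
conclusion is grid-valued, and interpolating between 24-h samples would
claim resolution the assay does not have. If even the first treated
duration loses the majority, $t_c = 0$ is returned with a warning flag.

`fit_logistic_survival()` summarizes the same schedule parametrically:
survivors $\sim$ Binomial$(n, 1/(1+e^{(d-t_{50})/s}))$, fitted by
binomial GLM (the maximum-likelihood route), with delta-method standard
errors and a flag for complete separation (all-survive-then-all-die has
no interior optimum). At the design size of 10 plants per duration the
median $|\hat t_{50} - t_{50}|$ over simulated assays is well under 6 h.

## 5. Sharp signals and the marker rule

A marker gene must do something *abrupt* right after the critical time.
`sharp_signal()` finds the adjacent step with the largest
$|\log_2(x_{t+1}/x_t)|$ and keeps it when it is both large
($\ge \theta = 1$ log2, a 2-fold jump) and abrupt relative to the rest of
the series (contrast $\ge 2$ against the median remaining step) — the
contrast term exists so that steep-but-uniform geometric profiles never
alarm. The signal is scale-invariant by construction.

`select_markers()` admits a gene when its sharp signal lands in the alarm
window $(t_c, t_c + \Delta]$ (default $\Delta = 48$ h, wide enough to
cover a second sampling interval for late responders) and its behaviour
through $t_c$ is informative: either rising through the critical time, or
declining *slowly* — monotone down before the break with a total
pre-$t_c$ decline of at most 1 log2. The slow-decline test is applied
directly to the pre-break segment rather than through the signal's
`pre_trend` label, whose 1-log2 flatness cut-off would erase exactly
these shallow decliners. Fast-saturating decliners are excluded (via the
trend screen's flag or simply because their big step happens well before
$t_c$). The alarm *direction* recorded per marker is whatever the
training panel showed — descriptions of such signals are contradictory
across sources (sharp decrease vs sharp increase for the same genes), so
the rule is learned from data, not asserted.

`predict_damage()` replays each marker's detector on a new panel: an
alarm fires when a sharp signal with the trained direction lands in the
window. With $m = 2$ of 3 alarms (default; $m = 3$ gives the conjunctive
reading) the verdict is `irrecoverable`; zero alarms is `recoverable`;
anything between is `indeterminate`. The panel must cover the alarm
window, and markers missing from it count as not evaluable.

## 6. What the synthetic data emulate — and what they do not

`sim_config()` fixes the study conditions: two ~2×10⁷-read libraries
(scaled to 2×10⁶ and 1 000–5 000 genes in the test suite so the whole
suite runs in minutes; the statistics are count-depth-per-gene
equivalent), 10% planted DE with |log2FC| centred on 2, the 8-point qPCR
grid (0–144 h including 12 h), 3 technical replicates at Ct noise
sd 0.15, the 7-duration recovery grid with 10 plants each and logistic
survival $t_{50} = 60$ h, $s = 10$ h (placing the majority-survival
boundary between 48 h and 72 h), and 52 leaves per symptom time point.

Counts are Poisson, not negative-binomial — deliberately: each library is
a single composite sample, so the random-sampling model *is* the
generative model, and the DE test's calibration can be checked honestly
(null p-values are uniform to KS < 0.05). Latent qPCR curves are
piecewise-linear in log2 space, the simplest family that reproduces the
observed profile shapes. A deterministic expected-counts mode supports
exact round-trip tests.

The marker demonstration panel (`simulate_marker_panel()`) plants the
three break shapes — rise-to-48 h-then-drop, rise-to-72 h-then-drop,
slow-decline-then-sharp-drop — plus three controls (steady riser,
fast-saturating decliner, flat). The rule-training demonstrations use the
noise-free panel: they are about reproducing the planted shapes, while
noise robustness is exercised separately by the rescued/collapse
prediction simulations at Ct noise 0.15, where rescued panels (no
post-critical collapse) come out `recoverable` in ≥95% of runs.

What the generator does **not** emulate: GC/length bias, mapping
artifacts, biological replicate variance, amplification-efficiency
differences between primer pairs, inter-plant variability in the qPCR
material, or correlated survival between plants sharing a pot. Passing
tests therefore demonstrate that the pipeline's logic and calibration are
correct under its own model assumptions — not that the assumptions hold
for any particular field data set.

## 7. Numerical choices and degenerate inputs

* Half-up rounding (not banker's) at the decimal counts reports use:
  2 decimals for DEG and annotation percentages, 1 for symptom
  percentages.
* `mars_test` caps $\hat p$ below 1; zero counts are a precondition error
  directing callers to the exact path; $T=0$ in the exact test returns
  p = 1 by convention.
* Kendall ties contribute 0 to $S$; an all-tied series is `flat`.
* Isotonic projection is idempotent and leaves monotone schedules
  untouched; raising any survival fraction can only delay $t_c$
  (verified as a property test).
* Empty marker rules and uncovered alarm windows are warnings/errors, not
  silent empties, at prediction time.

## 8. Worked pipeline

```{r pipeline}
cfg <- sim_config(seed = 42)

# critical time from a simulated recovery assay
sched <- simulate_recovery(cfg)
tc <- critical_time(sched)
tc

# trend screen on the 30-gene panel
panel <- simulate_qpcr_panel(cfg)
series <- build_series_panel(panel$panel)
screen_panel(series)$tally

# marker rule from the planted break shapes, and prediction
train <- build_series_panel(
  simulate_marker_panel(sim_config(seed = 42, ct_noise_sd = 0),
                        "collapse")$panel)
rule <- select_markers(train, t_c = tc$t_c)
rule

rescued <- build_series_panel(
  simulate_marker_panel(sim_config(seed = 43), "rescued")$panel)
predict_damage(rescued, rule)
```

## 9. Known limitations

The trend screen's quantitative thresholds are this package's
formalization of a verbal criterion and were calibrated on synthetic
panels only. The critical time inherits the recovery assay's 24-h grid
resolution. The DE module is strictly two-library; with replicates, a
dispersion-aware model (e.g. negative-binomial GLMs) should replace it.
Marker direction and window are learned from one training scenario and
should be re-trained per cultivar and stress regime before any field
use.
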