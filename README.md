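# floodmark

Marker-gene selection for waterlogging damage severity in grapevine.

Waterlogged soil deprives roots of oxygen. A flooded grapevine can be
rescued by drainage — but only up to a critical stress duration, after
which it dies even though no lethal phenotype is visible yet. floodmark
implements the full screen that turns this into a molecular diagnostic:

1. **Replicate-free differential expression** between one control (CK)
   and one waterlogged (CT) RNA-seq library, using the MA-plot
   random-sampling binomial model: with counts `k_i ~ Binomial(n_i, p)`,
   the statistic standardizes `M = log2 k1 − log2 k2` against its
   conditional null moments given `A = (log2 k1 + log2 k2)/2`
   (`E[M|A] = log2(n1/n2)`, `Var[M|A] = 4σ₁²σ₂²/(σ₁²+σ₂²)` with
   `σᵢ² = (1−p̂)/(nᵢ p̂ ln²2)`, `p̂ = 2^A/√(n1 n2)`), plus an exact
   conditional binomial oracle, Benjamini–Hochberg FDR, and RPKM.
   DEGs: `|log2FC| ≥ 1` and `q < 0.001`.
2. **qPCR quantification** by `2^−ΔΔCt` (with standard-curve efficiency
   support) into per-gene time courses over 0–144 h of stress.
3. **Trend screen**: Mann–Kendall-style monotonicity (`τ ≥ 0.8`, ≥2-fold
   swing, no significant reversal) with a discriminability filter that
   drops genes that crash to a floor immediately.
4. **Critical time** from a recovery assay (drain 10 plants per
   duration, count survivors): isotonic smoothing, then the largest
   duration keeping a ≥50% survival majority; plus a logistic
   `survival ~ duration` ML fit (`t50`, slope, SEs).
5. **Marker designation and prediction**: genes whose expression breaks
   sharply (≥2-fold adjacent step, ≥2× contrast) just after the critical
   time become alarms; on a new panel, ≥m firing alarms ⇒
   `irrecoverable`.

A synthetic-data generator (`sim_config()`, `simulate_*()`) reproduces
the statistical structure every stage assumes, so the entire pipeline is
runnable and tested without any external download.

## Worked example

```r
library(floodmark)
cfg <- sim_config(seed = 42)

sched <- simulate_recovery(cfg)          # 10 plants per duration
critical_time(sched)
#> Critical waterlogging duration: 48 h (majority rule >= 0.5)

screen_panel(build_series_panel(simulate_qpcr_panel(cfg)$panel))$tally
#>   continual_up continual_down  non_continual           flat      continual
#>              6              3             15              6              9

train <- build_series_panel(
  simulate_marker_panel(sim_config(seed = 42, ct_noise_sd = 0),
                        "collapse")$panel)
rule <- select_markers(train, t_c = 48)
rule
#> Marker rule: alarm window (48, 96] h, 2 alarm(s) => irrecoverable
#>    gene_id direction t_star_train delta_log2
#>   cat_like  decrease           96         -3
#>  gltx_like  decrease           72         -3
#>   pfk_like  decrease           72         -3

rescued <- build_series_panel(
  simulate_marker_panel(sim_config(seed = 43), "rescued")$panel)
predict_damage(rescued, rule)
#> Damage call: recoverable (0 of 3 marker alarm(s) fired)
```

Reading: under this simulated assay the majority of plants still survives
a 48-h flood but not a 72-h one, so 48 h is the critical duration. Of the
30-gene qPCR panel, 9 genes move monotonically through the whole window
(6 up, 3 down) and are usable as severity candidates. Three of them break
sharply (8-fold drops) inside the (48, 96] h alarm window and become
markers; a panel from a plant drained in time fires no alarm and is
called recoverable.

A thin command-line front end over the same functions is installed at
`inst/cli/floodmark.R` (subcommands `simulate`, `deg`, `qpcr`, `trend`,
`critical-time`, `select-markers`, `predict`, `report`).

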