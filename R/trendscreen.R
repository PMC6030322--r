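#' Classify a time course as continual (monotone) or not
#'
#' A gene shows a "continual" expression pattern when its relative
#' expression moves in one direction across the whole treatment window.
#' The screen formalizes this with a Mann-Kendall-style pairwise
#' concordance statistic `S = sum_{i<j} sign(rel_j - rel_i)` (ties
#' contribute 0), normalized to `tau = S / (T(T-1)/2)`, combined with a
#' no-significant-reversal rule: an adjacent step is noise-significant
#' when `|rel_{t+1} - rel_t| > z_adj * sqrt(se_t^2 + se_{t+1}^2)`.
#'
#' The call is `continual_up` when `tau >= tau_min`, the overall swing
#' `amplitude_log2 = |log2(max rel / min rel)|` is at least `a_min`, and
#' no adjacent decrease is noise-significant; `continual_down` is
#' symmetric; `flat` when the amplitude is below `a_min`; otherwise
#' `non_continual`.
#'
#' @param series an [build_series()] result (>= 4 time points).
#' @param tau_min minimum |tau| for a monotone call (default 0.8).
#' @param a_min minimum overall swing in log2 units (default 1, i.e. a
#'   2-fold change).
#' @param z_adj z multiplier for adjacent-step significance (default 2).
#' @param k_sat see [discriminability()].
#' @return one-row data frame (class `trend_call`): `gene_id, trend,
#'   s_stat, tau, amplitude_log2, n_discriminable, saturating`.
#' @export
classify_trend <- function(series, tau_min = 0.8, a_min = 1, z_adj = 2,
                           k_sat = 2) {
  rel <- series$rel
  T_ <- length(rel)
  if (T_ < 4)
    stop("trend classification needs >= 4 time points", call. = FALSE)
  if (any(rel <= 0)) stop("rel must be positive", call. = FALSE)
  s_stat <- sum(vapply(seq_len(T_ - 1), function(i)
    sum(sign(rel[(i + 1):T_] - rel[i])), numeric(1)))
  tau <- s_stat / (T_ * (T_ - 1) / 2)
  amplitude <- abs(log2(max(rel) / min(rel)))
  d <- adjacent_steps(series, z_adj)
  disc <- discriminability(series, z_adj, k_sat)
  trend <- if (amplitude < a_min) {
    "flat"
  } else if (tau >= tau_min && !any(d$sig & d$diff < 0)) {
    "continual_up"
  } else if (tau <= -tau_min && !any(d$sig & d$diff > 0)) {
    "continual_down"
  } else {
    "non_continual"
  }
  out <- data.frame(gene_id = series$gene_id[1], trend = trend,
                    s_stat = s_stat, tau = tau,
                    amplitude_log2 = amplitude,
                    n_discriminable = disc$n_discriminable,
                    saturating = disc$saturating,
                    stringsAsFactors = FALSE)
  class(out) <- c("trend_call", "data.frame")
  out
}

# adjacent differences and their noise significance
adjacent_steps <- function(series, z_adj) {
  rel <- series$rel
  se <- series$se
  T_ <- length(rel)
  diffs <- diff(rel)
  sig <- abs(diffs) > z_adj * sqrt(se[-T_]^2 + se[-1]^2)
  list(diff = diffs, sig = sig)
}

#' Discriminability of a time course's steps against noise
#'
#' Counts adjacent time pairs whose expression difference exceeds its
#' noise (`n_discriminable`), and flags "saturating" profiles: series
#' that make their whole move within the first `k_sat` points and are
#' indistinguishable between all later treatment times. Such genes track
#' the stress but cannot resolve its duration, so they are excluded from
#' marker candidacy. Formally, `saturating` is true when at least one of
#' the first `k_sat` adjacent steps is noise-significant, all these early
#' significant steps share one direction, and no later step is
#' noise-significant.
#'
#' @inheritParams classify_trend
#' @param k_sat number of initial points within which the move must
#'   complete (default 2).
#' @return list with `n_discriminable` and `saturating`.
#' @export
discriminability <- function(series, z_adj = 2, k_sat = 2) {
  d <- adjacent_steps(series, z_adj)
  idx <- seq_along(d$diff)          # step i joins points i and i+1
  early <- idx < k_sat + 1 & d$sig
  late <- idx >= k_sat + 1 & d$sig
  one_dir <- !any(early) ||
    all(sign(d$diff[early]) == sign(d$diff[early])[1])
  list(n_discriminable = sum(d$sig),
       saturating = any(early) && !any(late) && one_dir)
}

#' Trend screen over a panel of series
#'
#' Applies [classify_trend()] and [discriminability()] to every gene.
#' Saturating genes are removed from the continual classes (reported as
#' `non_continual` with the `saturating` flag kept) because their time
#' points cannot be told apart after the initial move.
#'
#' @param panel stacked series data frame ([build_series_panel()]).
#' @inheritParams classify_trend
#' @return list with `calls` (one `trend_call` row per gene) and
#'   `tally` (named counts per class, plus `continual`, the up + down
#'   total).
#' @export
screen_panel <- function(panel, tau_min = 0.8, a_min = 1, z_adj = 2,
                         k_sat = 2) {
  series <- split_series(panel)
  if (length(series) == 0) stop("empty panel", call. = FALSE)
  calls <- do.call(rbind, lapply(series, classify_trend,
                                 tau_min = tau_min, a_min = a_min,
                                 z_adj = z_adj, k_sat = k_sat))
  rownames(calls) <- NULL
  demote <- calls$saturating &
    calls$trend %in% c("continual_up", "continual_down")
  calls$trend[demote] <- "non_continual"
  lv <- c("continual_up", "continual_down", "non_continual", "flat")
  tally <- table(factor(calls$trend, levels = lv))
  tally <- c(as.vector(tally), sum(tally[c("continual_up",
                                           "continual_down")]))
  names(tally) <- c(lv, "continual")
  list(calls = calls, tally = tally)
}
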