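#' Largest abrupt step of an expression time course
#'
#' Finds the adjacent time pair with the largest absolute log2 change and
#' reports it as a sharp signal when it is both large (at least `theta`
#' log2 units) and abrupt relative to the rest of the series: `contrast`
#' is the step magnitude divided by the median absolute log2 step of the
#' remaining adjacent pairs, so a steep-but-uniform (geometric) series
#' never qualifies. `pre_trend` summarizes the series before the step:
#' `up`/`down` by the sign of the pairwise-concordance statistic when the
#' pre-step swing reaches 1 log2, `flat` otherwise.
#'
#' The signal is invariant to multiplying all expression values by a
#' positive constant.
#'
#' @param series an expression series (>= 4 time points, positive `rel`).
#' @param theta minimum |log2 step| (default 1, a 2-fold jump).
#' @param contrast_min minimum contrast against the rest of the series
#'   (default 2).
#' @return `NULL` when no step qualifies, else a list of class
#'   `sharp_signal`: `gene_id, t_star` (hour at the step's right end),
#'   `delta_log2`, `direction` (`increase`/`decrease`), `contrast`,
#'   `pre_trend`.
#' @export
sharp_signal <- function(series, theta = 1, contrast_min = 2) {
  rel <- series$rel
  t <- series$time_h
  if (length(rel) < 4)
    stop("sharp-signal detection needs >= 4 time points", call. = FALSE)
  if (any(rel <= 0)) stop("rel must be positive", call. = FALSE)
  steps <- diff(log2(rel))
  i <- which.max(abs(steps))
  delta <- steps[i]
  rest <- abs(steps[-i])
  contrast <- if (median(rest) == 0) Inf else abs(delta) / median(rest)
  if (abs(delta) < theta || contrast < contrast_min) return(NULL)
  pre <- rel[t < t[i + 1]]
  pre_trend <- "flat"
  if (length(pre) >= 2 && abs(log2(max(pre) / min(pre))) >= 1) {
    s <- sum(vapply(seq_len(length(pre) - 1), function(j)
      sum(sign(pre[(j + 1):length(pre)] - pre[j])), numeric(1)))
    pre_trend <- if (s > 0) "up" else if (s < 0) "down" else "flat"
  }
  out <- list(gene_id = series$gene_id[1], t_star = t[i + 1],
              delta_log2 = delta,
              direction = if (delta > 0) "increase" else "decrease",
              contrast = contrast, pre_trend = pre_trend)
  class(out) <- "sharp_signal"
  out
}

#' Designate damage-severity marker genes
#'
#' A gene becomes a marker when its expression breaks sharply just after
#' the critical waterlogging duration: its [sharp_signal()] must exist,
#' fall inside the alarm window `(t_c, t_c + window]`, and be consistent
#' with the gene's behaviour through the critical time -- either
#' elevated/rising through `t_c` (`pre_trend == "up"`), or declining
#' slowly through `t_c` (`pre_trend == "down"` with a total pre-`t_c`
#' decline of at most `slow_decline_max` log2 units; fast-saturating
#' decliners carry no duration information and are excluded). The alarm
#' direction recorded for each marker is the direction its sharp signal
#' showed on the training panel.
#'
#' @param panel stacked series data frame ([build_series_panel()]).
#' @param t_c critical time in hours, from [critical_time()].
#' @param window alarm-window width in hours after `t_c` (default 48).
#' @param m alarms required for an irrecoverable verdict (default 2;
#'   set to the number of markers for a conjunctive rule).
#' @param theta,contrast_min passed to [sharp_signal()].
#' @param slow_decline_max maximum |log2 decline| through `t_c` for
#'   down-markers (default 1).
#' @param trend_calls optional [screen_panel()] calls; genes flagged
#'   `saturating` are excluded from candidacy.
#' @return object of class `marker_rule`: `t_c, window, m, theta,
#'   contrast_min` and `markers`, a data frame with `gene_id,
#'   direction, t_star_train, delta_log2`. Empty (with a warning) when
#'   no gene qualifies.
#' @export
select_markers <- function(panel, t_c, window = 48, m = 2, theta = 1,
                           contrast_min = 2, slow_decline_max = 1,
                           trend_calls = NULL) {
  series <- split_series(panel)
  excluded <- character(0)
  if (!is.null(trend_calls))
    excluded <- trend_calls$gene_id[trend_calls$saturating]
  rows <- list()
  for (s in series) {
    gid <- s$gene_id[1]
    if (gid %in% excluded) next
    sig <- sharp_signal(s, theta, contrast_min)
    if (is.null(sig)) next
    if (!(sig$t_star > t_c && sig$t_star <= t_c + window)) next
    if (sig$pre_trend == "up") {
      ok <- TRUE
    } else {
      # slow decliner: monotone-down before the break, total decline
      # through t_c within slow_decline_max log2 (the pre_trend field
      # reads such shallow declines as flat, so test the slope directly)
      pre <- s$rel[s$time_h < sig$t_star]
      s_pre <- sum(vapply(seq_len(length(pre) - 1), function(j)
        sum(sign(pre[(j + 1):length(pre)] - pre[j])), numeric(1)))
      at_tc <- max(which(s$time_h <= t_c))
      decline <- log2(s$rel[at_tc] / s$rel[1])
      ok <- sig$direction == "decrease" && s_pre < 0 &&
        decline <= 0 && abs(decline) <= slow_decline_max
    }
    if (!ok) next
    rows[[gid]] <- data.frame(gene_id = gid, direction = sig$direction,
                              t_star_train = sig$t_star,
                              delta_log2 = sig$delta_log2,
                              stringsAsFactors = FALSE)
  }
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), direction = character(0),
               t_star_train = numeric(0), delta_log2 = numeric(0),
               stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  if (nrow(markers) == 0)
    warning("no marker genes qualified", call. = FALSE)
  out <- list(t_c = t_c, window = window, m = m, theta = theta,
              contrast_min = contrast_min, markers = markers)
  class(out) <- "marker_rule"
  out
}

#' @export
print.marker_rule <- function(x, ...) {
  cat(sprintf("Marker rule: alarm window (%g, %g] h, %d alarm(s) => irrecoverable\n",
              x$t_c, x$t_c + x$window, x$m))
  if (nrow(x$markers) == 0) cat("  (no markers)\n") else
    print(x$markers, row.names = FALSE)
  invisible(x)
}

#' Predict recoverability of a new sample panel
#'
#' For every marker in the rule, the alarm fires when the gene's series
#' in the new panel shows a sharp signal in the trained direction with
#' `t_star` inside the alarm window. The verdict is `irrecoverable` when
#' at least `m` alarms fire, `recoverable` when none fires, and
#' `indeterminate` otherwise. Markers missing from the panel are counted
#' as not evaluable; the panel must cover the alarm window.
#'
#' @param panel stacked series data frame for the new sample.
#' @param rule a [select_markers()] rule.
#' @return list of class `damage_call`: `verdict`, `alarms` (data frame
#'   `gene_id, evaluable, fired`), `n_fired`, `n_evaluable`.
#' @export
predict_damage <- function(panel, rule) {
  stopifnot(inherits(rule, "marker_rule"))
  if (nrow(rule$markers) == 0)
    stop("rule contains no markers", call. = FALSE)
  if (max(panel$time_h) < rule$t_c + rule$window)
    stop("panel does not cover the alarm window (", rule$t_c, ", ",
         rule$t_c + rule$window, "] h", call. = FALSE)
  series <- split_series(panel)
  res <- lapply(seq_len(nrow(rule$markers)), function(i) {
    gid <- rule$markers$gene_id[i]
    dir <- rule$markers$direction[i]
    if (!gid %in% names(series))
      return(data.frame(gene_id = gid, evaluable = FALSE, fired = FALSE,
                        stringsAsFactors = FALSE))
    sig <- sharp_signal(series[[gid]], rule$theta, rule$contrast_min)
    fired <- !is.null(sig) && sig$direction == dir &&
      sig$t_star > rule$t_c && sig$t_star <= rule$t_c + rule$window
    data.frame(gene_id = gid, evaluable = TRUE, fired = fired,
               stringsAsFactors = FALSE)
  })
  alarms <- do.call(rbind, res)
  if (!any(alarms$evaluable))
    stop("no marker gene evaluable in the panel", call. = FALSE)
  n_fired <- sum(alarms$fired)
  verdict <- if (n_fired >= rule$m) "irrecoverable"
    else if (n_fired == 0) "recoverable" else "indeterminate"
  out <- list(verdict = verdict, alarms = alarms, n_fired = n_fired,
              n_evaluable = sum(alarms$evaluable))
  class(out) <- "damage_call"
  out
}

#' @export
print.damage_call <- function(x, ...) {
  cat(sprintf("Damage call: %s (%d of %d marker alarm(s) fired)\n",
              x$verdict, x$n_fired, x$n_evaluable))
  invisible(x)
}
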