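#' Construct a recovery-assay survival schedule
#'
#' One row per waterlogging duration: how many plants were drained and
#' returned to normal growth after that duration, and how many survived.
#'
#' @param duration_h waterlogging durations in hours (unique, will be
#'   sorted ascending).
#' @param n_treated,n_survived plants treated and surviving per duration.
#' @return data frame of class `survival_schedule` with a derived
#'   `fraction` column.
#' @export
survival_schedule <- function(duration_h, n_treated, n_survived) {
  if (length(duration_h) == 0) stop("empty schedule", call. = FALSE)
  if (anyDuplicated(duration_h)) stop("durations must be unique",
                                      call. = FALSE)
  if (any(n_treated <= 0)) stop("n_treated must be positive", call. = FALSE)
  if (any(n_survived < 0) || any(n_survived > n_treated))
    stop("need 0 <= n_survived <= n_treated", call. = FALSE)
  o <- order(duration_h)
  out <- data.frame(duration_h = duration_h[o],
                    n_treated = n_treated[o],
                    n_survived = n_survived[o])
  out$fraction <- out$n_survived / out$n_treated
  class(out) <- c("survival_schedule", "data.frame")
  out
}

#' Critical waterlogging duration by the majority-survival rule
#'
#' The critical time is the longest waterlogging duration after which
#' the majority of plants can still be rescued by drainage. Observed
#' survival fractions that are not non-increasing in duration (sampling
#' noise at small n) are first replaced by their isotonic non-increasing
#' projection; the critical time is then the largest duration whose
#' (smoothed) fraction is at least `majority`. The value is reported on
#' the sampled duration grid, without interpolation.
#'
#' @param schedule a [survival_schedule()] with >= 2 durations including
#'   0.
#' @param majority survival fraction defining "majority" (default 0.5).
#' @return object of class `critical_time`: `t_c` (hours), `majority`,
#'   `fractions`, `fractions_smoothed`, `smoothed` (whether the isotonic
#'   projection changed anything) and `majority_lost` (TRUE, with a
#'   warning, when no treated duration retains a majority and `t_c`
#'   degenerates to 0).
#' @export
critical_time <- function(schedule, majority = 0.5) {
  stopifnot(inherits(schedule, "survival_schedule"))
  d <- schedule$duration_h
  if (length(d) < 2 || d[1] != 0)
    stop("schedule needs >= 2 durations including 0", call. = FALSE)
  f <- schedule$fraction
  fs <- f
  smoothed <- FALSE
  if (any(diff(f) > 0)) {
    fs <- -isoreg(seq_along(f), -f)$yf   # non-increasing projection
    smoothed <- TRUE
  }
  ok <- fs >= majority
  t_c <- if (any(ok)) max(d[ok]) else 0
  flag <- t_c == 0
  if (flag)
    warning("majority of survivors lost at the first treated duration; ",
            "t_c = 0", call. = FALSE)
  out <- list(t_c = t_c, majority = majority, fractions = f,
              fractions_smoothed = fs, smoothed = smoothed,
              durations_h = d, majority_lost = flag)
  class(out) <- "critical_time"
  out
}

#' @export
print.critical_time <- function(x, ...) {
  cat(sprintf("Critical waterlogging duration: %g h (majority rule >= %g)\n",
              x$t_c, x$majority))
  if (x$smoothed) cat("  (fractions isotonically smoothed)\n")
  invisible(x)
}

#' Maximum-likelihood logistic fit of survival against duration
#'
#' Fits `n_survived ~ Binomial(n_treated, p(d))` with
#' `p(d) = 1 / (1 + exp((d - t50) / s))` by binomial GLM (logit link);
#' `t50` is the duration of 50% survival and `s` the logistic scale in
#' hours. Standard errors come from the observed information via the
#' delta method. Complete separation (all-survive then all-die with no
#' mixed duration) is flagged: the likelihood then has no interior
#' maximum and the slope estimate diverges (step-like curve).
#'
#' @param schedule a [survival_schedule()] with >= 3 durations.
#' @return list of class `logistic_survival`: `t50_h, slope_h, se_t50,
#'   se_slope, separated`.
#' @export
fit_logistic_survival <- function(schedule) {
  stopifnot(inherits(schedule, "survival_schedule"))
  if (nrow(schedule) < 3)
    stop("logistic fit needs >= 3 durations", call. = FALSE)
  if (all(schedule$fraction == 1) || all(schedule$fraction == 0))
    stop("need both survivors and deaths somewhere in the schedule",
         call. = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(cbind(n_survived, n_treated - n_survived) ~ duration_h,
        family = binomial(), data = schedule),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  V <- vcov(fit)
  # t50 = -a/b, s = -1/b; delta-method gradients
  g_t50 <- c(-1 / b, a / b^2)
  g_s <- c(0, 1 / b^2)
  out <- list(t50_h = -a / b, slope_h = -1 / b,
              se_t50 = sqrt(drop(t(g_t50) %*% V %*% g_t50)),
              se_slope = sqrt(drop(t(g_s) %*% V %*% g_s)),
              separated = separated)
  class(out) <- "logistic_survival"
  out
}

#' @export
print.logistic_survival <- function(x, ...) {
  cat(sprintf("Logistic survival fit: t50 = %.1f h (se %.1f), slope = %.1f h (se %.1f)\n",
              x$t50_h, x$se_t50, x$slope_h, x$se_slope))
  if (x$separated) cat("  warning: complete separation; slope unreliable\n")
  invisible(x)
}

#' Percentage of symptomatic leaves per time point
#'
#' `100 * n_symptomatic / n_total`, rounded half-up to one decimal for
#' reporting.
#'
#' @param counts data frame with `time_h, n_symptomatic, n_total`.
#' @return `counts` with a `percent` column added.
#' @export
symptom_percentages <- function(counts) {
  need <- c("time_h", "n_symptomatic", "n_total")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$n_total <= 0))
    stop("n_total must be positive in every row", call. = FALSE)
  if (any(counts$n_symptomatic < 0 | counts$n_symptomatic > counts$n_total))
    stop("need 0 <= n_symptomatic <= n_total", call. = FALSE)
  counts$percent <- round_half_up(100 * counts$n_symptomatic /
                                    counts$n_total, 1)
  counts
}
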