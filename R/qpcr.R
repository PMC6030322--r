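#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10(input copies) over a dilution
#' series. The amplification efficiency is `E = 10^(-1/slope) - 1`; a
#' perfect doubling per cycle gives slope -3.32193 and `E = 1` (100%).
#'
#' @param copies known input copy numbers (> 0), at least 3 dilutions.
#' @param ct measured Ct values, one per dilution point.
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared` and `efficiency`.
#' @export
#' @examples
#' sc <- fit_standard_curve(10^(1:5), 40 - 3.32193 * (1:5))
#' sc$efficiency  # 1 (100%)
fit_standard_curve <- function(copies, ct) {
  if (length(copies) < 3 || length(ct) != length(copies))
    stop("need >= 3 dilution points with matching Ct values", call. = FALSE)
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  x <- log10(copies)
  if (sd(x) == 0) stop("zero variance in copies", call. = FALSE)
  fit <- lm(ct ~ x)
  slope <- unname(coef(fit)[2])
  out <- list(slope = slope,
              intercept = unname(coef(fit)[1]),
              # suppressWarnings: noise-free dilution series trip lm's
              # "essentially perfect fit" warning; R^2 is still defined
              r_squared = suppressWarnings(summary(fit)$r.squared),
              efficiency = 10^(-1 / slope) - 1)
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.3f %+.4f * log10(copies)\n",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.4f, efficiency = %.1f%%\n",
              x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Copy numbers from Ct values via a standard curve
#'
#' Inverts the fitted line: `copies = 10^((ct - intercept) / slope)`.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param ct Ct value(s).
#' @return estimated input copy numbers.
#' @export
ct_to_copies <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

check_ct_table <- function(panel) {
  need <- c("gene_id", "condition", "time_h", "replicate",
            "ct_target", "ct_reference")
  if (!all(need %in% names(panel)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(panel$ct_reference)))
    stop("missing reference-gene Ct for sample(s): ",
         paste(utils::head(which(is.na(panel$ct_reference)), 5),
               collapse = ", "), call. = FALSE)
  invisible(panel)
}

#' Per-sample relative expression by the 2^-ddCt method
#'
#' For every well of the gene, `dCt = ct_target - ct_reference`;
#' `ddCt = dCt - mean(dCt of the calibrator wells)`; relative expression
#' is `2^-ddCt`. The calibrator defaults to the treated sample at 0 h
#' (stress onset), so values read as change under stress and the
#' calibrator time point sits at 1. A uniform Ct offset applied to all
#' wells cancels out.
#'
#' @param panel long-format Ct table with columns `gene_id, condition,
#'   time_h, replicate, ct_target, ct_reference`.
#' @param gene gene to quantify.
#' @param calibrator_condition,calibrator_time_h the calibrator sample.
#' @return data frame with `condition, time_h, replicate, rel`.
#' @export
relative_expression <- function(panel, gene,
                                calibrator_condition = "CT",
                                calibrator_time_h = 0) {
  check_ct_table(panel)
  rows <- panel[panel$gene_id == gene, , drop = FALSE]
  if (nrow(rows) == 0) stop("gene not in panel: ", gene, call. = FALSE)
  dct <- rows$ct_target - rows$ct_reference
  cal <- rows$condition == calibrator_condition &
    rows$time_h == calibrator_time_h
  if (!any(cal))
    stop("calibrator sample (", calibrator_condition, ", ",
         calibrator_time_h, " h) absent for gene ", gene, call. = FALSE)
  ddct <- dct - mean(dct[cal])
  data.frame(condition = rows$condition, time_h = rows$time_h,
             replicate = rows$replicate, rel = 2^(-ddct),
             stringsAsFactors = FALSE)
}

#' Relative-expression time series for one gene
#'
#' Aggregates the per-well `2^-ddCt` values of one condition into a time
#' series: mean, standard error across technical replicates, and
#' replicate count per time point, sorted by time. No gap filling is
#' performed for missing time points.
#'
#' @inheritParams relative_expression
#' @param condition condition whose series to build (default `"CT"`).
#' @return object of class `expression_series`: a data frame with
#'   `gene_id, time_h, rel, se, n`.
#' @export
build_series <- function(panel, gene, condition = "CT",
                         calibrator_condition = "CT",
                         calibrator_time_h = 0) {
  vals <- relative_expression(panel, gene, calibrator_condition,
                              calibrator_time_h)
  vals <- vals[vals$condition == condition, , drop = FALSE]
  times <- sort(unique(vals$time_h))
  if (length(times) < 3)
    stop("panel covers fewer than 3 time points for gene ", gene,
         call. = FALSE)
  agg <- lapply(times, function(t) {
    v <- vals$rel[vals$time_h == t]
    data.frame(gene_id = gene, time_h = t, rel = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  class(out) <- c("expression_series", "data.frame")
  out
}

#' Relative-expression series for every gene of a panel
#'
#' @inheritParams build_series
#' @param genes genes to include (default all in the panel).
#' @return a stacked data frame of [build_series()] results (class
#'   `series_panel`).
#' @export
build_series_panel <- function(panel, genes = unique(panel$gene_id),
                               condition = "CT",
                               calibrator_condition = "CT",
                               calibrator_time_h = 0) {
  out <- do.call(rbind, lapply(genes, build_series, panel = panel,
                               condition = condition,
                               calibrator_condition = calibrator_condition,
                               calibrator_time_h = calibrator_time_h))
  class(out) <- c("series_panel", "data.frame")
  out
}

# split a stacked series panel into per-gene expression_series
split_series <- function(panel) {
  stopifnot(all(c("gene_id", "time_h", "rel", "se") %in% names(panel)))
  lapply(split(as.data.frame(panel), panel$gene_id), function(s) {
    s <- s[order(s$time_h), , drop = FALSE]
    class(s) <- c("expression_series", "data.frame")
    s
  })
}
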