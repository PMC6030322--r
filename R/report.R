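#' Summary of differential-expression calls
#'
#' Tallies the status and presence classes of a DEG table and reports
#' the share of up- and down-regulated genes among all DEGs, rounded
#' half-up to two decimals. With zero DEGs the percentages are `NA`.
#'
#' @param records a [deg_table()] result (columns `status`, `presence`).
#' @return list with `counts` (named vector: up, down, no_change, DEG
#'   total), `presence` (named vector), `percent_up`, `percent_down`.
#' @export
deg_summary <- function(records) {
  stopifnot(all(c("status", "presence") %in% names(records)))
  st <- table(factor(records$status,
                     levels = c("up", "down", "no_change")))
  n_deg <- sum(st[c("up", "down")])
  counts <- c(up = unname(st["up"]), down = unname(st["down"]),
              no_change = unname(st["no_change"]), deg = n_deg)
  pr <- table(factor(records$presence,
                     levels = c("both", "ck_only", "ct_only", "absent")))
  list(counts = counts,
       presence = setNames(as.vector(pr), names(pr)),
       percent_up = if (n_deg > 0)
         round_half_up(100 * counts[["up"]] / n_deg, 2) else NA_real_,
       percent_down = if (n_deg > 0)
         round_half_up(100 * counts[["down"]] / n_deg, 2) else NA_real_)
}

#' Percentage summary of database-annotation counts
#'
#' Reproduces the arithmetic of an annotation summary table: for each
#' database (and for rows such as "annotated in at least one database"),
#' the percentage of the unigene total, rounded half-up to two decimals.
#' The annotation counts themselves are inputs; no alignment is run.
#'
#' @param counts named vector of annotated-unigene counts.
#' @param total total number of unigenes (each count must not exceed it).
#' @return data frame with `category, count, percent`.
#' @export
#' @examples
#' annotation_summary(c(GO = 9326, any = 12634), 42895)
annotation_summary <- function(counts, total) {
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("counts must be named", call. = FALSE)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (any(counts < 0) || any(counts > total))
    stop("each count must lie in [0, total]", call. = FALSE)
  data.frame(category = names(counts),
             count = as.vector(counts),
             percent = round_half_up(100 * as.vector(counts) / total, 2),
             stringsAsFactors = FALSE)
}
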