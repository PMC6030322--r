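# Readers and writers for the pipeline's plain-text formats. All files
# are UTF-8 with '.' decimals; comment lines start with '#'.

#' Read a two-library count table
#'
#' Tab-delimited with header `gene_id length_bp count_ck count_ct`,
#' preceded by comment lines `# n_ck=<int>` and `# n_ct=<int>` carrying
#' the mapped-read library totals (and optionally `# seed=<int>`).
#'
#' @param path file path.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  header <- readLines(path, n = 10)
  grab <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), header, value = TRUE)
    if (length(ln) == 0) stop("missing '# ", key, "=' header line in ",
                              path, call. = FALSE)
    as.numeric(sub(paste0("^#\\s*", key, "=\\s*"), "", ln[1]))
  }
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  out <- count_table(x, n_ck = grab("n_ck"), n_ct = grab("n_ct"))
  seed_ln <- grep("^#\\s*seed=", header, value = TRUE)
  if (length(seed_ln))
    attr(out, "seed") <- as.integer(sub("^#\\s*seed=\\s*", "", seed_ln[1]))
  out
}

#' Write a two-library count table
#'
#' @param counts a [count_table()].
#' @param path file path.
#' @export
write_count_table <- function(counts, path) {
  stopifnot(inherits(counts, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_ck=%d", as.integer(attr(counts, "n_ck"))),
               sprintf("# n_ct=%d", as.integer(attr(counts, "n_ct")))),
             con)
  seed <- attr(counts, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", seed), con)
  write.table(as.data.frame(counts), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a long-format qPCR Ct table
#'
#' CSV with columns
#' `gene_id,condition,time_h,replicate,ct_target,ct_reference`.
#'
#' @param path file path.
#' @return Ct table data frame.
#' @export
read_ct_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE)
  check_ct_table(x)
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Write a qPCR Ct table
#' @param panel Ct table data frame.
#' @param path file path.
#' @export
write_ct_table <- function(panel, path) {
  check_ct_table(panel)
  write.table(as.data.frame(panel), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write stacked relative-expression series
#'
#' Tab-delimited with columns `gene_id,time_h,rel,se,n`.
#'
#' @param path file path.
#' @return stacked series data frame (class `series_panel`).
#' @export
read_series <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "time_h", "rel", "se", "n") %in% names(x)))
  class(x) <- c("series_panel", "data.frame")
  x
}

#' @rdname read_series
#' @param panel stacked series data frame.
#' @export
write_series <- function(panel, path) {
  write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a recovery-assay survival schedule
#'
#' CSV with columns `duration_h,n_treated,n_survived`.
#'
#' @param path file path.
#' @return a [survival_schedule()].
#' @export
read_survival_schedule <- function(path) {
  x <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE)
  survival_schedule(x$duration_h, x$n_treated, x$n_survived)
}

#' Read a leaf symptom-count table
#'
#' CSV with columns `time_h,n_symptomatic,n_total`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_symptom_table <- function(path) {
  x <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("time_h", "n_symptomatic", "n_total") %in% names(x)))
  x
}

#' Serialize / restore a marker rule as JSON
#'
#' @param rule a [select_markers()] rule.
#' @param path file path.
#' @export
write_marker_rule <- function(rule, path) {
  stopifnot(inherits(rule, "marker_rule"))
  jsonlite::write_json(unclass(rule), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_marker_rule
#' @return `read_marker_rule()` returns the restored `marker_rule`.
#' @export
read_marker_rule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$markers <- as.data.frame(x$markers, stringsAsFactors = FALSE)
  if (nrow(x$markers) == 0)
    x$markers <- data.frame(gene_id = character(0),
                            direction = character(0),
                            t_star_train = numeric(0),
                            delta_log2 = numeric(0))
  class(x) <- "marker_rule"
  x
}
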