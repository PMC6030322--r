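#' Construct a two-library count table
#'
#' A count table holds one row per gene with its length and its read
#' counts in the control (CK) and treated (CT) libraries, plus the mapped
#' totals of the two libraries as attributes.
#'
#' @param x data frame with columns `gene_id, length_bp, count_ck,
#'   count_ct`.
#' @param n_ck,n_ct mapped-read totals of the CK and CT libraries.
#' @return `x` with class `count_table` and attributes `n_ck`, `n_ct`.
#' @export
count_table <- function(x, n_ck, n_ct) {
  need <- c("gene_id", "length_bp", "count_ck", "count_ct")
  if (!all(need %in% names(x)))
    stop("count table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(x$gene_id)) stop("gene_id must be unique", call. = FALSE)
  if (any(x$length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  if (any(x$count_ck < 0) || any(x$count_ct < 0))
    stop("counts must be nonnegative", call. = FALSE)
  if (n_ck < 1 || n_ct < 1) stop("library totals must be >= 1", call. = FALSE)
  if (any(x$count_ck > n_ck) || any(x$count_ct > n_ct))
    stop("a gene count exceeds its library total", call. = FALSE)
  attr(x, "n_ck") <- as.numeric(n_ck)
  attr(x, "n_ct") <- as.numeric(n_ct)
  class(x) <- c("count_table", "data.frame")
  x
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * k / (n * length_bp)` for a gene with `k` mapped reads
#' and length `length_bp` bp in a library of `n` mapped reads.
#'
#' @param k read count(s), `0 <= k <= n`.
#' @param n mapped-read library total, `>= 1`.
#' @param length_bp gene length in bp, `>= 1`.
#' @return RPKM value(s); zero exactly when `k` is zero.
#' @export
#' @examples
#' compute_rpkm(100, 1e7, 1000)  # 10
compute_rpkm <- function(k, n, length_bp) {
  if (any(n < 1)) stop("library total must be >= 1", call. = FALSE)
  if (any(length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  1e9 * as.numeric(k) / (as.numeric(n) * as.numeric(length_bp))
}

#' Presence class of a gene across the two libraries
#'
#' A gene is `both` if detected (count at or above `min_count`) in both
#' libraries, `ck_only`/`ct_only` if detected in just one, and `absent`
#' otherwise. Library-specific transcripts are reported separately from
#' fold-change calls because a log2 ratio is undefined at zero.
#'
#' @param k_ck,k_ct nonnegative counts (vectorized).
#' @param min_count detection threshold (default 1).
#' @return character vector in `both, ck_only, ct_only, absent`.
#' @export
classify_presence <- function(k_ck, k_ct, min_count = 1) {
  if (any(k_ck < 0) || any(k_ct < 0))
    stop("counts must be nonnegative", call. = FALSE)
  in_ck <- k_ck >= min_count
  in_ct <- k_ct >= min_count
  out <- rep("absent", length(k_ck))
  out[in_ck & in_ct] <- "both"
  out[in_ck & !in_ct] <- "ck_only"
  out[!in_ck & in_ct] <- "ct_only"
  out
}

#' MA-plot random-sampling test for two replicate-free libraries
#'
#' Tests, per gene, whether the same underlying expression proportion
#' generated both counts, under the random-sampling model in which each
#' count is Binomial with its library size and a common unknown
#' proportion. On the MA plane (`M = log2 k1 - log2 k2`,
#' `A = (log2 k1 + log2 k2)/2`), the common proportion is estimated from
#' `A` as `p = 2^A / sqrt(n1 * n2)`; by the normal approximation of
#' `log2` of a Binomial, the conditional distribution of `M` given `A`
#' under the null has mean `log2(n1/n2)` and variance
#' `4 s1 s2 / (s1 + s2)` with `s_i = (1 - p) / (n_i p log(2)^2)`. The
#' statistic `z` standardizes `M` against these moments; `p` is the
#' two-sided normal tail.
#'
#' Genes with a zero count cannot enter this path (log2 undefined); route
#' them through [classify_presence()] and [exact_cond_test()].
#'
#' @param k1,k2 positive counts (vectorized).
#' @param n1,n2 library totals.
#' @return data frame with columns `M, A, z, p`.
#' @seealso [exact_cond_test()] for the exact conditional oracle.
#' @export
mars_test <- function(k1, n1, k2, n2) {
  if (any(k1 < 1) || any(k2 < 1))
    stop("mars_test requires counts >= 1 in both libraries; ",
         "use exact_cond_test for zero counts", call. = FALSE)
  M <- log2(k1) - log2(k2)
  A <- (log2(k1) + log2(k2)) / 2
  p_hat <- pmin(2^A / sqrt(as.numeric(n1) * as.numeric(n2)), 1 - 1e-12)
  l2 <- log(2)^2
  s1 <- (1 - p_hat) / (n1 * p_hat * l2)
  s2 <- (1 - p_hat) / (n2 * p_hat * l2)
  v <- 4 * s1 * s2 / (s1 + s2)
  z <- (M - log2(n1 / n2)) / sqrt(v)
  data.frame(M = M, A = A, z = z, p = 2 * pnorm(-abs(z)))
}

#' Exact conditional binomial test for two library counts
#'
#' Conditional on the total `T = k1 + k2`, the first count is
#' `Binomial(T, n1/(n1+n2))` under the null of a common proportion. The
#' two-sided p-value is the minimum-likelihood sum: the total probability
#' of all outcomes no more likely than the observed one. Serves as the
#' exact oracle for [mars_test()]'s normal approximation.
#'
#' @param k1,k2 nonnegative counts (vectorized); `T = 0` returns 1 by
#'   convention.
#' @param n1,n2 library totals.
#' @return two-sided p-value(s) in `[0, 1]`.
#' @export
exact_cond_test <- function(k1, n1, k2, n2) {
  if (any(k1 < 0) || any(k2 < 0))
    stop("counts must be nonnegative", call. = FALSE)
  one <- function(k1, n1, k2, n2) {
    T_ <- k1 + k2
    if (T_ == 0) return(1)
    q <- n1 / (n1 + n2)
    probs <- dbinom(0:T_, T_, q)
    obs <- probs[k1 + 1]
    min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  }
  mapply(one, k1, n1, k2, n2)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j`, clipped
#' at 1 (computed via [stats::p.adjust()]).
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Fill differential-expression status from fold change and q-value
#'
#' A gene is `up` if `log2fc >= fc_threshold` and `q < q_threshold`,
#' `down` if `log2fc <= -fc_threshold` and `q < q_threshold`, and
#' `no_change` otherwise (genes with `|log2fc| < 1` are treated as
#' unchanged regardless of significance).
#'
#' @param records data frame with columns `log2fc` and `q`.
#' @param fc_threshold minimum |log2 fold change| (default 1).
#' @param q_threshold FDR threshold (default 0.001).
#' @return `records` with a `status` column added/replaced.
#' @export
call_degs <- function(records, fc_threshold = 1, q_threshold = 0.001) {
  stopifnot(all(c("log2fc", "q") %in% names(records)))
  status <- rep("no_change", nrow(records))
  sig <- !is.na(records$q) & records$q < q_threshold
  lfc <- records$log2fc
  status[sig & !is.na(lfc) & lfc >= fc_threshold] <- "up"
  status[sig & !is.na(lfc) & lfc <= -fc_threshold] <- "down"
  records$status <- status
  records
}

#' Replicate-free differential-expression calling for a count table
#'
#' Runs the full two-library pipeline: RPKM per library, presence
#' classification, the MA-plot random-sampling test for genes detected in
#' both libraries, the exact conditional test for genes with a zero in
#' one library, Benjamini-Hochberg adjustment over all tested genes, and
#' status calling. The fold change is treated over control:
#' `log2fc = log2((k_ct/n_ct) / (k_ck/n_ck))`, so genes more highly
#' expressed under stress come out positive (infinite for
#' library-specific transcripts).
#'
#' @param counts a [count_table()].
#' @param min_count detection threshold for presence classes.
#' @param fc_threshold,q_threshold see [call_degs()].
#' @return data frame with one row per gene: `gene_id, rpkm_ck, rpkm_ct,
#'   log2fc, M, A, z, p, q, status, presence`.
#' @export
deg_table <- function(counts, min_count = 1, fc_threshold = 1,
                      q_threshold = 0.001) {
  stopifnot(inherits(counts, "count_table"))
  n_ck <- attr(counts, "n_ck")
  n_ct <- attr(counts, "n_ct")
  k_ck <- counts$count_ck
  k_ct <- counts$count_ct
  out <- data.frame(
    gene_id = counts$gene_id,
    rpkm_ck = compute_rpkm(k_ck, n_ck, counts$length_bp),
    rpkm_ct = compute_rpkm(k_ct, n_ct, counts$length_bp),
    log2fc = log2((k_ct / n_ct) / (k_ck / n_ck)),
    M = NA_real_, A = NA_real_, z = NA_real_, p = NA_real_,
    stringsAsFactors = FALSE)
  both <- k_ck >= 1 & k_ct >= 1
  if (any(both)) {
    m <- mars_test(k_ct[both], n_ct, k_ck[both], n_ck)
    out$M[both] <- m$M
    out$A[both] <- m$A
    out$z[both] <- m$z
    out$p[both] <- m$p
  }
  zero <- !both
  if (any(zero))
    out$p[zero] <- exact_cond_test(k_ct[zero], n_ct, k_ck[zero], n_ck)
  out$q <- bh_adjust(out$p)
  out <- call_degs(out, fc_threshold, q_threshold)
  out$presence <- classify_presence(k_ck, k_ct, min_count)
  out$status[out$presence == "absent"] <- "no_change"
  out
}
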