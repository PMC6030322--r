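# shared fixtures and independent oracles, built in code

# small desk-scale count simulation config
small_count_config <- function(seed, n_genes = 2000, de_fraction = 0.1,
                               effect_sd = 0.5) {
  sim_config(seed = seed, n_genes = n_genes, de_fraction = de_fraction,
             effect_mean = 2, effect_sd = effect_sd,
             lib_size_ck = 2e6, lib_size_ct = 2e6)
}

# brute-force BH step-up, written against the textbook definition and
# kept independent of the implementation under test
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * p[o][i:m] / (i:m))), numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# an expression series data frame from bare vectors
make_series <- function(rel, times = seq(0, by = 24,
                                         length.out = length(rel)),
                        se = rep(0, length(rel)), gene = "g") {
  s <- data.frame(gene_id = gene, time_h = times, rel = rel, se = se,
                  n = 3)
  class(s) <- c("expression_series", "data.frame")
  s
}

# stack several series into a panel
make_panel <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("series_panel", "data.frame")
  out
}

# all permutations of 1..n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(combinat_perms(n - 1), function(p)
      c(i, setdiff(seq_len(n), i)[p]))
  }))
}

# schedule from survival fractions at n plants per duration
schedule_from_fractions <- function(fractions,
                                    durations = seq(0, by = 24,
                                      length.out = length(fractions)),
                                    n = 10) {
  survival_schedule(durations, rep(n, length(fractions)),
                    round(fractions * n))
}
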