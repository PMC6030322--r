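#' Simulation configuration for the synthetic-data generator
#'
#' Bundles every parameter the generators use: the two-library count
#' simulation, the qPCR time-course panel, the recovery (survival) assay
#' and the leaf-symptom counts. Defaults describe the study design the
#' pipeline targets: two composite libraries of 2e7 mapped reads, an
#' 8-point qPCR grid over six days of stress, a 7-duration recovery assay
#' with 10 plants per duration, and a 30-gene qPCR panel.
#'
#' @param seed integer seed controlling all randomness of the generators.
#' @param n_genes number of genes in the count simulation.
#' @param lib_size_ck,lib_size_ct expected mapped-read totals of the
#'   control (CK) and treated (CT) libraries.
#' @param de_fraction proportion of genes with a planted expression change.
#' @param effect_mean,effect_sd mean and sd of the magnitude of planted
#'   log2 fold changes (sign drawn uniformly).
#' @param prop_sdlog sdlog of the log-normal baseline expression
#'   proportions (spread of gene abundances).
#' @param time_grid_h qPCR sampling grid in hours; must start at 0 and be
#'   strictly increasing.
#' @param trend_mix named integer vector giving the number of panel genes
#'   per latent trend class; names must be a subset of
#'   `continual_up`, `continual_down`, `saturating_down`, `transient`,
#'   `flat`.
#' @param ct_noise_sd per-well Ct noise, in cycles.
#' @param amplitude_log2 maximum |log2 relative expression| of the latent
#'   qPCR curves.
#' @param n_reps technical qPCR replicates per well.
#' @param base_ct,ref_ct baseline Ct of the target at relative expression 1
#'   and the (constant) reference-gene Ct.
#' @param durations_h recovery-assay waterlogging durations in hours.
#' @param t50_h,slope_h logistic survival parameters: duration of 50%
#'   survival and the logistic scale, both in hours.
#' @param plants_per_duration plants subjected to each duration.
#' @param leaves_per_timepoint leaves scored per time point for symptoms.
#' @param symptom_t50_h,symptom_slope_h logistic parameters of the
#'   symptomatic-leaf probability over time.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_counts()], [simulate_qpcr_panel()],
#'   [simulate_recovery()], [simulate_symptoms()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 200)
#' cts <- simulate_counts(cfg)
#' head(cts$counts)
sim_config <- function(seed = 1L,
                       n_genes = 5000L,
                       lib_size_ck = 2e7,
                       lib_size_ct = 2e7,
                       de_fraction = 0.1,
                       effect_mean = 2,
                       effect_sd = 0.5,
                       prop_sdlog = 1,
                       time_grid_h = c(0, 12, 24, 48, 72, 96, 120, 144),
                       trend_mix = c(continual_up = 6, continual_down = 3,
                                     saturating_down = 5, transient = 10,
                                     flat = 6),
                       ct_noise_sd = 0.15,
                       amplitude_log2 = 3,
                       n_reps = 3L,
                       base_ct = 25,
                       ref_ct = 18,
                       durations_h = seq(0, 144, by = 24),
                       t50_h = 60,
                       slope_h = 10,
                       plants_per_duration = 10L,
                       leaves_per_timepoint = 52L,
                       symptom_t50_h = 75,
                       symptom_slope_h = 30) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              lib_size_ck = lib_size_ck, lib_size_ct = lib_size_ct,
              de_fraction = de_fraction, effect_mean = effect_mean,
              effect_sd = effect_sd, prop_sdlog = prop_sdlog,
              time_grid_h = time_grid_h, trend_mix = trend_mix,
              ct_noise_sd = ct_noise_sd, amplitude_log2 = amplitude_log2,
              n_reps = as.integer(n_reps), base_ct = base_ct,
              ref_ct = ref_ct, durations_h = durations_h,
              t50_h = t50_h, slope_h = slope_h,
              plants_per_duration = as.integer(plants_per_duration),
              leaves_per_timepoint = as.integer(leaves_per_timepoint),
              symptom_t50_h = symptom_t50_h,
              symptom_slope_h = symptom_slope_h)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes <= 0) stop("n_genes must be positive", call. = FALSE)
  if (cfg$lib_size_ck <= 0 || cfg$lib_size_ct <= 0)
    stop("library sizes must be positive", call. = FALSE)
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$ct_noise_sd < 0) stop("ct_noise_sd must be >= 0", call. = FALSE)
  tg <- cfg$time_grid_h
  if (length(tg) < 2 || tg[1] != 0 || any(diff(tg) <= 0))
    stop("time_grid_h must start at 0 and be strictly increasing",
         call. = FALSE)
  known <- c("continual_up", "continual_down", "saturating_down",
             "transient", "flat")
  if (length(cfg$trend_mix) == 0)
    stop("trend_mix must be a non-empty named vector", call. = FALSE)
  if (!all(names(cfg$trend_mix) %in% known))
    stop("unknown trend class in trend_mix; allowed: ",
         paste(known, collapse = ", "), call. = FALSE)
  if (any(cfg$trend_mix < 0)) stop("trend_mix counts must be >= 0",
                                   call. = FALSE)
  if (cfg$n_reps <= 0) stop("n_reps must be positive", call. = FALSE)
  if (cfg$plants_per_duration <= 0)
    stop("plants_per_duration must be positive", call. = FALSE)
  if (cfg$leaves_per_timepoint <= 0)
    stop("leaves_per_timepoint must be positive", call. = FALSE)
  if (cfg$slope_h <= 0) stop("slope_h must be positive", call. = FALSE)
  cfg
}

#' Simulate a two-library gene count table with planted fold changes
#'
#' Draws per-gene baseline expression proportions from a log-normal
#' distribution (normalized to sum one), plants log2 fold changes on a
#' random subset of genes in the treated library, and samples counts
#' independently per library from a Poisson with mean
#' `lib_size * proportion`. A Poisson is the random-sampling model the
#' replicate-free differential-expression test assumes: each library is a
#' single composite sample, so there is no biological dispersion to model.
#'
#' With `mode = "expected"` counts are set to their rounded expectations
#' instead of being sampled, which makes noise-free round-trip checks
#' possible (the recovered log2 fold change equals the planted one up to
#' rounding).
#'
#' @param config a [sim_config()].
#' @param mode `"sample"` (Poisson draws) or `"expected"` (rounded means).
#' @return A list with `counts` (a count table, see [count_table()]) and
#'   `truth`, a data frame with `gene_id`, `is_de` and the planted
#'   `log2fc`.
#' @export
simulate_counts <- function(config, mode = c("sample", "expected")) {
  validate_sim_config(config)
  mode <- match.arg(mode)
  set.seed(config$seed)
  g <- config$n_genes
  p <- rlnorm(g, meanlog = 0, sdlog = config$prop_sdlog)
  p <- p / sum(p)
  n_de <- round(config$de_fraction * g)
  is_de <- rep(FALSE, g)
  if (n_de > 0) is_de[sample.int(g, n_de)] <- TRUE
  effect <- numeric(g)
  if (n_de > 0) {
    mag <- abs(rnorm(n_de, config$effect_mean, config$effect_sd))
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    effect[is_de] <- sgn * mag
  }
  mu_ck <- config$lib_size_ck * p
  mu_ct <- config$lib_size_ct * p * 2^effect
  if (mode == "sample") {
    k_ck <- rpois(g, mu_ck)
    k_ct <- rpois(g, mu_ct)
  } else {
    k_ck <- round(mu_ck)
    k_ct <- round(mu_ct)
  }
  len <- pmax(200L, round(exp(rnorm(g, log(1200), 0.4))))
  ids <- sprintf("gene_%05d", seq_len(g))
  counts <- count_table(
    data.frame(gene_id = ids, length_bp = as.integer(len),
               count_ck = k_ck, count_ct = k_ct,
               stringsAsFactors = FALSE),
    n_ck = sum(k_ck), n_ct = sum(k_ct))
  attr(counts, "seed") <- config$seed
  truth <- data.frame(gene_id = ids, is_de = is_de, log2fc = effect,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}

# latent log2 relative-expression curves, piecewise linear on the grid
latent_curve <- function(class, times, amplitude) {
  T_ <- length(times)
  i <- seq_len(T_) - 1
  switch(class,
    continual_up   = amplitude * i / (T_ - 1),
    continual_down = -amplitude * i / (T_ - 1),
    saturating_down = c(0, rep(-amplitude, T_ - 1)),
    transient = {
      peak <- max(2, floor((T_ - 1) / 2))
      up <- amplitude * pmin(i, peak) / peak
      down <- amplitude * pmax(0, i - peak) / (T_ - 1 - peak)
      up - down
    },
    flat = rep(0, T_),
    stop("unknown trend class: ", class, call. = FALSE))
}

# Ct table from latent log2 curves: Ct_target = base_ct - log2x + noise,
# reference gene constant + noise, CK condition held at log2x = 0
ct_panel_from_curves <- function(curves, config) {
  times <- config$time_grid_h
  reps <- seq_len(config$n_reps)
  grid <- expand.grid(replicate = reps, time_h = times,
                      condition = c("CK", "CT"),
                      gene_id = names(curves),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  l2 <- mapply(function(gid, cond, t) {
    if (cond == "CK") 0 else curves[[gid]][match(t, times)]
  }, grid$gene_id, grid$condition, grid$time_h)
  n <- nrow(grid)
  panel <- data.frame(
    gene_id = grid$gene_id,
    condition = grid$condition,
    time_h = grid$time_h,
    replicate = grid$replicate,
    ct_target = config$base_ct - l2 + rnorm(n, 0, config$ct_noise_sd),
    ct_reference = config$ref_ct + rnorm(n, 0, config$ct_noise_sd),
    stringsAsFactors = FALSE)
  class(panel) <- c("ct_table", "data.frame")
  panel
}

#' Simulate a qPCR Ct panel with planted time-course trend classes
#'
#' Each gene receives a noise-free latent log2 relative-expression curve
#' on the time grid according to its class in `trend_mix`
#' (`continual_up`: linear rise to `amplitude_log2`; `continual_down`:
#' linear fall; `saturating_down`: immediate fall to the floor, then
#' flat; `transient`: rise then fall back; `flat`: constant). Target Ct is
#' `base_ct - log2(x(t))` plus Gaussian well noise; the reference gene is
#' constant plus the same noise; the CK condition is held at `x(t) = 1`.
#'
#' @param config a [sim_config()]; `trend_mix` defines the panel.
#' @return A list with `panel` (a long-format Ct table with columns
#'   `gene_id, condition, time_h, replicate, ct_target, ct_reference`)
#'   and `truth` (`gene_id`, `class`).
#' @export
simulate_qpcr_panel <- function(config) {
  validate_sim_config(config)
  mix <- config$trend_mix[config$trend_mix > 0]
  if (length(mix) == 0) stop("trend_mix is empty", call. = FALSE)
  set.seed(config$seed)
  classes <- rep(names(mix), times = mix)
  ids <- sprintf("g%03d", seq_along(classes))
  curves <- lapply(classes, latent_curve, times = config$time_grid_h,
                   amplitude = config$amplitude_log2)
  names(curves) <- ids
  panel <- ct_panel_from_curves(curves, config)
  list(panel = panel,
       truth = data.frame(gene_id = ids, class = classes,
                          stringsAsFactors = FALSE))
}

# latent log2 curves of the six-gene marker demonstration panel on the
# default 8-point grid; "collapse" plants the post-critical-time breaks
# (two rising genes with a sharp late drop, one slow decliner with a
# sharp drop), "rescued" continues each pre-break trend smoothly
marker_curves <- function(scenario = c("collapse", "rescued")) {
  scenario <- match.arg(scenario)
  if (scenario == "collapse") {
    list(
      pfk_like  = c(0, 0.5, 1.0, 2.0, -1.0, -1.2, -1.4, -1.5),
      cat_like  = c(0, 0.4, 0.8, 1.6, 2.4, -0.6, -0.8, -1.0),
      gltx_like = c(0, -0.2, -0.4, -0.8, -3.8, -4.0, -4.1, -4.2),
      steady_up = c(0, 0.6, 1.2, 1.8, 2.2, 2.5, 2.7, 2.8),
      fast_down = c(0, -2.5, -3.5, -3.6, -3.7, -3.8, -3.9, -4.0),
      flat_bg   = rep(0, 8))
  } else {
    list(
      pfk_like  = c(0, 0.5, 1.0, 2.0, 2.3, 2.5, 2.6, 2.7),
      cat_like  = c(0, 0.4, 0.8, 1.6, 2.4, 2.6, 2.7, 2.8),
      gltx_like = c(0, -0.2, -0.4, -0.8, -1.0, -1.2, -1.3, -1.4),
      steady_up = c(0, 0.6, 1.2, 1.8, 2.2, 2.5, 2.7, 2.8),
      fast_down = c(0, -2.5, -3.5, -3.6, -3.7, -3.8, -3.9, -4.0),
      flat_bg   = rep(0, 8))
  }
}

#' Simulate the marker-gene demonstration panel
#'
#' Generates a six-gene Ct panel containing the three profile shapes the
#' marker selection targets -- two genes rising through the critical time
#' with a sharp drop just after it, and one slow decliner with a sharp
#' late drop -- plus three controls (a steady riser, a fast-saturating
#' decliner, and a flat gene). The `"rescued"` scenario continues each
#' pre-break trend without a collapse, emulating plants drained in time.
#'
#' @param config a [sim_config()]; must use an 8-point time grid.
#' @param scenario `"collapse"` (post-critical-time breaks planted) or
#'   `"rescued"` (no breaks).
#' @return A list with `panel` (Ct table) and `truth`
#'   (`gene_id`, `is_marker`).
#' @export
simulate_marker_panel <- function(config, scenario = c("collapse", "rescued")) {
  validate_sim_config(config)
  scenario <- match.arg(scenario)
  if (length(config$time_grid_h) != 8)
    stop("marker panel curves are defined on an 8-point time grid",
         call. = FALSE)
  set.seed(config$seed)
  curves <- marker_curves(scenario)
  panel <- ct_panel_from_curves(curves, config)
  list(panel = panel,
       truth = data.frame(
         gene_id = names(curves),
         is_marker = names(curves) %in% c("pfk_like", "cat_like",
                                          "gltx_like"),
         stringsAsFactors = FALSE))
}

#' Simulate a recovery-assay survival schedule
#'
#' For each waterlogging duration, the number of plants that survive
#' after being returned to normal growth is drawn as
#' `Binomial(plants_per_duration, p(d))` with
#' `p(d) = 1 / (1 + exp((d - t50_h) / slope_h))`.
#'
#' @param config a [sim_config()].
#' @return A [survival_schedule()] data frame with columns
#'   `duration_h, n_treated, n_survived`.
#' @export
simulate_recovery <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  d <- config$durations_h
  p <- survival_prob(d, config$t50_h, config$slope_h)
  n <- config$plants_per_duration
  survival_schedule(d, rep(n, length(d)), rbinom(length(d), n, p))
}

#' Logistic survival probability over waterlogging duration
#'
#' `p(d) = 1 / (1 + exp((d - t50_h) / slope_h))`: survival is 0.5 at
#' `t50_h` and decreases with duration; as `slope_h` approaches 0 the
#' curve tends to a step from 1 to 0 at `t50_h`.
#'
#' @param d duration(s) in hours.
#' @param t50_h duration of 50% survival.
#' @param slope_h logistic scale in hours (> 0).
#' @return survival probabilities in (0, 1).
#' @export
survival_prob <- function(d, t50_h, slope_h) {
  stopifnot(slope_h > 0)
  plogis((t50_h - d) / slope_h)
}

#' Simulate leaf symptom counts over time
#'
#' Symptomatic leaves are drawn as `Binomial(leaves_per_timepoint, q(t))`
#' with a nondecreasing symptom probability `q(t)`; by default a logistic
#' ramp `plogis((t - symptom_t50_h) / symptom_slope_h)`.
#'
#' @param config a [sim_config()].
#' @param q optional vector of symptom probabilities, one per element of
#'   `config$durations_h`; must be nondecreasing.
#' @return Data frame with `time_h, n_symptomatic, n_total`.
#' @export
simulate_symptoms <- function(config, q = NULL) {
  validate_sim_config(config)
  t <- config$durations_h
  if (is.null(q))
    q <- plogis((t - config$symptom_t50_h) / config$symptom_slope_h)
  if (length(q) != length(t))
    stop("q must have one probability per time point", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]", call. = FALSE)
  if (any(diff(q) < 0)) stop("q must be nondecreasing", call. = FALSE)
  set.seed(config$seed)
  n <- config$leaves_per_timepoint
  data.frame(time_h = t,
             n_symptomatic = rbinom(length(t), n, q),
             n_total = rep(n, length(t)))
}
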