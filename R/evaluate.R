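#' Marker-level true/false positive rates of one run
#'
#' A marker counts as "called" when it lies in a block whose tag has final
#' p-value below `threshold`.  TPR is the fraction of truth markers called,
#' FPR the fraction of non-truth markers called.
#'
#' @param result a [peel_off()] result (or any list with `p_values`).
#' @param partition the `block_partition` of the same run.
#' @param truth a `sim_cohort` truth list, or a logical per-marker truth
#'   vector.
#' @param threshold significance level.
#' @return Named numeric vector `c(tpr, fpr)`; `tpr` is `NA` when the truth
#'   track has no positive marker.
#' @export
marker_rates <- function(result, partition, truth, threshold) {
  labels <- if (is.list(truth) && !is.null(truth$marker_labels))
    truth$marker_labels else as.logical(truth)
  L <- length(labels)
  if (max(partition$end) > L) stop("partition extends beyond the truth track")
  called <- rep(FALSE, L)
  for (b in which(result$p_values < threshold))
    called[partition$start[b]:partition$end[b]] <- TRUE
  npos <- sum(labels)
  c(tpr = if (npos) sum(called & labels) / npos else NA_real_,
    fpr = sum(called & !labels) / sum(!labels))
}

# Per-marker called mask of a whole fit (both polarities, all chromosomes).
fit_called_markers <- function(fit, threshold, polarity = NULL) {
  L <- nrow(fit$markers)
  called <- rep(FALSE, L)
  for (run in fit$runs) {
    if (!is.null(polarity) && run$polarity != polarity) next
    off <- run$col_offset
    for (b in which(run$peel$p_values < threshold)) {
      called[(off + run$partition$start[b]):(off + run$partition$end[b])] <- TRUE
    }
  }
  called
}

#' Marker-level rates of a whole pipeline fit
#'
#' Combines amplification and deletion calls (a marker is called if either
#' polarity calls it) across all chromosomes of a [tagcna_fit()].
#'
#' @param fit a `tagcna_fit`.
#' @param truth truth list or logical vector (see [marker_rates()]).
#' @param threshold significance level.
#' @return Named numeric vector `c(tpr, fpr)`.
#' @export
fit_marker_rates <- function(fit, truth, threshold) {
  labels <- if (is.list(truth) && !is.null(truth$marker_labels))
    truth$marker_labels else as.logical(truth)
  called <- fit_called_markers(fit, threshold)
  npos <- sum(labels)
  c(tpr = if (npos) sum(called & labels) / npos else NA_real_,
    fpr = sum(called & !labels) / sum(!labels))
}

#' TPR/FPR pairs over a grid of significance levels
#'
#' @param fit a [tagcna_fit()].
#' @param truth truth list or logical vector.
#' @param thresholds significance levels to sweep.
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(fit, truth,
                       thresholds = c(0, 0.001, 0.005, 0.01, 0.02, 0.05,
                                      0.1, 0.2, 0.5, 1, 1.01)) {
  rates <- t(vapply(thresholds, function(th) fit_marker_rates(fit, truth, th),
                    numeric(2)))
  data.frame(threshold = thresholds, tpr = rates[, 1], fpr = rates[, 2])
}

#' Empirical type-I error on background-only cohorts
#'
#' Simulates `n_reps` null cohorts, runs the full pipeline (per-subject
#' segmentation, thresholding, tag selection, peel-off) on each, and reports
#' the fraction of replications in which at least one tag of either polarity
#' reaches final p-value below `alpha` - the family-wise false positive rate
#' of the whole procedure.
#'
#' @param n_reps number of null replications.
#' @param null_config a [sim_config()] with empty `sce_specs`.
#' @param run_params named list overriding pipeline settings: `theta_amp`
#'   (default 0.1), `theta_del` (-0.1), `w` (20), `E` (1000), plus
#'   segmentation settings `seg_alpha`, `seg_min_width`, `seg_n_perm`.
#' @param alpha family-wise significance cutoff.
#' @param seed base seed; replication r uses `seed + r`.
#' @return A list with `rate` (the proportion), `hits` (per-replication
#'   logical) and `n_reps`.
#' @export
type_I_error <- function(n_reps, null_config, run_params = list(),
                         alpha = 0.05, seed = 1) {
  rp <- run_defaults(run_params, theta_amp = 0.1, theta_del = -0.1)
  # independent per-replication seeds (separate generation and analysis
  # streams), so different base seeds give disjoint replication sets
  seeds <- maybe_with_seed(seed,
    matrix(sample.int(2147483646L, 2L * n_reps), nrow = 2L))
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- null_config
    cfg$seed <- seeds[1L, r]
    sim <- simulate_null_cohort(cfg)
    fit <- fit_simulated(sim, rp, alpha, seeds[2L, r])
    hits[r] <- any_significant(fit, alpha)
  }
  list(rate = mean(hits), hits = hits, n_reps = n_reps)
}

#' Detection power across normal-cell contamination levels
#'
#' For each contamination SD, simulates replicate cohorts carrying one
#' amplified and one deleted consensus event (frequency 0.15), runs the full
#' pipeline and counts a success when both events are recovered - a
#' significant block of matching polarity overlapping each truth interval by
#' at least one marker.
#'
#' @param sd_values contamination SDs to sweep.
#' @param base a [sim_config()] supplying cohort size, noise and passenger
#'   settings; the default is the passenger-free contamination preset (see
#'   [sim_preset()]).
#' @param run_params pipeline overrides as in [type_I_error()].
#' @param alpha significance cutoff.
#' @param n_reps replications per SD.
#' @param seed base seed.
#' @return Data frame with columns `sd` and `power`.
#' @export
contamination_power <- function(sd_values,
                                base = sim_preset("contamination", "desk"),
                                run_params = list(), alpha = 0.05,
                                n_reps = 20, seed = 1) {
  rp <- run_defaults(run_params, theta_amp = 0.1, theta_del = -0.1)
  # one generation seed per replication (shared across the sweep, so the
  # cohorts differ only through contamination) plus an analysis seed per
  # replication x SD, all drawn from one seeded stream
  seeds <- maybe_with_seed(seed,
    matrix(sample.int(2147483646L, n_reps * (1L + length(sd_values))),
           nrow = n_reps))
  det <- matrix(FALSE, n_reps, length(sd_values))
  for (r in seq_len(n_reps)) {
    b <- base
    b$seed <- seeds[r, 1L]
    cohorts <- simulate_contamination_sweep(sd_values, b)
    for (s in seq_along(sd_values)) {
      fit <- fit_simulated(cohorts[[s]], rp, alpha, seeds[r, 1L + s])
      det[r, s] <- all_truth_detected(fit, cohorts[[s]]$truth, alpha)
    }
  }
  data.frame(sd = sd_values, power = colMeans(det))
}

# Shared pipeline defaults for simulation experiments.  Subject-level CBS
# uses fewer permutations than the correlation-profile partition: at
# alpha = 0.01 a split is accepted only with zero exceedances either way,
# so 100 draws resolve the decision while curtailment stops rejections at
# the first exceedance.
run_defaults <- function(run_params, theta_amp = 0.1, theta_del = -0.1) {
  defaults <- list(theta_amp = theta_amp, theta_del = theta_del, w = 20,
                   E = 1000, seg_alpha = 0.01, seg_min_width = 2,
                   seg_n_perm = 200, subject_n_perm = 100)
  defaults[names(run_params)] <- run_params
  defaults
}

# Segment a raw simulated cohort and run the significance pipeline on it.
fit_simulated <- function(sim, rp, alpha, seed) {
  maybe_with_seed(seed, {
    seg <- segment_cohort(sim$data, alpha = rp$seg_alpha,
                          min_width = rp$seg_min_width,
                          n_perm = rp$subject_n_perm, seed = NULL)
    tagcna_fit(seg, theta_amp = rp$theta_amp, theta_del = rp$theta_del,
               w = rp$w, E = rp$E, alpha = alpha, seed = NULL,
               seg_alpha = rp$seg_alpha, seg_min_width = rp$seg_min_width,
               seg_n_perm = rp$seg_n_perm)
  })
}

any_significant <- function(fit, alpha) {
  any(vapply(fit$runs, function(r) any(r$peel$p_values < alpha), logical(1)))
}

# TRUE when every truth consensus interval is overlapped (>= 1 marker) by a
# significant block of the same polarity.
all_truth_detected <- function(fit, truth, alpha) {
  iv <- truth$sce_intervals
  if (!nrow(iv)) return(TRUE)
  for (s in seq_len(nrow(iv))) {
    called <- fit_called_markers(fit, alpha, polarity = iv$polarity[s])
    if (!any(called[iv$start[s]:iv$end[s]])) return(FALSE)
  }
  TRUE
}
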