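#' Specification of one embedded consensus event
#'
#' @param ratio pure-tumour log2-ratio of the event (positive = gain,
#'   negative = loss); converted to tumour copy number as `c_t = 2 * 2^ratio`
#'   before tumour/normal mixing (0.585 = 3 copies, 1.322 = 5 copies).
#' @param length event length in markers.
#' @param frequency fraction of subjects carrying the event, in (0, 1].
#' @param polarity `"amp"` or `"del"`; defaults to the sign of `ratio`.
#' @return A list describing the event.
#' @export
sce_spec <- function(ratio, length, frequency,
                     polarity = if (ratio >= 0) "amp" else "del") {
  stopifnot(length >= 1, frequency > 0, frequency <= 1)
  list(ratio = ratio, length = as.integer(length), frequency = frequency,
       polarity = match.arg(polarity, c("amp", "del")))
}

#' Configuration of the tumour/normal mixture cohort simulator
#'
#' Defaults reproduce the power-study conditions: 100 subjects, 10000
#' markers, three embedded amplification events of pure-tumour ratio
#' \{0.585, 1, 1.322\} and length \{200, 100, 50\} markers at carrier
#' frequency 0.15, per-subject Gaussian marker noise with SD drawn uniformly
#' from [0.1, 0.2], normal-cell fraction uniform on [0.3, 0.7], and two
#' passenger (non-consensus) regions per subject of length 50-500 markers and
#' ratio uniform on [0.585, 1.322].
#'
#' @param n_subjects cohort size N.
#' @param n_markers markers per simulated genome L.
#' @param sce_specs list of [sce_spec()] entries (may be empty for a null
#'   cohort).
#' @param noise_sd_range interval from which each subject's Gaussian noise SD
#'   is drawn uniformly.
#' @param normal_fraction one of [normal_fraction_uniform()],
#'   [normal_fraction_gaussian()], [normal_fraction_none()].
#' @param n_passengers passenger regions per subject.
#' @param passenger_length_range integer interval of passenger lengths
#'   (markers).
#' @param passenger_ratio_range interval of passenger pure-tumour ratios.
#' @param guard_gap minimum marker gap kept between consensus events.
#' @param seed integer seed; the whole cohort is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 100, n_markers = 10000,
                       sce_specs = list(sce_spec(0.585, 200, 0.15),
                                        sce_spec(1, 100, 0.15),
                                        sce_spec(1.322, 50, 0.15)),
                       noise_sd_range = c(0.1, 0.2),
                       normal_fraction = normal_fraction_uniform(0.3, 0.7),
                       n_passengers = 2,
                       passenger_length_range = c(50, 500),
                       passenger_ratio_range = c(0.585, 1.322),
                       guard_gap = 100,
                       seed = NULL) {
  stopifnot(n_subjects >= 1, n_markers >= 2,
            length(noise_sd_range) == 2, all(noise_sd_range >= 0),
            diff(noise_sd_range) >= 0,
            n_passengers >= 0, guard_gap >= 0)
  if (length(sce_specs)) {
    lens <- vapply(sce_specs, `[[`, integer(1), "length")
    if (sum(lens) > n_markers)
      stop("total consensus-event length exceeds the number of markers")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_markers = as.integer(n_markers),
                 sce_specs = sce_specs,
                 noise_sd_range = as.numeric(noise_sd_range),
                 normal_fraction = normal_fraction,
                 n_passengers = as.integer(n_passengers),
                 passenger_length_range = as.integer(passenger_length_range),
                 passenger_ratio_range = as.numeric(passenger_ratio_range),
                 guard_gap = as.integer(guard_gap),
                 seed = seed),
            class = "sim_config")
}

#' Normal-cell fraction models
#'
#' @param lo,hi bounds of the uniform model.
#' @return A model descriptor consumed by [simulate_cohort()].
#' @export
normal_fraction_uniform <- function(lo = 0.3, hi = 0.7) {
  stopifnot(lo >= 0, hi < 1, lo <= hi)
  list(kind = "uniform", lo = lo, hi = hi)
}

#' @rdname normal_fraction_uniform
#' @param mean,sd parameters of the Gaussian model.
#' @param lower,upper truncation bounds (a fraction must stay in `[0, 1)`);
#'   draws outside are redrawn.
#' @export
normal_fraction_gaussian <- function(mean = 0.6, sd = 0.1,
                                     lower = 0, upper = 0.99) {
  stopifnot(sd >= 0, lower >= 0, upper < 1, lower <= upper)
  list(kind = "gaussian", mean = mean, sd = sd, lower = lower, upper = upper)
}

#' @rdname normal_fraction_uniform
#' @export
normal_fraction_none <- function() list(kind = "none")

draw_normal_fraction <- function(model) {
  switch(model$kind,
         none = 0,
         uniform = runif(1, model$lo, model$hi),
         gaussian = {
           repeat {
             p <- rnorm(1, model$mean, model$sd)
             if (p >= model$lower && p <= model$upper) break
           }
           p
         },
         stop("unknown normal-fraction model: ", model$kind))
}

# Observed log2-ratio of a tumour/normal mixture: tumour copy number ct
# diluted by normal fraction p of diploid cells, relative to diploid.
mixed_log2_ratio <- function(ct, p) {
  log2(((1 - p) * ct + 2 * p) / 2)
}

# Place k non-overlapping intervals of the given lengths uniformly on
# 1..L with at least `gap` markers between any two.
place_intervals <- function(lengths, L, gap, max_tries = 10000L) {
  k <- length(lengths)
  if (k == 0) return(data.frame(start = integer(), end = integer()))
  if (sum(lengths) + gap * (k - 1) > L)
    stop("consensus events (plus guard gaps) cannot fit in the simulated genome")
  starts <- integer(k)
  for (s in seq_len(k)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- sample.int(L - lengths[s] + 1L, 1)
      ok <- TRUE
      if (s > 1) {
        for (q in seq_len(s - 1)) {
          if (cand <= starts[q] + lengths[q] - 1L + gap &&
              starts[q] <= cand + lengths[s] - 1L + gap) { ok <- FALSE; break }
        }
      }
      if (ok) { starts[s] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place consensus events without overlap; reduce lengths or guard gap")
  }
  data.frame(start = starts, end = starts + lengths - 1L)
}

#' Simulate a tumour/normal mixture cohort with embedded consensus events
#'
#' For every subject: draw a normal-cell fraction p and a noise SD; set the
#' tumour copy number to 2 everywhere except at consensus events (for
#' carriers) and at that subject's passenger regions, where it is
#' `2 * 2^ratio`; observe `log2(((1 - p) * c_t + 2p) / 2)` plus i.i.d.
#' Gaussian marker noise.  Consensus positions are fixed across subjects at
#' seeded-random non-overlapping offsets; passengers are drawn independently
#' per subject, rejection-sampled away from the consensus intervals so the
#' truth labelling stays unambiguous.
#'
#' @param config a [sim_config()].
#' @return A `sim_cohort` list: `data` (raw [ratio_matrix()], one chromosome
#'   named `chr1` with unit marker spacing) and `truth` (list with
#'   `sce_intervals` data frame, `carrier_sets`, per-subject
#'   `passenger_intervals`, logical `marker_labels`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_subjects
  L <- config$n_markers
  specs <- config$sce_specs
  maybe_with_seed(config$seed, {
    iv <- place_intervals(vapply(specs, `[[`, integer(1), "length")
                          %||% integer(), L, config$guard_gap)
    carriers <- lapply(specs, function(s)
      sort(sample.int(N, round(s$frequency * N))))
    labels <- rep(FALSE, L)
    for (s in seq_along(specs)) labels[iv$start[s]:iv$end[s]] <- TRUE
    values <- matrix(0, N, L)
    passengers <- vector("list", N)
    plen <- config$passenger_length_range
    prat <- config$passenger_ratio_range
    for (n in seq_len(N)) {
      p <- draw_normal_fraction(config$normal_fraction)
      sigma <- runif(1, config$noise_sd_range[1], config$noise_sd_range[2])
      ct <- rep(2, L)
      for (s in seq_along(specs)) {
        if (n %in% carriers[[s]])
          ct[iv$start[s]:iv$end[s]] <- 2 * 2^specs[[s]]$ratio
      }
      pv <- data.frame(start = integer(), end = integer(), ratio = numeric())
      for (k in seq_len(config$n_passengers)) {
        # uniform over start positions that keep the region clear of every
        # consensus interval; redraw the length if none exists at this one
        cand <- NA_integer_
        for (t in seq_len(100L)) {
          len <- if (plen[1] == plen[2]) plen[1] else
            sample(seq.int(plen[1], plen[2]), 1)
          if (len > L) next
          ok <- rep(TRUE, L - len + 1L)
          for (s in seq_along(specs)) {
            lo <- max(1L, iv$start[s] - len + 1L)
            hi <- min(L - len + 1L, iv$end[s])
            if (lo <= hi) ok[lo:hi] <- FALSE
          }
          valid <- which(ok)
          if (length(valid)) {
            cand <- valid[sample.int(length(valid), 1)]
            break
          }
        }
        if (is.na(cand))
          stop("could not place a passenger region off the consensus events")
        ratio_p <- runif(1, prat[1], prat[2])
        ct[cand:(cand + len - 1L)] <- 2 * 2^ratio_p
        pv <- rbind(pv, data.frame(start = cand, end = cand + len - 1L,
                                   ratio = ratio_p))
      }
      passengers[[n]] <- pv
      values[n, ] <- mixed_log2_ratio(ct, p) + rnorm(L, 0, sigma)
    }
    NULL
  })
  markers <- marker_map(sprintf("m%06d", seq_len(L)), "chr1", seq_len(L))
  truth <- list(
    sce_intervals = if (length(specs)) cbind(iv, data.frame(
      polarity = vapply(specs, `[[`, character(1), "polarity"),
      ratio = vapply(specs, `[[`, numeric(1), "ratio"),
      frequency = vapply(specs, `[[`, numeric(1), "frequency")))
      else data.frame(start = integer(), end = integer(),
                      polarity = character(), ratio = numeric(),
                      frequency = numeric()),
    carrier_sets = carriers,
    passenger_intervals = passengers,
    marker_labels = labels)
  structure(list(data = ratio_matrix(values, markers), truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' Simulate a background-only (null) cohort
#'
#' No consensus events: every subject only receives its own independently
#' placed passenger regions, mixed and noised as in [simulate_cohort()], so
#' no locus is enriched across subjects and the truth track is all-false.
#'
#' @param config a [sim_config()] with an empty `sce_specs` list.
#' @return A `sim_cohort` (see [simulate_cohort()]).
#' @export
simulate_null_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$sce_specs))
    stop("a null cohort must have no consensus events (empty sce_specs)")
  simulate_cohort(config)
}

#' Cohorts for a normal-cell contamination sweep
#'
#' One cohort per contamination SD, identical apart from the normal-cell
#' fraction model, which is Gaussian with mean 0.6 and the given SD
#' (truncated to a valid fraction).  Each cohort carries one amplified
#' (pure-tumour ratio +1, 4 copies) and one deleted (ratio -1, 1 copy)
#' consensus event of 100 markers at carrier frequency 0.15.
#'
#' @param sd_values positive contamination standard deviations.
#' @param base a [sim_config()] supplying cohort size, noise and passenger
#'   settings (its `sce_specs` and `normal_fraction` are overridden).
#' @return List of `sim_cohort` objects, one per SD.
#' @export
simulate_contamination_sweep <- function(sd_values, base = sim_config()) {
  stopifnot(all(sd_values > 0))
  lapply(sd_values, function(s) {
    cfg <- base
    cfg$normal_fraction <- normal_fraction_gaussian(0.6, s)
    cfg$sce_specs <- list(sce_spec(1, 100, 0.15, "amp"),
                          sce_spec(-1, 100, 0.15, "del"))
    simulate_cohort(cfg)
  })
}

#' Ready-made simulation presets
#'
#' `"power"` is the three-event power-study cohort, `"null"` the
#' background-only cohort, `"contamination"` the base for a
#' [simulate_contamination_sweep()].  `scale = "paper"` uses the full study
#' conditions (100 subjects, 10000 markers, passenger lengths U[50, 500]);
#' `scale = "desk"` is a reduced rendition for quick runs (50 subjects,
#' 2000 markers) in which passenger lengths scale with the genome
#' (U[10, 100]) so per-subject background coverage keeps its full-scale
#' proportion, while consensus event lengths stay at \{200, 100, 50\}
#' markers.
#'
#' The contamination base differs in two ways.  It carries no passenger
#' regions - its background is marker noise alone (SD on the middle level,
#' U[0.2, 0.4]), so the detection-power sweep isolates the contamination
#' mechanism rather than competition with equally compressed passenger
#' events.  And its desk scale keeps the full cohort size (100 subjects,
#' 2000 markers): detection power depends on the absolute carrier count, so
#' halving subjects would change the quantity being swept, not just its
#' cost.
#'
#' @param preset `"power"`, `"null"` or `"contamination"`.
#' @param scale `"paper"` or `"desk"`.
#' @param f consensus-event carrier frequency (power preset).
#' @param noise_sd_range per-subject noise SD interval.
#' @param seed integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(preset = c("power", "null", "contamination"),
                       scale = c("paper", "desk"), f = 0.15,
                       noise_sd_range = c(0.1, 0.2), seed = NULL) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  N <- if (scale == "paper" || preset == "contamination") 100 else 50
  L <- if (scale == "paper") 10000 else 2000
  plen <- if (scale == "paper") c(50, 500) else c(10, 100)
  specs <- switch(preset,
                  power = list(sce_spec(0.585, 200, f),
                               sce_spec(1, 100, f),
                               sce_spec(1.322, 50, f)),
                  null = list(),
                  contamination = list())  # events set by the sweep
  if (preset == "contamination" && missing(noise_sd_range))
    noise_sd_range <- c(0.2, 0.4)
  sim_config(n_subjects = N, n_markers = L, sce_specs = specs,
             noise_sd_range = noise_sd_range,
             n_passengers = if (preset == "contamination") 0 else 2,
             passenger_length_range = plen, seed = seed)
}

#' Write a simulated cohort to disk
#'
#' Writes the matrix TSV, the marker map TSV and a BED truth track of the
#' embedded consensus intervals.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ratio_matrix(cohort$data, file.path(dir, "matrix.tsv"),
                     file.path(dir, "markers.tsv"))
  iv <- cohort$truth$sce_intervals
  con <- file(file.path(dir, "truth.bed"), "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tpolarity\tratio\tfrequency", con)
  mk <- cohort$data$markers
  for (r in seq_len(nrow(iv))) {
    writeLines(paste(c("chr1",
                       sprintf("%d", as.integer(mk$pos[iv$start[r]]) - 1L),
                       sprintf("%d", as.integer(mk$pos[iv$end[r]])),
                       iv$polarity[r],
                       sprintf("%g", iv$ratio[r]),
                       sprintf("%g", iv$frequency[r])), collapse = "\t"), con)
  }
  invisible(dir)
}
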