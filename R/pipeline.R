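#' Run the full significance analysis on a segmented cohort matrix
#'
#' Per chromosome and per polarity: threshold the matrix into aberration
#' calls, compute the windowed correlation profile, partition it into
#' correlation blocks, take the tag-marker matrix and assess it with the
#' peel-off max-T permutation test, mapping significant tags back to
#' consensus event regions.  With `scope = "genome"` the correlation blocks
#' are still built per chromosome (windows never cross a boundary) but all
#' tags are pooled into a single genome-wide permutation family per
#' polarity.
#'
#' @param X a [ratio_matrix()] of segmented log2-ratios.
#' @param theta_amp,theta_del aberration thresholds (log2-ratio units);
#'   defaults 0.848 / -0.737 (3.6 and 1.2 copies), the usual focal-event
#'   settings for real tumour cohorts.
#' @param w correlation window in markers.
#' @param E permutations per peel-off iteration.
#' @param alpha significance cutoff.
#' @param seed integer seed covering the whole run; `NULL` uses the ambient
#'   stream.
#' @param scope `"chromosome"` (default) for per-chromosome permutation
#'   families, `"genome"` for one family per polarity.
#' @param seg_alpha,seg_min_width,seg_n_perm settings of the block-partition
#'   changepoint engine.
#' @param add_one use the add-one p-value estimator.
#' @return A `tagcna_fit`: list with `runs` (one entry per chromosome x
#'   polarity holding `profile`, `partition`, `tags`, `peel`, `sces`,
#'   `col_offset`), the combined `sces` table, `markers` and `params`.
#' @export
tagcna_fit <- function(X, theta_amp = 0.848, theta_del = -0.737, w = 20,
                       E = 1000, alpha = 0.05, seed = NULL,
                       scope = c("chromosome", "genome"),
                       seg_alpha = 0.01, seg_min_width = 2, seg_n_perm = 200,
                       add_one = FALSE) {
  stopifnot(inherits(X, "ratio_matrix"))
  scope <- match.arg(scope)
  calls <- split_by_threshold(X, theta_amp, theta_del)
  chroms <- unique(X$markers$chrom)
  runs <- list()
  maybe_with_seed(seed, {
    for (pol in c("amp", "del")) {
      cm <- calls[[pol]]
      pol_runs <- list()
      for (ch in chroms) {
        idx <- which(X$markers$chrom == ch)
        sub_vals <- cm$values[, idx, drop = FALSE]
        profile <- correlation_profile(sub_vals, w)
        part <- partition_blocks(profile, alpha = seg_alpha,
                                 min_width = seg_min_width,
                                 n_perm = seg_n_perm, seed = NULL,
                                 chrom = ch)
        tags <- tag_matrix(sub_vals[, part$tag_index, drop = FALSE],
                           part, pol)
        pol_runs[[ch]] <- list(chrom = ch, polarity = pol,
                               profile = profile, partition = part,
                               tags = tags, col_offset = idx[1] - 1L)
      }
      if (scope == "chromosome") {
        for (ch in chroms) {
          run <- pol_runs[[ch]]
          run$peel <- peel_off(run$tags, E = E, alpha = alpha, seed = NULL,
                               add_one = add_one)
          run$sces <- call_sces(run$peel, run$tags,
                                X$markers[X$markers$chrom == ch, ,
                                          drop = FALSE],
                                alpha)
          runs[[length(runs) + 1L]] <- run
        }
      } else {
        pooled <- do.call(cbind, lapply(pol_runs, function(r) r$tags$values))
        peel_all <- peel_off(tag_matrix(pooled, NULL, pol), E = E,
                             alpha = alpha, seed = NULL, add_one = add_one)
        off <- 0L
        for (ch in chroms) {
          run <- pol_runs[[ch]]
          M <- ncol(run$tags$values)
          sl <- seq.int(off + 1L, off + M)
          run$peel <- list(p_values = peel_all$p_values[sl],
                           scores = peel_all$scores[sl],
                           removed_at = peel_all$removed_at[sl],
                           distributions = peel_all$distributions,
                           dist_means = peel_all$dist_means,
                           H = peel_all$H, alpha = alpha, E = as.integer(E),
                           add_one = add_one)
          run$sces <- call_sces(run$peel, run$tags,
                                X$markers[X$markers$chrom == ch, ,
                                          drop = FALSE],
                                alpha)
          runs[[length(runs) + 1L]] <- run
          off <- off + M
        }
      }
    }
    NULL
  })
  sces <- do.call(rbind, lapply(runs, `[[`, "sces"))
  structure(list(runs = runs, sces = sce_regions(sces), markers = X$markers,
                 params = list(theta_amp = theta_amp, theta_del = theta_del,
                               w = w, E = E, alpha = alpha, seed = seed,
                               scope = scope, seg_alpha = seg_alpha,
                               seg_min_width = seg_min_width,
                               seg_n_perm = seg_n_perm, add_one = add_one)),
            class = "tagcna_fit")
}

#' @export
print.tagcna_fit <- function(x, ...) {
  cat(sprintf("tagcna_fit: %d chromosome x polarity run(s), %d significant region(s) at alpha = %g\n",
              length(x$runs), nrow(x$sces), x$params$alpha))
  for (r in x$runs) {
    cat(sprintf("  %s %s: %d blocks, H = %d, null mean %s\n",
                r$chrom, r$polarity, nrow(r$partition), r$peel$H,
                paste(sprintf("%.3g", r$peel$dist_means), collapse = " -> ")))
  }
  invisible(x)
}

#' Run the pipeline from files to files
#'
#' Reads a cohort matrix and marker map, runs [tagcna_fit()] and writes
#' per-polarity BED-detail region files (`sce_amp.bed`, `sce_del.bed`), a
#' per-tag statistics table (`tag_stats.tsv`) and a JSON run manifest
#' recording every parameter, the seed and the peel-off iteration trace.
#' Outputs are deterministic: identical inputs, parameters and seed yield
#' byte-identical files.
#'
#' @param matrix_path,marker_path input TSV paths (see
#'   [read_ratio_matrix()]).
#' @param out_dir output directory (created if needed).
#' @param ... passed to [tagcna_fit()].
#' @param seed integer seed for the run.
#' @return Invisibly, the `tagcna_fit`.
#' @export
run_pipeline <- function(matrix_path, marker_path, out_dir, ..., seed = 7) {
  X <- read_ratio_matrix(matrix_path, marker_path)
  fit <- tagcna_fit(X, ..., seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sce_regions(fit$sces[fit$sces$polarity == "amp", , drop = FALSE],
                    file.path(out_dir, "sce_amp.bed"))
  write_sce_regions(fit$sces[fit$sces$polarity == "del", , drop = FALSE],
                    file.path(out_dir, "sce_del.bed"))
  stats <- do.call(rbind, lapply(fit$runs, function(r) {
    mk <- fit$markers[fit$markers$chrom == r$chrom, , drop = FALSE]
    data.frame(chrom = r$chrom, polarity = r$polarity,
               block_start_pos = mk$pos[r$partition$start],
               block_end_pos = mk$pos[r$partition$end],
               tag_marker_id = mk$marker_id[r$partition$tag_index],
               score = r$peel$scores,
               p_value = r$peel$p_values,
               removed_at = r$peel$removed_at,
               stringsAsFactors = FALSE)
  }))
  write.table(stats, file.path(out_dir, "tag_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "tagcna",
    version = as.character(utils::packageVersion("tagcna")),
    params = fit$params,
    inputs = list(matrix = basename(matrix_path),
                  markers = basename(marker_path)),
    trace = lapply(fit$runs, function(r)
      list(chrom = r$chrom, polarity = r$polarity,
           n_blocks = nrow(r$partition), H = r$peel$H,
           peeled_per_iteration = as.integer(tabulate(
             r$peel$removed_at[r$peel$removed_at > 0], nbins = r$peel$H)),
           null_means = r$peel$dist_means)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
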