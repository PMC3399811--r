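#' Split a ratio matrix into amplification and deletion call matrices
#'
#' Cells with log2-ratio `>= theta_amp` are kept in the amplification matrix,
#' cells `<= theta_del` in the deletion matrix (inclusive bounds); everything
#' else becomes exactly zero ("no aberration").  Amplifications and deletions
#' are analysed separately throughout.
#'
#' @param X a [ratio_matrix()] of segmented log2-ratios.
#' @param theta_amp amplification threshold, `> 0` (log2-ratio units).
#' @param theta_del deletion threshold, `< 0`.
#' @return A list with call matrices `amp` and `del`.
#' @examples
#' rm <- ratio_matrix(rbind(c(0.9, -0.8, 0.05), c(0, 0, 0)),
#'                    marker_map(c("a", "b", "c"), "chr1", 1:3))
#' calls <- split_by_threshold(rm, 0.848, -0.737)
#' calls$amp$values
#' @export
split_by_threshold <- function(X, theta_amp = 0.848, theta_del = -0.737) {
  stopifnot(inherits(X, "ratio_matrix"))
  if (!(theta_amp > 0)) stop("theta_amp must be positive")
  if (!(theta_del < 0)) stop("theta_del must be negative")
  v <- X$values
  amp <- v * (v >= theta_amp)
  del <- v * (v <= theta_del)
  list(amp = new_call_matrix(amp, X$markers, "amp", theta_amp),
       del = new_call_matrix(del, X$markers, "del", theta_del))
}

#' Score tag markers by summed aberration magnitude
#'
#' The per-tag statistic folds frequency and amplitude into one number:
#' `S_m = sum_n |t_nm|`, the sum over subjects of the absolute log2-ratio at
#' tag m.  Non-aberrant (zero) cells contribute nothing, so a tag's score
#' grows both with how many subjects are aberrant and with how strongly.
#'
#' @param T a [tag_matrix()] (or numeric matrix).
#' @return Numeric vector of non-negative scores, one per tag; a score is 0
#'   exactly when the tag column is all zero.
#' @export
score_tags <- function(T) {
  colSums(abs(matrix_values(T)))
}

#' Permute tag markers within each subject
#'
#' Each subject's row is independently and uniformly permuted across the tag
#' positions, preserving the row's multiset of values - the elementary move
#' of the max-T permutation null.
#'
#' @param T a [tag_matrix()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return A [tag_matrix()] with permuted rows.
#' @export
permute_tags <- function(T, seed = NULL) {
  stopifnot(inherits(T, "tag_matrix"))
  M <- ncol(T$values)
  if (M < 2) return(T)
  out <- T
  maybe_with_seed(seed, {
    for (n in seq_len(nrow(out$values))) {  # subject-major RNG order
      out$values[n, ] <- out$values[n, sample.int(M)]
    }
    NULL
  })
  out
}

# Core null sampler on a matrix of magnitudes (no class overhead).
max_score_null <- function(A, E) {
  N <- nrow(A)
  M <- ncol(A)
  maxima <- numeric(E)
  if (M < 2) {
    maxima[] <- if (M == 1) sum(A) else 0
    return(maxima)
  }
  perm <- A
  for (e in seq_len(E)) {
    for (n in seq_len(N)) perm[n, ] <- A[n, sample.int(M)]
    maxima[e] <- max(.colSums(perm, N, M))
  }
  maxima
}

#' Max-T permutation null distribution of the tag scores
#'
#' Draws `E` independent within-subject permutations of the tag matrix and
#' records, for each, the maximum tag score - the max-T statistic whose
#' right tail yields family-wise error control.
#'
#' @param T a [tag_matrix()].
#' @param E number of permutations.
#' @param seed optional integer seed.
#' @return A `null_distribution` object: list with `maxima` (length `E`,
#'   all `>= 0`) and `E`.
#' @export
null_distribution <- function(T, E, seed = NULL) {
  stopifnot(inherits(T, "tag_matrix"), E >= 1)
  maxima <- maybe_with_seed(seed, max_score_null(abs(T$values), as.integer(E)))
  structure(list(maxima = maxima, E = as.integer(E)),
            class = "null_distribution")
}

#' Right-tail permutation p-values against a null distribution
#'
#' `p(m) = (1/E) * sum_e I(maxima[e] >= S_m)` - the fraction of permutation
#' maxima at least as large as the observed score.  The literal estimator can
#' return 0; `add_one = TRUE` switches to `(1 + count) / (1 + E)`.
#'
#' @param scores numeric vector of observed tag scores.
#' @param D a [null_distribution()] (or numeric vector of maxima).
#' @param add_one use the add-one estimator.
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
p_values <- function(scores, D, add_one = FALSE) {
  maxima <- if (inherits(D, "null_distribution")) D$maxima else as.numeric(D)
  if (!length(maxima)) stop("null distribution is empty")
  E <- length(maxima)
  counts <- vapply(scores, function(s) sum(maxima >= s), numeric(1))
  if (add_one) (1 + counts) / (1 + E) else counts / E
}

#' Iterative peel-off permutation significance test
#'
#' Repeatedly: build the max-T null `D_h` from the current tag matrix `T_h`,
#' assign p-values to its tags, and delete every tag with `p < alpha`
#' (strictly) to form `T_{h+1}`.  Each deletion removes a presumed consensus
#' event from the permutation pool, so the null mean drifts left toward a
#' background-only distribution.  The loop stops at the first iteration that
#' removes nothing (or when every tag has been peeled, with a warning, in
#' which case the last non-empty matrix defines the final null).  Finally all
#' original tags - including those peeled along the way - are re-assessed
#' against the final distribution `D_H`; those final p-values are the
#' authoritative ones.
#'
#' @param T a [tag_matrix()].
#' @param E permutations per iteration.
#' @param alpha peel cutoff in `[0, 1)`; tags tied exactly at `alpha` are
#'   kept.
#' @param seed optional integer seed for the whole procedure.
#' @param add_one use the add-one p-value estimator.
#' @return A `peel_off_result`: list with `p_values` (final, per original
#'   tag), `scores`, `removed_at` (iteration of peeling, 0 = never),
#'   `distributions` (list of `D_1 ... D_H` maxima vectors), `dist_means`,
#'   `H`, `alpha`, `E`, `add_one`.
#' @export
peel_off <- function(T, E, alpha = 0.05, seed = NULL, add_one = FALSE) {
  stopifnot(inherits(T, "tag_matrix"), E >= 1)
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must lie in [0, 1)")
  A <- abs(T$values)
  M <- ncol(A)
  scores <- score_tags(T)
  removed_at <- integer(M)
  dists <- list()
  maybe_with_seed(seed, {
    active <- rep(TRUE, M)
    h <- 0L
    repeat {
      h <- h + 1L
      D <- max_score_null(A[, active, drop = FALSE], as.integer(E))
      dists[[h]] <- D
      p_act <- p_values(scores[active], D, add_one = add_one)
      drop <- p_act < alpha
      if (!any(drop)) break
      removed_at[which(active)[drop]] <- h
      active[which(active)[drop]] <- FALSE
      if (!any(active)) {
        warning("every tag was peeled; final null taken from the last non-empty tag matrix")
        break
      }
    }
    NULL
  })
  H <- length(dists)
  final_p <- p_values(scores, dists[[H]], add_one = add_one)
  structure(list(p_values = final_p,
                 scores = scores,
                 removed_at = removed_at,
                 distributions = dists,
                 dist_means = vapply(dists, mean, numeric(1)),
                 H = H, alpha = alpha, E = as.integer(E),
                 add_one = add_one),
            class = "peel_off_result")
}

#' @export
print.peel_off_result <- function(x, ...) {
  cat(sprintf("peel_off_result: %d tags, H = %d iteration(s), E = %d\n",
              length(x$scores), x$H, x$E))
  cat(sprintf("  null mean by iteration: %s\n",
              paste(sprintf("%.3g", x$dist_means), collapse = " -> ")))
  cat(sprintf("  tags with final p < %g: %d\n", x$alpha,
              sum(x$p_values < x$alpha)))
  invisible(x)
}

#' Map significant tags to consensus event regions
#'
#' Each tag with final p-value below `alpha` stands for its whole correlation
#' block; the block's first-to-last marker positions become the region
#' bounds.  The aberrant-subject count is taken at the tag marker.
#'
#' @param result a [peel_off()] result (or list with `p_values`, `scores`).
#' @param tags the [tag_matrix()] the result was computed from (carries the
#'   block partition and tag columns).
#' @param markers a [marker_map()] slice for the same chromosome, aligned
#'   with the partition's marker indices.
#' @param alpha significance cutoff.
#' @return An [sce_regions()] data frame (empty when nothing is significant).
#' @export
call_sces <- function(result, tags, markers, alpha = 0.05) {
  stopifnot(inherits(tags, "tag_matrix"))
  markers <- validate_marker_map(markers)
  part <- tags$partition
  if (max(part$end) > nrow(markers))
    stop("partition extends beyond the marker map")
  sig <- which(result$p_values < alpha)
  sce_regions(data.frame(
    chrom = markers$chrom[part$tag_index[sig]],
    start_pos = markers$pos[part$start[sig]],
    end_pos = markers$pos[part$end[sig]],
    tag_marker_id = markers$marker_id[part$tag_index[sig]],
    polarity = rep(tags$polarity, length(sig)),
    score = result$scores[sig],
    p_value = result$p_values[sig],
    n_subjects_aberrant = vapply(sig, function(m)
      sum(tags$values[, m] != 0), integer(1)),
    stringsAsFactors = FALSE))
}
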