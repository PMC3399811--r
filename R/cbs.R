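#' Circular binary segmentation of a numeric series
#'
#' Recursive changepoint partition: at each step the pair of split points
#' maximising the circular two-sample t statistic (arc versus complement) is
#' found, the split is kept if its permutation p-value falls below `alpha`,
#' and the procedure recurses on the resulting pieces.  Segments shorter than
#' `min_width` are never created; ties in the maximising pair go to the
#' leftmost candidate, so the result is deterministic given the seed.
#'
#' Permutation sampling is curtailed: drawing stops as soon as the exceedance
#' count rules out `p < alpha`, which changes no decision.  When
#' `fast_accept = TRUE` (default) a split whose Bonferroni-bounded analytic
#' p-value over all admissible split pairs is below `alpha/100` is accepted
#' without permuting - a hybrid shortcut that only fires when the decision is
#' unambiguous by two orders of magnitude.
#'
#' @param series numeric vector; all values must be finite.
#' @param alpha per-split significance level in (0, 1).
#' @param min_width minimum segment length (markers), `>= 1`.
#' @param n_perm permutations per split test.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param fast_accept enable the analytic fast-accept shortcut.
#' @return A `cbs_segmentation` object: list with integer vectors `starts`,
#'   `ends`, `lengths` (1-based, tiling the series) and numeric
#'   `means` (arithmetic mean of the series over each segment).
#' @examples
#' x <- c(rep(0, 50), rep(1, 50))
#' cbs_segment(x, seed = 1)$starts
#' @export
cbs_segment <- function(series, alpha = 0.01, min_width = 2, n_perm = 200,
                        seed = NULL, fast_accept = TRUE) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 1) stop("series must have length >= 1")
  if (!all(is.finite(series))) stop("series contains non-finite values")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  min_width <- as.integer(min_width)
  if (min_width < 1) stop("min_width must be >= 1")
  if (n_perm < 1) stop("n_perm must be >= 1")

  final <- list()
  maybe_with_seed(seed, {
    queue <- list(c(1L, n))
    while (length(queue)) {
      iv <- queue[[1]]
      queue <- queue[-1]
      s <- iv[1]; e <- iv[2]
      len <- e - s + 1L
      if (len < 2L * min_width) {
        final[[length(final) + 1L]] <- iv
        next
      }
      d <- cpp_cbs_decide(series[s:e], min_width, alpha, as.integer(n_perm),
                          isTRUE(fast_accept), 0.01)
      if (!isTRUE(d$split)) {
        final[[length(final) + 1L]] <- iv
        next
      }
      # d$i / d$j are 0-based boundaries within the segment
      bounds <- sort(unique(c(s - 1L, s - 1L + d$i, s - 1L + d$j, e)))
      pieces <- Map(function(a, z) c(a + 1L, z),
                    bounds[-length(bounds)], bounds[-1])
      queue <- c(pieces, queue)  # left-to-right, depth-first
    }
    NULL
  })
  starts <- vapply(final, `[`, integer(1), 1L)
  ends <- vapply(final, `[`, integer(1), 2L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  means <- vapply(seq_along(starts),
                  function(b) mean(series[starts[b]:ends[b]]), numeric(1))
  structure(list(starts = starts, ends = ends, lengths = ends - starts + 1L,
                 means = means, n = n),
            class = "cbs_segmentation")
}

#' @export
print.cbs_segmentation <- function(x, ...) {
  cat(sprintf("cbs_segmentation: %d point(s), %d segment(s)\n",
              x$n, length(x$starts)))
  invisible(x)
}

#' Piecewise-constant fit of one subject's log2-ratio profile
#'
#' Applies [cbs_segment()] to a single subject's raw marker ratios and
#' returns the series of segment means, marker by marker - the usual
#' individual-sample preprocessing before thresholding into aberration calls.
#'
#' @inheritParams cbs_segment
#' @param ratios numeric vector of raw log2-ratios for one subject.
#' @return Numeric vector of the same length: each marker replaced by its
#'   segment mean.
#' @export
segment_subject <- function(ratios, alpha = 0.01, min_width = 2, n_perm = 200,
                            seed = NULL, fast_accept = TRUE) {
  seg <- cbs_segment(ratios, alpha = alpha, min_width = min_width,
                     n_perm = n_perm, seed = seed, fast_accept = fast_accept)
  rep(seg$means, seg$lengths)
}

#' Segment every subject of a raw cohort, chromosome by chromosome
#'
#' Convenience wrapper running [segment_subject()] on each row of a raw
#' [ratio_matrix()], independently per chromosome (a segment never crosses a
#' chromosome boundary).
#'
#' @inheritParams cbs_segment
#' @param x a raw [ratio_matrix()].
#' @return A [ratio_matrix()] of piecewise-constant per-subject profiles.
#' @export
segment_cohort <- function(x, alpha = 0.01, min_width = 2, n_perm = 200,
                           seed = NULL, fast_accept = TRUE) {
  stopifnot(inherits(x, "ratio_matrix"))
  out <- x$values
  maybe_with_seed(seed, {
    for (ch in unique(x$markers$chrom)) {
      idx <- which(x$markers$chrom == ch)
      for (n in seq_len(nrow(out))) {
        out[n, idx] <- segment_subject(x$values[n, idx], alpha = alpha,
                                       min_width = min_width, n_perm = n_perm,
                                       seed = NULL, fast_accept = fast_accept)
      }
    }
    NULL
  })
  ratio_matrix(out, x$markers)
}
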