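#' Pearson correlation between two marker columns
#'
#' Correlation across subjects between the aberration calls at markers `i`
#' and `j`, using means and standard deviations taken over all N subjects.
#' A column with zero variance (no aberration anywhere, or a constant call)
#' carries no consensus signal and is assigned correlation 0 by convention.
#'
#' @param X a call matrix (from [split_by_threshold()]) or numeric matrix,
#'   subjects x markers.
#' @param i,j distinct column indices.
#' @return The correlation coefficient (0 under the zero-variance convention).
#' @export
pairwise_correlation <- function(X, i, j) {
  vals <- matrix_values(X)
  if (nrow(vals) < 2) stop("correlation needs at least 2 subjects")
  if (i == j) stop("i and j must be distinct markers")
  if (min(i, j) < 1 || max(i, j) > ncol(vals)) stop("marker index out of range")
  a <- vals[, i]
  b <- vals[, j]
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Windowed correlation profile of a chromosome
#'
#' For each marker k, the mean Pearson correlation between k and every other
#' marker j with `|j - k| <= floor(w/2)` (k itself excluded).  At chromosome
#' ends the neighbour set shrinks and the divisor is the actual neighbour
#' count.  Zero-variance columns contribute correlation 0.
#'
#' @param X a call matrix for a single chromosome (or numeric matrix).
#' @param w window size in markers (total span), `>= 2` and at most the
#'   number of markers.
#' @return A `correlation_profile` object: list with `values` (one averaged
#'   correlation per marker, in `[-1, 1]`) and `window`.
#' @export
correlation_profile <- function(X, w = 20) {
  vals <- matrix_values(X)
  N <- nrow(vals)
  L <- ncol(vals)
  if (N < 2) stop("correlation profile needs at least 2 subjects")
  if (w < 2) stop("window size w must be >= 2")
  if (w > L)
    stop(sprintf("window size w = %d exceeds the chromosome's %d markers", w, L))
  halfw <- w %/% 2
  mu <- colMeans(vals)
  s <- sqrt(pmax(0, (colSums(vals^2) - N * mu^2) / (N - 1)))
  acc <- numeric(L)
  cnt <- numeric(L)
  for (d in seq_len(min(halfw, L - 1))) {
    i1 <- seq_len(L - d)
    i2 <- i1 + d
    cross <- colSums(vals[, i1, drop = FALSE] * vals[, i2, drop = FALSE])
    r <- (cross - N * mu[i1] * mu[i2]) / ((N - 1) * s[i1] * s[i2])
    r[!is.finite(r)] <- 0  # zero-variance convention
    r <- pmin(1, pmax(-1, r))
    acc[i1] <- acc[i1] + r
    cnt[i1] <- cnt[i1] + 1
    acc[i2] <- acc[i2] + r
    cnt[i2] <- cnt[i2] + 1
  }
  profile <- ifelse(cnt > 0, acc / cnt, 0)
  structure(list(values = profile, window = w), class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile: %d markers, window %d, mean %.3f\n",
              length(x$values), x$window, mean(x$values)))
  invisible(x)
}

#' Partition a correlation profile into blocks and pick tag markers
#'
#' Segments the windowed correlation profile with [cbs_segment()]; each
#' resulting segment becomes one correlation block, represented by the tag
#' marker at its middle site, `start + floor((len - 1) / 2)` (left of centre
#' for even lengths, a deterministic tie-break).
#'
#' @param profile a [correlation_profile()] (or numeric vector).
#' @param alpha,min_width,n_perm,seed,fast_accept passed to [cbs_segment()].
#' @param chrom optional chromosome label stored on the partition.
#' @return A `block_partition` data frame with columns `start`, `end`,
#'   `tag_index` (all 1-based marker indices within the chromosome).
#' @export
partition_blocks <- function(profile, alpha = 0.01, min_width = 2,
                             n_perm = 200, seed = NULL, fast_accept = TRUE,
                             chrom = NA_character_) {
  values <- if (inherits(profile, "correlation_profile")) profile$values else as.numeric(profile)
  seg <- cbs_segment(values, alpha = alpha, min_width = min_width,
                     n_perm = n_perm, seed = seed, fast_accept = fast_accept)
  tag <- seg$starts + (seg$lengths - 1L) %/% 2L
  new_block_partition(seg$starts, seg$ends, tag, chrom = chrom)
}

#' Build the tag-marker matrix from a call matrix and a block partition
#'
#' Column-subset of the call matrix at the tag indices, preserving subject
#' order: the N x M matrix on which scoring and peel-off permutation run.
#'
#' @param X a call matrix (or numeric matrix) for the same chromosome as
#'   `partition`.
#' @param partition a `block_partition` from [partition_blocks()].
#' @return A [tag_matrix()].
#' @export
build_tag_matrix <- function(X, partition) {
  vals <- matrix_values(X)
  if (max(partition$end) != ncol(vals) || min(partition$start) != 1L)
    stop("partition does not tile the call matrix's marker range")
  polarity <- if (is.list(X) && !is.null(X$polarity)) X$polarity else "amp"
  tag_matrix(vals[, partition$tag_index, drop = FALSE], partition, polarity)
}
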