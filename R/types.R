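#' Marker annotation table
#'
#' A marker map annotates the columns of a cohort matrix with genomic
#' coordinates: one row per marker, in column order, holding a text id, a
#' chromosome name and a 1-based base-pair point position.  Markers of one
#' chromosome must be contiguous and their positions strictly increasing.
#'
#' @param marker_id character vector of marker labels.
#' @param chrom chromosome name per marker.
#' @param pos 1-based base-pair position per marker.
#' @return A `marker_map` data frame with columns `marker_id`, `chrom`, `pos`.
#' @examples
#' marker_map(c("m1", "m2", "m3"), "chr1", c(100, 200, 300))
#' @export
marker_map <- function(marker_id, chrom, pos) {
  df <- data.frame(marker_id = as.character(marker_id),
                   chrom = as.character(rep_len(chrom, length(marker_id))),
                   pos = as.numeric(pos),
                   stringsAsFactors = FALSE)
  validate_marker_map(df)
}

validate_marker_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.numeric(df$pos)
  if (anyNA(df)) stop("marker map contains missing values")
  runs <- rle(df$chrom)
  if (anyDuplicated(runs$values))
    stop("markers of each chromosome must be contiguous in the map")
  for (ch in runs$values) {
    p <- df$pos[df$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop(sprintf("marker positions not strictly increasing on chromosome %s",
                   ch))
  }
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Cohort matrix of segmented log2 copy-number ratios
#'
#' The central input container: an N x L numeric matrix of per-subject
#' segmented log2-ratios (rows = subjects, columns = markers) together with a
#' [marker_map()] describing the columns.  Missing or non-finite cells are
#' rejected; no imputation is performed.
#'
#' @param values numeric matrix, subjects x markers.
#' @param markers a [marker_map()] (or coercible data frame) with one row per
#'   matrix column.
#' @return A `ratio_matrix` object (list with elements `values`, `markers`).
#' @export
ratio_matrix <- function(values, markers) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  markers <- validate_marker_map(markers)
  if (ncol(values) != nrow(markers))
    stop(sprintf("matrix has %d columns but marker map has %d rows",
                 ncol(values), nrow(markers)))
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("ratio matrix must have at least one subject and one marker")
  if (anyNA(values) || !all(is.finite(values)))
    stop("ratio matrix contains missing or non-finite cells")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  colnames(values) <- markers$marker_id
  structure(list(values = values, markers = markers), class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat(sprintf("ratio_matrix: %d subjects x %d markers (%d chromosome%s)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$markers$chrom)),
              if (length(unique(x$markers$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

# Thresholded aberration matrix for one polarity.  Aberrant cells keep their
# log2-ratio; non-aberrant cells are exactly zero.
new_call_matrix <- function(values, markers, polarity, threshold) {
  polarity <- match.arg(polarity, c("amp", "del"))
  nz <- values[values != 0]
  if (polarity == "amp") {
    if (length(nz) && any(nz < threshold))
      stop("amplification call matrix has nonzero cells below its threshold")
  } else {
    if (length(nz) && any(nz > threshold))
      stop("deletion call matrix has nonzero cells above its threshold")
  }
  structure(list(values = values, markers = markers, polarity = polarity,
                 threshold = threshold),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix (%s, threshold %g): %d subjects x %d markers, %.1f%% aberrant cells\n",
              x$polarity, x$threshold, nrow(x$values), ncol(x$values),
              100 * mean(x$values != 0)))
  invisible(x)
}

#' @export
dim.call_matrix <- function(x) dim(x$values)

# Accept a call/ratio/tag matrix container or a bare numeric matrix.
matrix_values <- function(x) {
  if (is.list(x) && !is.null(x$values)) as.matrix(x$values) else as.matrix(x)
}

#' Tag-marker matrix
#'
#' The subjects x tags submatrix on which scoring and permutation operate.
#' Usually built with [build_tag_matrix()]; this constructor also lets a tag
#' matrix be assembled directly (e.g. for permutation experiments), with a
#' trivial one-marker-per-block partition when none is given.
#'
#' @param values numeric matrix, subjects x tag markers.
#' @param partition a `block_partition` (from [partition_blocks()]), or `NULL`
#'   for the identity partition.
#' @param polarity `"amp"` or `"del"`.
#' @return A `tag_matrix` object.
#' @export
tag_matrix <- function(values, partition = NULL, polarity = "amp") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  polarity <- match.arg(polarity, c("amp", "del"))
  if (is.null(partition)) {
    partition <- new_block_partition(seq_len(ncol(values)),
                                     seq_len(ncol(values)),
                                     seq_len(ncol(values)))
  }
  if (nrow(partition) != ncol(values))
    stop("partition has a different number of blocks than tag columns")
  structure(list(values = values, partition = partition, polarity = polarity),
            class = "tag_matrix")
}

#' @export
print.tag_matrix <- function(x, ...) {
  cat(sprintf("tag_matrix (%s): %d subjects x %d tag markers\n",
              x$polarity, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.tag_matrix <- function(x) dim(x$values)

new_block_partition <- function(start, end, tag_index, chrom = NA_character_) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   tag_index = as.integer(tag_index))
  if (any(df$end < df$start)) stop("blocks must have end >= start")
  if (nrow(df) > 1) {
    if (any(df$start[-1] != df$end[-nrow(df)] + 1L))
      stop("blocks must tile the marker range without gaps or overlap")
  }
  if (any(df$tag_index < df$start | df$tag_index > df$end))
    stop("tag_index must lie inside its block")
  attr(df, "chrom") <- chrom
  class(df) <- c("block_partition", "data.frame")
  df
}

#' Table of significant consensus event regions
#'
#' Validates a data frame of SCE calls (one row per significant tag marker,
#' spanning its correlation block) as produced by [call_sces()].
#'
#' @param df data frame with columns `chrom`, `start_pos`, `end_pos`
#'   (1-based inclusive bounds), `tag_marker_id`, `polarity`, `score`,
#'   `p_value`, `n_subjects_aberrant`.
#' @return The validated `sce_regions` data frame.
#' @export
sce_regions <- function(df) {
  need <- c("chrom", "start_pos", "end_pos", "tag_marker_id", "polarity",
            "score", "p_value", "n_subjects_aberrant")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!all(need %in% names(df)))
    stop("SCE region table needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (nrow(df)) {
    if (any(df$end_pos < df$start_pos)) stop("SCE regions need start_pos <= end_pos")
    if (any(df$p_value < 0 | df$p_value > 1)) stop("p_value must lie in [0, 1]")
    if (!all(df$polarity %in% c("amp", "del"))) stop("polarity must be 'amp' or 'del'")
  }
  rownames(df) <- NULL
  class(df) <- c("sce_regions", "data.frame")
  df
}
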