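#' Read a cohort log2-ratio matrix with its marker map
#'
#' The matrix file is tab-separated with a corner cell, marker ids across the
#' first row and subject ids down the first column.  The marker file is
#' tab-separated with columns `marker_id`, `chrom`, `pos`.  Cells must all be
#' numeric and present; missing data are a hard error rather than imputed.
#'
#' @param path path to the matrix TSV.
#' @param marker_path path to the marker-map TSV.
#' @return A [ratio_matrix()].
#' @seealso [write_ratio_matrix()]
#' @export
read_ratio_matrix <- function(path, marker_path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop(sprintf("'%s' has no data rows", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  if (length(header) < 2)
    stop(sprintf("'%s': header row must hold a corner cell plus marker ids", path))
  ids <- header[-1]
  L <- length(ids)
  body <- parts[-1]
  nf <- lengths(body)
  bad <- which(nf != L + 1L)
  if (length(bad))
    stop(sprintf("line %d of '%s' has %d fields; expected %d",
                 bad[1] + 1L, path, nf[bad[1]], L + 1L))
  subjects <- vapply(body, `[`, character(1), 1L)
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  num <- suppressWarnings(as.numeric(cells))
  nonnum <- is.na(num) & !(cells %in% c("NA", ""))
  if (any(nonnum)) {
    k <- which(nonnum)[1]
    stop(sprintf("non-numeric value '%s' at row %d, column %d of '%s'",
                 cells[k], (k - 1L) %/% L + 1L, (k - 1L) %% L + 1L, path))
  }
  if (anyNA(num)) {
    k <- which(is.na(num))[1]
    stop(sprintf("missing cell at row %d, column %d of '%s'; missing data are not supported",
                 (k - 1L) %/% L + 1L, (k - 1L) %% L + 1L, path))
  }
  values <- matrix(num, nrow = length(body), ncol = L, byrow = TRUE,
                   dimnames = list(subjects, ids))
  markers <- read.delim(marker_path, sep = "\t", stringsAsFactors = FALSE)
  markers <- validate_marker_map(markers)
  if (nrow(markers) != L)
    stop(sprintf("marker map '%s' has %d rows but matrix has %d columns",
                 marker_path, nrow(markers), L))
  if (!identical(markers$marker_id, ids))
    stop("marker ids in the matrix header do not match the marker map")
  ratio_matrix(values, markers)
}

#' Write a cohort log2-ratio matrix (and optionally its marker map)
#'
#' Inverse of [read_ratio_matrix()]; values are written with 17 significant
#' digits so the round trip is lossless.
#'
#' @param x a [ratio_matrix()].
#' @param path output path for the matrix TSV.
#' @param marker_path optional output path for the marker-map TSV.
#' @return Invisibly, `x`.
#' @export
write_ratio_matrix <- function(x, path, marker_path = NULL) {
  stopifnot(inherits(x, "ratio_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("subject", x$markers$marker_id), collapse = "\t"), con)
  for (n in seq_len(nrow(x$values))) {
    writeLines(paste(c(rownames(x$values)[n],
                       sprintf("%.17g", x$values[n, ])), collapse = "\t"), con)
  }
  if (!is.null(marker_path)) write_marker_map(x$markers, marker_path)
  invisible(x)
}

#' Write a marker map as TSV
#'
#' @param markers a [marker_map()].
#' @param path output path.
#' @return Invisibly, `markers`.
#' @export
write_marker_map <- function(markers, path) {
  markers <- validate_marker_map(markers)
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(markers)
}

#' Expand SEG-style segment records onto a marker map
#'
#' Reads a tab-separated segment table with columns `sample`, `chrom`,
#' `start`, `end`, `num_markers`, `seg_mean` (coordinates 1-based inclusive)
#' and expands it to a per-marker matrix: every marker whose position falls
#' inside a segment receives that segment's mean.  Markers covered by no
#' segment are filled with 0 (no aberration) and counted in a warning.
#'
#' @param path path to the SEG TSV.
#' @param marker_map a [marker_map()] covering the genome analysed.
#' @return A [ratio_matrix()] with one row per distinct sample, in order of
#'   first appearance.
#' @export
read_seg_segments <- function(path, marker_map) {
  marker_map <- validate_marker_map(marker_map)
  seg <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "num_markers", "seg_mean")
  if (!all(need %in% names(seg)))
    stop("SEG file needs columns: ", paste(need, collapse = ", "))
  seg$chrom <- as.character(seg$chrom)
  unknown <- setdiff(unique(seg$chrom), unique(marker_map$chrom))
  if (length(unknown))
    stop("SEG records on chromosome(s) absent from the marker map: ",
         paste(unknown, collapse = ", "))
  for (s in unique(seg$sample)) {
    for (ch in unique(seg$chrom[seg$sample == s])) {
      rec <- seg[seg$sample == s & seg$chrom == ch, , drop = FALSE]
      rec <- rec[order(rec$start), , drop = FALSE]
      if (nrow(rec) > 1) {
        ov <- which(rec$start[-1] <= rec$end[-nrow(rec)])
        if (length(ov))
          stop(sprintf(
            "overlapping segments for sample '%s' on %s: [%g, %g] and [%g, %g]",
            s, ch, rec$start[ov[1]], rec$end[ov[1]],
            rec$start[ov[1] + 1], rec$end[ov[1] + 1]))
      }
    }
  }
  subjects <- unique(seg$sample)
  L <- nrow(marker_map)
  values <- matrix(0, nrow = length(subjects), ncol = L,
                   dimnames = list(subjects, marker_map$marker_id))
  covered <- matrix(FALSE, nrow = length(subjects), ncol = L)
  for (r in seq_len(nrow(seg))) {
    idx <- which(marker_map$chrom == seg$chrom[r] &
                   marker_map$pos >= seg$start[r] &
                   marker_map$pos <= seg$end[r])
    if (length(idx)) {
      n <- match(seg$sample[r], subjects)
      values[n, idx] <- seg$seg_mean[r]
      covered[n, idx] <- TRUE
    }
  }
  n_uncovered <- sum(!covered)
  if (n_uncovered > 0)
    warning(sprintf("%d marker cell(s) covered by no segment; filled with 0",
                    n_uncovered))
  ratio_matrix(values, marker_map)
}

#' Write SCE regions as a BED-detail file
#'
#' One data line per region with columns chrom, start, end, name
#' (tag marker id), score, polarity, p_value and n_subjects_aberrant.
#' Internal coordinates are 1-based inclusive; output follows the BED
#' convention (0-based start, exclusive end).  Records are sorted by
#' chromosome then start.  An empty region list yields a header-only file.
#'
#' @param regions an [sce_regions()] data frame (or coercible).
#' @param path output path.
#' @return Invisibly, the written data frame.
#' @export
write_sce_regions <- function(regions, path) {
  regions <- sce_regions(regions)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom", "start", "end", "name", "score", "polarity",
                     "p_value", "n_subjects_aberrant"), collapse = "\t"), con)
  if (nrow(regions)) {
    regions <- regions[order(regions$chrom, regions$start_pos), , drop = FALSE]
    for (r in seq_len(nrow(regions))) {
      writeLines(paste(c(regions$chrom[r],
                         sprintf("%d", as.integer(regions$start_pos[r]) - 1L),
                         sprintf("%d", as.integer(regions$end_pos[r])),
                         regions$tag_marker_id[r],
                         sprintf("%.17g", regions$score[r]),
                         regions$polarity[r],
                         sprintf("%.17g", regions$p_value[r]),
                         sprintf("%d", as.integer(regions$n_subjects_aberrant[r]))),
                       collapse = "\t"), con)
    }
  }
  invisible(regions)
}

#' Read SCE regions written by [write_sce_regions()]
#'
#' @param path path to a BED-detail SCE file.
#' @return An [sce_regions()] data frame (coordinates back in 1-based
#'   inclusive form).
#' @export
read_sce_regions <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop(sprintf("'%s' does not look like an SCE region file (no header)", path))
  if (length(lines) == 1) {
    return(sce_regions(data.frame(chrom = character(), start_pos = numeric(),
                                  end_pos = numeric(), tag_marker_id = character(),
                                  polarity = character(), score = numeric(),
                                  p_value = numeric(),
                                  n_subjects_aberrant = integer())))
  }
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 8L)
  if (length(bad))
    stop(sprintf("line %d of '%s' has %d fields; expected 8",
                 bad[1] + 1L, path, lengths(parts)[bad[1]]))
  f <- function(k) vapply(parts, `[`, character(1), k)
  sce_regions(data.frame(
    chrom = f(1),
    start_pos = as.numeric(f(2)) + 1,
    end_pos = as.numeric(f(3)),
    tag_marker_id = f(4),
    polarity = f(6),
    score = as.numeric(f(5)),
    p_value = as.numeric(f(7)),
    n_subjects_aberrant = as.integer(f(8)),
    stringsAsFactors = FALSE))
}
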