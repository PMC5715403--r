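# Conserved-block selection.
#
# Before tree building, poorly aligned alignment segments are removed and
# only runs of well-conserved columns retained -- the same role Gblocks plays
# in the published analysis (where it left a 315-aa block set for the
# SAM-radical domain tree and 64 aa for the NifX-like domain trees; block
# lengths are aligner-dependent and this implementation logs its own).

#' Select conserved blocks from an alignment
#'
#' Columns are classified by modal-residue frequency: `conserved` at
#' `conserved_fraction`, `highly conserved` at `flank_fraction`. With
#' `allow_gaps = FALSE` any column containing a gap is excluded outright and
#' splits blocks. Candidate blocks are maximal runs interrupted by fewer than
#' `max_noncons_run` consecutive non-conserved columns; each block is trimmed
#' until both flanks are highly conserved columns, and blocks shorter than
#' `min_block_len` are discarded.
#'
#' @param alignment Named character vector or record tibble of equal-length
#'   aligned sequences.
#' @param conserved_fraction Modal-residue frequency for "conserved" (0.5).
#' @param flank_fraction Modal-residue frequency for "highly conserved" (0.85).
#' @param max_noncons_run Non-conserved run length that breaks a block (8).
#' @param min_block_len Minimum retained block length in columns (10).
#' @param allow_gaps Keep gap-containing columns eligible (default `FALSE`).
#' @return A `block_set`: list with `intervals` (tibble `start`, `end`,
#'   `length`; 1-based inclusive, sorted, disjoint) and `total_length`.
#' @export
select_blocks <- function(alignment, conserved_fraction = 0.5,
                          flank_fraction = 0.85, max_noncons_run = 8L,
                          min_block_len = 10L, allow_gaps = FALSE) {
  seqs <- alignment_seqs(alignment)
  if (length(unique(nchar(seqs))) != 1) stop("not an alignment: ragged rows")
  m <- seq_matrix(seqs)
  nc <- ncol(m)
  nr <- nrow(m)
  if (nc < min_block_len) return(new_block_set(integer(0), integer(0)))

  # per-column status: "gap" (hard break), "hc", "c", "nc"
  status <- vapply(seq_len(nc), function(j) {
    col <- m[, j]
    if (!allow_gaps && any(col == "-")) return("gap")
    res <- col[col != "-"]
    if (!length(res)) return("gap")
    f <- max(table(res)) / nr
    if (f >= flank_fraction) "hc" else if (f >= conserved_fraction) "c" else "nc"
  }, character(1))

  brk <- status == "gap"
  r <- rle(status)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (r$values[k] == "nc" && r$lengths[k] >= max_noncons_run) {
      brk[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
    }
  }
  segs <- split(which(!brk), cumsum(brk)[!brk])
  starts <- integer(0)
  stops <- integer(0)
  for (seg in segs) {
    hc <- seg[status[seg] == "hc"]
    if (!length(hc)) next
    seg <- seg[seg >= min(hc) & seg <= max(hc)]
    if (length(seg) < min_block_len) next
    starts <- c(starts, seg[1])
    stops <- c(stops, seg[length(seg)])
  }
  new_block_set(starts, stops)
}

new_block_set <- function(starts, stops) {
  intervals <- tibble::tibble(start = as.integer(starts),
                              end = as.integer(stops),
                              length = as.integer(stops - starts + 1L))
  structure(list(intervals = intervals,
                 total_length = sum(intervals$length)),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("<block_set> %d block(s), %d columns total\n",
              nrow(x$intervals), x$total_length))
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Extract retained block columns from an alignment
#'
#' @param alignment Named character vector or record tibble.
#' @param blocks A `block_set` (or tibble of `start`/`end` intervals).
#' @return Named character vector: the concatenation of retained columns,
#'   row order preserved; zero-length rows if no blocks.
#' @export
extract_blocks <- function(alignment, blocks) {
  seqs <- alignment_seqs(alignment)
  iv <- if (inherits(blocks, "block_set")) blocks$intervals else blocks
  width <- unique(nchar(seqs))
  if (length(width) != 1) stop("not an alignment: ragged rows")
  if (nrow(iv) == 0) {
    return(stats::setNames(rep("", length(seqs)), names(seqs)))
  }
  if (any(iv$start < 1 | iv$end > width | iv$start > iv$end)) {
    stop("block out of range")
  }
  out <- vapply(seqs, function(s) {
    paste(substring(s, iv$start, iv$end), collapse = "")
  }, character(1))
  stats::setNames(out, names(seqs))
}

#' Write a block report TSV
#' @param blocks A `block_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_report <- function(blocks, path) {
  utils::write.table(blocks$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
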