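# Motif fingerprint engine.
#
# The curation filter rests on six motifs strictly conserved in the NifB
# SAM-radical domain: HPC, the AdoMet cysteine triad Cx3Cx2C common to all
# radical-SAM enzymes, ExRP, AGPG, TxTxN and Cx2CRxDAxG. A candidate is
# accepted as NifB only if all six can be placed on the sequence, in order.
#
# Pattern grammar: uppercase canonical residue letters are literals; a
# lowercase 'x' is one arbitrary residue; an integer immediately after 'x'
# repeats the wildcard ("Cx3Cx2C" = C, three wildcards, C, two wildcards, C).
# Coordinates are 1-based and inclusive throughout.

#' Parse a motif pattern string
#'
#' @param text Pattern string, e.g. `"Cx3Cx2C"`.
#' @param name Pattern name; defaults to the pattern text.
#' @return A `motif_pattern`: list with `name`, `text`, `tokens` (list of
#'   literal/wildcard tokens), `span` (total residue length) and `mask`
#'   (character vector of length `span`; `NA` marks wildcard positions).
#' @examples
#' parse_pattern("Cx3Cx2C")$span  # 8
#' @export
parse_pattern <- function(text, name = text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(text)) {
    stop("pattern syntax error: empty pattern")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% AA20) {
      tokens[[length(tokens) + 1L]] <- list(type = "literal", letter = ch)
      i <- i + 1L
    } else if (ch == "x") {
      j <- i + 1L
      digits <- character(0)
      while (j <= length(chars) && grepl("[0-9]", chars[j])) {
        digits <- c(digits, chars[j])
        j <- j + 1L
      }
      count <- if (length(digits)) as.integer(paste(digits, collapse = "")) else 1L
      if (count < 1L) {
        stop("pattern syntax error at position ", i,
             ": wildcard count must be >= 1")
      }
      tokens[[length(tokens) + 1L]] <- list(type = "wildcard", count = count)
      i <- j
    } else if (grepl("[0-9]", ch)) {
      stop("pattern syntax error at position ", i,
           ": digit must follow 'x'")
    } else {
      stop("pattern syntax error at position ", i,
           ": unexpected character '", ch, "'")
    }
  }
  mask <- unlist(lapply(tokens, function(tk) {
    if (tk$type == "literal") tk$letter else rep(NA_character_, tk$count)
  }))
  if (all(is.na(mask))) {
    stop("pattern syntax error: pattern must contain at least one literal")
  }
  structure(list(name = name, text = text, tokens = tokens,
                 span = length(mask), mask = mask),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (span %d)\n", x$name, x$text, x$span))
  invisible(x)
}

#' Scan a sequence for all occurrences of a motif pattern
#'
#' Reports every match position left-to-right, including overlapping
#' occurrences. Literal tokens match only their exact letter; a wildcard
#' matches any residue including `X`; a literal never matches `X` (an unknown
#' residue cannot confirm a strictly conserved position).
#'
#' @param sequence Residue string.
#' @param pattern A `motif_pattern`.
#' @return Tibble of hits: `pattern_name`, `start`, `end`, `matched`
#'   (1-based inclusive coordinates). Empty if the sequence is shorter than
#'   the pattern span.
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"),
            is.character(sequence), length(sequence) == 1)
  empty <- tibble::tibble(pattern_name = character(), start = integer(),
                          end = integer(), matched = character())
  n <- nchar(sequence)
  span <- pattern$span
  if (n < span) return(empty)
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offs <- seq_len(n - span + 1L)
  ok <- rep(TRUE, length(offs))
  for (p in which(!is.na(pattern$mask))) {
    ok <- ok & (s[offs + p - 1L] == pattern$mask[p])
  }
  starts <- offs[ok]
  if (!length(starts)) return(empty)
  tibble::tibble(pattern_name = pattern$name,
                 start = as.integer(starts),
                 end = as.integer(starts + span - 1L),
                 matched = substring(sequence, starts, starts + span - 1L))
}

#' The default NifB fingerprint
#'
#' The six motifs strictly conserved in the SAM-radical domain of
#' experimentally validated NifB proteins, in N-to-C order: HPC, Cx3Cx2C
#' (the AdoMet cysteine triad), ExRP, AGPG, TxTxN and Cx2CRxDAxG.
#'
#' @return A `nifb_fingerprint` (ordered list of `motif_pattern`s).
#' @export
nifb_fingerprint <- function() {
  path <- system.file("extdata", "nifb_fingerprint.tsv", package = "nifb",
                      mustWork = TRUE)
  read_fingerprint(path)
}

#' Read a fingerprint definition file
#'
#' Plain text, one motif per line: `name<TAB>pattern`.
#'
#' @param path Path to the definition file.
#' @return A `nifb_fingerprint`.
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty fingerprint file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("malformed fingerprint file: ", path)
  fingerprint(lapply(parts, function(p) parse_pattern(p[2], name = p[1])))
}

#' Build a fingerprint from motif patterns
#' @param patterns List of `motif_pattern` objects (ordered N to C).
#' @return A `nifb_fingerprint`.
#' @export
fingerprint <- function(patterns) {
  if (!length(patterns)) stop("empty fingerprint")
  stopifnot(all(vapply(patterns, inherits, logical(1), "motif_pattern")))
  nm <- vapply(patterns, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate pattern name in fingerprint")
  structure(patterns, class = "nifb_fingerprint", names = nm)
}

#' @export
print.nifb_fingerprint <- function(x, ...) {
  cat(sprintf("<nifb_fingerprint> %d motifs: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Match a full motif fingerprint against a sequence
#'
#' Ordered search: motif i+1 must start strictly after the end of the placed
#' hit of motif i, so accepted hits are non-overlapping and in N-to-C order.
#' Placement is greedy leftmost with backtracking over alternative hits (for
#' fixed-span motifs greedy placement is already optimal). `passed` requires
#' every motif to be placed; `missing` lists motifs that could not be.
#'
#' @param record A one-row record tibble/list with `id` and `sequence`, or a
#'   plain sequence string.
#' @param fingerprint A `nifb_fingerprint`.
#' @param ordered Require N-to-C order and non-overlap (default). With
#'   `FALSE`, mere presence of each motif anywhere suffices.
#' @return A `fingerprint_result`: list with `record_id`, `passed`, `hits`
#'   (tibble, one row per placed motif) and `missing` (character).
#' @export
match_fingerprint <- function(record, fingerprint, ordered = TRUE) {
  stopifnot(inherits(fingerprint, "nifb_fingerprint"))
  if (is.character(record)) record <- list(id = NA_character_, sequence = record)
  seq <- record$sequence
  hits <- lapply(fingerprint, function(p) scan_motif(seq, p))
  spans <- vapply(fingerprint, `[[`, integer(1), "span")
  npat <- length(fingerprint)

  if (!ordered) {
    found <- vapply(hits, nrow, integer(1)) > 0
    placed <- dplyr::bind_rows(lapply(hits[found], function(h) h[1, ]))
    return(new_fingerprint_result(record$id, all(found), placed,
                                  names(fingerprint)[!found]))
  }

  # Depth-first search over hit choices; the first solution found is the
  # greedy leftmost placement.
  solve <- function(k, min_start) {
    if (k > npat) return(integer(0))
    cand <- hits[[k]]$start[hits[[k]]$start >= min_start]
    for (st in cand) {
      rest <- solve(k + 1L, st + spans[k])
      if (!is.null(rest)) return(c(st, rest))
    }
    NULL
  }
  sol <- solve(1L, 1L)
  if (!is.null(sol)) {
    placed <- tibble::tibble(
      pattern_name = names(fingerprint),
      start = as.integer(sol),
      end = as.integer(sol + spans - 1L),
      matched = substring(seq, sol, sol + spans - 1L))
    return(new_fingerprint_result(record$id, TRUE, placed, character(0)))
  }
  # No full placement: greedy pass that skips unplaceable motifs, so that
  # `missing` names exactly the motifs that broke the chain.
  pos <- 1L
  placed <- list()
  missing <- character(0)
  for (k in seq_len(npat)) {
    cand <- hits[[k]][hits[[k]]$start >= pos, , drop = FALSE]
    if (nrow(cand)) {
      placed[[length(placed) + 1L]] <- cand[1, ]
      pos <- cand$end[1] + 1L
    } else {
      missing <- c(missing, names(fingerprint)[k])
    }
  }
  new_fingerprint_result(record$id, FALSE, dplyr::bind_rows(placed), missing)
}

new_fingerprint_result <- function(record_id, passed, hits, missing) {
  if (nrow(hits) == 0) {
    hits <- tibble::tibble(pattern_name = character(), start = integer(),
                           end = integer(), matched = character())
  }
  structure(list(record_id = record_id, passed = passed, hits = hits,
                 missing = missing),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat(sprintf("<fingerprint_result> %s: %s", x$record_id,
              if (x$passed) "PASS" else "FAIL"))
  if (length(x$missing)) cat(" (missing: ", paste(x$missing, collapse = ", "),
                             ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Discover conserved motifs from an alignment of validated proteins
#'
#' Emulates how the NifB fingerprint was originally derived: align proteins of
#' proven function and read off the strictly conserved blocks. A column is
#' conserved when it contains no gaps and one residue reaches frequency
#' `min_conservation`; maximal runs mixing conserved columns (emitted as
#' literals) with short stretches of non-conserved gap-free columns (emitted
#' as wildcards, at most `max_wildcard_run` consecutive) become patterns.
#' Patterns must start and end on a literal and contain at least
#' `min_motif_len` literals.
#'
#' @param alignment Named character vector (or record tibble) of equal-length
#'   aligned sequences, gap character `-`.
#' @param min_conservation Minimum modal-residue frequency in (0, 1].
#' @param min_motif_len Minimum number of literal positions per motif (>= 2).
#' @param max_wildcard_run Longest wildcard stretch allowed inside a motif.
#'   Default 3 (the AdoMet motif Cx3Cx2C needs a run of three).
#' @return List of `motif_pattern`s, ordered by alignment position, with a
#'   `column` attribute giving each motif's first alignment column.
#' @export
discover_fingerprint <- function(alignment, min_conservation = 1.0,
                                 min_motif_len = 2L, max_wildcard_run = 3L) {
  seqs <- alignment_seqs(alignment)
  if (length(seqs) < 2) stop("insufficient sequences: need >= 2 rows")
  if (length(unique(nchar(seqs))) != 1) stop("not an alignment: ragged rows")
  stopifnot(min_conservation > 0, min_conservation <= 1, min_motif_len >= 2)
  m <- seq_matrix(seqs)
  ncol_a <- ncol(m)
  cls <- character(ncol_a)   # CONS / WILD / GAP
  modal <- character(ncol_a)
  for (j in seq_len(ncol_a)) {
    col <- m[, j]
    if (any(col == "-")) {
      cls[j] <- "GAP"
      next
    }
    tab <- sort(table(col), decreasing = TRUE)
    modal[j] <- names(tab)[1]
    cls[j] <- if (tab[1] / length(col) >= min_conservation) "CONS" else "WILD"
  }
  # break at gap columns and at wildcard runs longer than max_wildcard_run
  brk <- cls == "GAP"
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (r$values[k] == "WILD" && r$lengths[k] > max_wildcard_run) {
      brk[(ends[k] - r$lengths[k] + 1L):ends[k]] <- TRUE
    }
  }
  segs <- split(which(!brk), cumsum(brk)[!brk])
  patterns <- list()
  cols <- integer(0)
  for (seg in segs) {
    lit <- seg[cls[seg] == "CONS"]
    if (!length(lit)) next
    seg <- seg[seg >= min(lit) & seg <= max(lit)]   # trim to literal ends
    if (length(lit) < min_motif_len) next
    text <- build_pattern_text(cls[seg], modal[seg])
    patterns[[length(patterns) + 1L]] <- parse_pattern(text)
    cols <- c(cols, seg[1])
  }
  # de-duplicate names (identical motif texts can recur along the alignment)
  nm <- vapply(patterns, `[[`, character(1), "name")
  dup <- duplicated(nm)
  if (any(dup)) {
    nm <- make.unique(nm, sep = ".")
    for (k in which(dup)) patterns[[k]]$name <- nm[k]
  }
  attr(patterns, "column") <- cols
  patterns
}

build_pattern_text <- function(cls, modal) {
  out <- character(0)
  i <- 1L
  while (i <= length(cls)) {
    if (cls[i] == "CONS") {
      out <- c(out, modal[i])
      i <- i + 1L
    } else {
      j <- i
      while (j <= length(cls) && cls[j] != "CONS") j <- j + 1L
      k <- j - i
      out <- c(out, if (k == 1L) "x" else paste0("x", k))
      i <- j
    }
  }
  paste(out, collapse = "")
}

# Accept alignments as named character vectors or record tibbles.
alignment_seqs <- function(alignment) {
  if (is.data.frame(alignment)) {
    stats::setNames(alignment$sequence, alignment$id)
  } else if (is.character(alignment)) {
    alignment
  } else {
    stop("not an alignment")
  }
}
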