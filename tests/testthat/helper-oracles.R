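# Independent brute-force oracles and small fixture builders. These are
# written against the rule statements only and deliberately share no code
# with the package implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Expand a pattern string into a per-position vector of required letters
# (NA = any residue), by plain character walking.
oracle_expand <- function(text) {
  chars <- strsplit(text, "")[[1]]
  out <- character(0)
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "x") {
      j <- i + 1
      num <- ""
      while (j <= length(chars) && chars[j] %in% as.character(0:9)) {
        num <- paste0(num, chars[j]); j <- j + 1
      }
      k <- if (nzchar(num)) as.integer(num) else 1L
      out <- c(out, rep(NA_character_, k))
      i <- j
    } else {
      out <- c(out, chars[i])
      i <- i + 1
    }
  }
  out
}

# Exhaustive-offset motif scanner: tests every start position token by token.
oracle_scan <- function(sequence, pattern_text) {
  req <- oracle_expand(pattern_text)
  s <- strsplit(sequence, "")[[1]]
  starts <- integer(0)
  if (length(s) >= length(req)) {
    for (off in 1:(length(s) - length(req) + 1)) {
      ok <- TRUE
      for (p in seq_along(req)) {
        if (!is.na(req[p]) && s[off + p - 1] != req[p]) { ok <- FALSE; break }
      }
      if (ok) starts <- c(starts, off)
    }
  }
  starts
}

# Random motif pattern text with at least one literal.
random_pattern_text <- function() {
  ntok <- sample(2:6, 1)
  toks <- character(ntok)
  for (i in seq_len(ntok)) {
    toks[i] <- if (runif(1) < 0.55) sample(AA, 1) else {
      k <- sample(1:3, 1)
      if (k == 1 && runif(1) < 0.5) "x" else paste0("x", k)
    }
  }
  if (!any(toks %in% AA)) toks[sample(ntok, 1)] <- sample(AA, 1)
  paste(toks, collapse = "")
}

# Column-by-column block-selection oracle applying the stated rules:
# gap columns are excluded and break blocks; runs of >= max_noncons_run
# consecutive non-conserved columns break blocks; blocks are trimmed to
# highly conserved flanks and dropped when shorter than min_block_len.
oracle_blocks <- function(seqs, conserved_fraction = 0.5,
                          flank_fraction = 0.85, max_noncons_run = 8,
                          min_block_len = 10) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  nc <- ncol(m)
  if (nc < min_block_len) return(data.frame(start = integer(), end = integer()))
  status <- character(nc)
  for (j in 1:nc) {
    col <- m[, j]
    if (any(col == "-")) { status[j] <- "gap"; next }
    counts <- integer(0)
    for (a in unique(col)) counts <- c(counts, sum(col == a))
    f <- max(counts) / nrow(m)
    status[j] <- if (f >= flank_fraction) "hc" else
      if (f >= conserved_fraction) "c" else "nc"
  }
  # mark breaks
  broken <- status == "gap"
  run <- 0
  for (j in 1:nc) {
    if (status[j] == "nc") run <- run + 1 else run <- 0
    if (run == max_noncons_run) {
      broken[(j - max_noncons_run + 1):j] <- TRUE
    } else if (run > max_noncons_run) {
      broken[j] <- TRUE
    }
  }
  out <- data.frame(start = integer(), end = integer())
  j <- 1
  while (j <= nc) {
    if (broken[j]) { j <- j + 1; next }
    k <- j
    while (k < nc && !broken[k + 1]) k <- k + 1
    seg <- j:k
    hc <- seg[status[seg] == "hc"]
    if (length(hc)) {
      seg <- seg[seg >= min(hc) & seg <= max(hc)]
      if (length(seg) >= min_block_len) {
        out <- rbind(out, data.frame(start = seg[1], end = seg[length(seg)]))
      }
    }
    j <- k + 1
  }
  out
}

# Random gappy alignment with conservation structure: a template row copied
# with per-column mutation probabilities so that all column classes occur.
random_alignment <- function(nrow = 6, ncol = 60, gap_p = 0.05) {
  template <- sample(AA, ncol, replace = TRUE)
  mut_p <- sample(c(0, 0.1, 0.45, 0.9), ncol, replace = TRUE)
  rows <- character(nrow)
  for (i in 1:nrow) {
    r <- template
    mut <- runif(ncol) < mut_p
    r[mut] <- sample(AA, sum(mut), replace = TRUE)
    g <- runif(ncol) < gap_p
    r[g] <- "-"
    rows[i] <- paste(r, collapse = "")
  }
  setNames(rows, paste0("s", 1:nrow))
}

# Random additive distance matrix from a random tree, plus the tree.
random_additive <- function(nleaf) {
  tr <- ape::rtree(nleaf)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

make_records <- function(seqs, ids = NULL) {
  ids <- ids %||% paste0("r", seq_along(seqs))
  tibble::tibble(id = ids, description = "", sequence = unname(seqs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
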