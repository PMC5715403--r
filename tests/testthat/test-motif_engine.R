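test_that("pattern grammar parses literals, wildcards and counts", {
  p <- parse_pattern("Cx3Cx2C")
  expect_equal(p$span, 8)
  expect_equal(p$mask, c("C", NA, NA, NA, "C", NA, NA, "C"))
  expect_equal(parse_pattern("HPC")$span, 3)
  expect_equal(parse_pattern("HPC")$mask, c("H", "P", "C"))
  # multi-digit counts
  expect_equal(parse_pattern("Cx12C")$span, 14)
})

test_that("pattern grammar rejects malformed input", {
  expect_error(parse_pattern("Cx0C"), "pattern syntax error")
  expect_error(parse_pattern(""), "pattern syntax error")
  expect_error(parse_pattern("Cy2C"), "pattern syntax error")
  expect_error(parse_pattern("C2C"), "digit must follow")
  expect_error(parse_pattern("x3"), "at least one literal")
})

test_that("scanning finds exact and overlapping matches, none without anchors", {
  adomet <- parse_pattern("Cx3Cx2C")
  hit <- scan_motif("CAAACAAC", adomet)
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(1L, 8L))
  expect_equal(hit$matched, "CAAACAAC")
  expect_equal(nrow(scan_motif("AAAA", adomet)), 0)
  # sequence shorter than pattern span: empty, not an error
  expect_equal(nrow(scan_motif("CA", adomet)), 0)
  # overlapping occurrences are all reported
  cc <- parse_pattern("CC")
  expect_equal(scan_motif("CCCC", cc)$start, 1:3)
})

test_that("X matches wildcards but never literals", {
  p <- parse_pattern("CxC")
  expect_equal(scan_motif("CXC", p)$start, 1L)
  expect_equal(nrow(scan_motif("XAC", p)), 0)
  expect_equal(nrow(scan_motif("CAX", p)), 0)
})

test_that("scanner agrees with the exhaustive-offset oracle", {
  set.seed(202)
  for (i in 1:300) {
    text <- random_pattern_text()
    s <- random_seq(sample(20:200, 1))
    expect_equal(scan_motif(s, parse_pattern(text))$start,
                 oracle_scan(s, text),
                 info = paste(text, s))
  }
})

test_that("fingerprint matching places all six motifs on a constructed NifB", {
  fp <- nifb_fingerprint()
  spacer <- paste(rep("A", 10), collapse = "")
  set.seed(7)
  seq <- paste(vapply(fp, function(p) {
    m <- p$mask
    m[is.na(m)] <- sample(setdiff(AA, "C"), sum(is.na(m)), replace = TRUE)
    paste(m, collapse = "")
  }, character(1)), collapse = spacer)
  res <- match_fingerprint(seq, fp)
  expect_true(res$passed)
  expect_equal(nrow(res$hits), 6)
  expect_equal(res$hits$pattern_name, names(fp))
  # hits strictly ordered and non-overlapping
  expect_true(all(diff(res$hits$start) > 0))
  expect_true(all(res$hits$start[-1] > res$hits$end[-6]))
  expect_length(res$missing, 0)

  # ablating the AdoMet motif leaves exactly that motif missing
  hit2 <- res$hits[res$hits$pattern_name == "Cx3Cx2C", ]
  seq2 <- seq
  substr(seq2, hit2$start, hit2$end) <- paste(rep("A", 8), collapse = "")
  res2 <- match_fingerprint(seq2, fp)
  expect_false(res2$passed)
  expect_equal(res2$missing, "Cx3Cx2C")

  # a bare residue misses everything
  res3 <- match_fingerprint("A", fp)
  expect_false(res3$passed)
  expect_equal(res3$missing, names(fp))
})

test_that("unordered mode only requires presence", {
  fp <- fingerprint(list(parse_pattern("DEF"), parse_pattern("ACA")))
  # motifs present but in the wrong order
  seq <- "ACAAADEFAA"
  expect_true(match_fingerprint(seq, fp, ordered = FALSE)$passed)
  rev_seq <- "DEFAAACAAA"
  expect_true(match_fingerprint(rev_seq, fp, ordered = FALSE)$passed)
  expect_true(match_fingerprint(rev_seq, fp)$passed)
  expect_false(match_fingerprint(seq, fp)$passed)
})

test_that("removing a pattern never shrinks the passing set", {
  set.seed(303)
  fp <- nifb_fingerprint()
  seqs <- vapply(rep(150, 60), random_seq, character(1))
  # salt some sequences with real motif instances so both outcomes occur
  seqs[1:20] <- paste0("HPCAA", seqs[1:20], "AAAGPG")
  full <- vapply(seqs, function(s) match_fingerprint(s, fp)$passed, logical(1))
  for (drop in seq_along(fp)) {
    sub <- fingerprint(fp[-drop])
    reduced <- vapply(seqs, function(s) match_fingerprint(s, sub)$passed,
                      logical(1))
    expect_true(all(reduced >= full))
  }
})

test_that("motif discovery reads conserved blocks off an alignment", {
  al <- setNames(rep("HPCAAA", 3), c("a", "b", "c"))
  pats <- discover_fingerprint(al, min_conservation = 1, min_motif_len = 3)
  expect_length(pats, 1)
  expect_equal(pats[[1]]$text, "HPCAAA")

  al2 <- setNames(c("HPCA", "HPCG", "HPCT"), c("a", "b", "c"))
  pats2 <- discover_fingerprint(al2, min_conservation = 1)
  expect_length(pats2, 1)
  expect_equal(pats2[[1]]$text, "HPC")

  expect_error(discover_fingerprint(setNames("HPC", "a")),
               "insufficient sequences")
  expect_error(discover_fingerprint(setNames(c("HPC", "HP"), c("a", "b"))),
               "not an alignment")
})

test_that("discovery matches an independent column-tally oracle", {
  # Oracle: classify columns, break at gaps and long wildcard runs, trim to
  # literals, require enough literals -- computed with explicit loops.
  oracle_discover <- function(seqs, min_cons, min_len, max_wild) {
    m <- do.call(rbind, strsplit(unname(seqs), ""))
    nc <- ncol(m)
    cls <- character(nc); modal <- character(nc)
    for (j in 1:nc) {
      col <- m[, j]
      if (any(col == "-")) { cls[j] <- "gap"; next }
      tab <- table(col)
      modal[j] <- names(tab)[which.max(tab)]
      cls[j] <- if (max(tab) / length(col) >= min_cons) "lit" else "wild"
    }
    brk <- cls == "gap"
    run <- 0
    for (j in 1:nc) {
      run <- if (cls[j] == "wild") run + 1 else 0
      if (run == max_wild + 1) brk[(j - max_wild):j] <- TRUE
      else if (run > max_wild + 1) brk[j] <- TRUE
    }
    texts <- character(0)
    j <- 1
    while (j <= nc) {
      if (brk[j]) { j <- j + 1; next }
      k <- j
      while (k < nc && !brk[k + 1]) k <- k + 1
      seg <- j:k
      lits <- seg[cls[seg] == "lit"]
      if (length(lits) >= min_len) {
        seg <- seg[seg >= min(lits) & seg <= max(lits)]
        txt <- ""
        q <- 1
        while (q <= length(seg)) {
          if (cls[seg[q]] == "lit") { txt <- paste0(txt, modal[seg[q]]); q <- q + 1 }
          else {
            w <- 0
            while (q <= length(seg) && cls[seg[q]] == "wild") { w <- w + 1; q <- q + 1 }
            txt <- paste0(txt, if (w == 1) "x" else paste0("x", w))
          }
        }
        texts <- c(texts, txt)
      }
      j <- k + 1
    }
    texts
  }
  set.seed(404)
  for (i in 1:60) {
    al <- random_alignment(nrow = sample(3:8, 1), ncol = sample(30:80, 1),
                           gap_p = 0.03)
    got <- vapply(discover_fingerprint(al, min_conservation = 0.8,
                                       min_motif_len = 2,
                                       max_wildcard_run = 3),
                  `[[`, character(1), "text")
    expect_equal(unname(got),
                 oracle_discover(al, 0.8, 2, 3), info = paste("case", i))
  }
})

test_that("discovery on the generator's noise-free set recovers the fingerprint", {
  cfg <- synthetic_config(seed = 11, spacer_length_range = c(10L, 10L))
  set.seed(11)
  recs <- dplyr::bind_rows(lapply(1:8, function(i) {
    generate_nifb_record(cfg, "SINGLE", id = paste0("r", i))$record
  }))
  # fixed spacers make the noise-free records a ready-made alignment
  expect_length(unique(nchar(recs$sequence)), 1)
  pats <- discover_fingerprint(setNames(recs$sequence, recs$id),
                               min_conservation = 1)
  expect_equal(vapply(pats, `[[`, character(1), "text"),
               vapply(nifb_fingerprint(), `[[`, character(1), "text"),
               ignore_attr = TRUE)
})
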