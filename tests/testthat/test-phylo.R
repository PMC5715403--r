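test_that("progressive alignment handles identical and near-identical input", {
  rec2 <- make_records(c("MKVLHP", "MKVLHP"))
  al <- align_progressive(rec2)
  expect_equal(unname(al), c("MKVLHP", "MKVLHP"))
  # one insertion: a single gap opens in the shorter row
  al2 <- align_progressive(make_records(c("HPC", "HAPC")))
  expect_equal(unname(nchar(al2)), c(4L, 4L))
  expect_equal(unname(al2), c("H-PC", "HAPC"))
  al3 <- align_progressive(make_records(rep("MKVLHP", 3)))
  expect_true(all(al3 == "MKVLHP"))
  expect_error(align_progressive(make_records("MKV")), "nothing to align")
})

test_that("ungapping aligned rows recovers the input sequences", {
  set.seed(51)
  for (i in 1:5) {
    n <- sample(3:6, 1)
    base <- random_seq(60)
    seqs <- vapply(1:n, function(j) {
      s <- strsplit(base, "")[[1]]
      drop <- sample(60, sample(0:5, 1))
      if (length(drop)) s <- s[-drop]
      mut <- sample(length(s), 3)
      s[mut] <- sample(AA, 3, replace = TRUE)
      paste(s, collapse = "")
    }, character(1))
    rec <- make_records(seqs)
    al <- align_progressive(rec)
    expect_equal(names(al), rec$id)
    expect_length(unique(nchar(al)), 1)
    expect_equal(unname(gsub("-", "", al)), rec$sequence)
  }
})

test_that("block selection keeps conserved runs and splits at gap columns", {
  full <- setNames(rep(strrep("A", 50), 4), paste0("s", 1:4))
  b <- select_blocks(full)
  expect_equal(b$intervals$start, 1L)
  expect_equal(b$intervals$end, 50L)
  expect_equal(b$total_length, 50L)
  gapped <- full
  substr(gapped[1], 25, 25) <- "-"
  b2 <- select_blocks(gapped)
  expect_equal(b2$intervals$start, c(1L, 26L))
  expect_equal(b2$intervals$end, c(24L, 50L))
  # alignment shorter than the minimum block: empty set, no error
  tiny <- setNames(rep("AAAA", 3), paste0("s", 1:3))
  expect_equal(nrow(select_blocks(tiny)$intervals), 0)
})

test_that("block selection matches the rule-application oracle", {
  set.seed(52)
  for (i in 1:80) {
    al <- random_alignment(nrow = sample(4:8, 1), ncol = sample(20:90, 1))
    got <- select_blocks(al)$intervals
    want <- oracle_blocks(al)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$end, want$end, info = paste("case", i))
  }
})

test_that("block selection is invariant to row order", {
  set.seed(53)
  al <- random_alignment(nrow = 6, ncol = 70)
  perm <- sample(length(al))
  expect_equal(select_blocks(al)$intervals,
               select_blocks(al[perm])$intervals)
})

test_that("block extraction concatenates retained columns", {
  al <- setNames(c("ABCDEFGHIKLM", "MLKIHGFEDCBA"), c("x", "y"))
  al <- gsub("B", "N", al)  # keep to canonical letters
  full <- extract_blocks(al, tibble::tibble(start = 1L, end = 12L))
  expect_equal(unname(full), unname(al))
  none <- extract_blocks(al, tibble::tibble(start = integer(),
                                            end = integer()))
  expect_equal(unname(none), c("", ""))
  some <- extract_blocks(al, tibble::tibble(start = c(1L, 10L),
                                            end = c(3L, 12L)))
  expect_equal(unname(some)[1], paste0(substr(al[1], 1, 3),
                                       substr(al[1], 10, 12)))
  expect_error(extract_blocks(al, tibble::tibble(start = 1L, end = 13L)),
               "block out of range")
})

test_that("p-distances count mismatches over comparable columns", {
  expect_equal(pdistance(setNames(c("MKVL", "MKVL"), c("a", "b")))["a", "b"], 0)
  d <- pdistance(setNames(c("AAAA", "AAAT"), c("a", "b")), correction = "NONE")
  expect_equal(d["a", "b"], 0.25)
  dp <- pdistance(setNames(c("AAAA", "AAAT"), c("a", "b")))
  expect_equal(dp["a", "b"], -log(0.75))
  expect_equal(round(dp["a", "b"], 4), 0.2877)
  # pairwise deletion: gapped columns dropped per pair
  dg <- pdistance(setNames(c("A-AT", "AAAA"), c("a", "b")), "NONE")
  expect_equal(dg["a", "b"], 1 / 3)
  expect_error(pdistance(setNames(c("A---", "-AAA"), c("a", "b"))),
               "incomparable pair.*a.*b")
  expect_error(pdistance(setNames(c("AAAA", "TTTT"), c("a", "b"))),
               "saturated distance")
})

test_that("p-distance is permutation-equivariant", {
  set.seed(54)
  al <- random_alignment(nrow = 5, ncol = 40, gap_p = 0.02)
  d <- pdistance(al, "NONE")
  perm <- sample(5)
  dp <- pdistance(al[perm], "NONE")
  expect_equal(dp, d[names(al)[perm], names(al)[perm]])
})

test_that("neighbor joining reproduces closed forms on 2 and 3 taxa", {
  dm2 <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(dm2)
  expect_equal(sum(t2$edge.length), 0.6)
  labs <- c("a", "b", "c")
  dm3 <- matrix(c(0, .3, .5, .3, 0, .4, .5, .4, 0), 3, 3,
                dimnames = list(labs, labs))
  t3 <- nj_tree(dm3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], (.3 + .5 - .4) / 2, tolerance = 1e-12)
  expect_equal(len[["b"]], (.3 + .4 - .5) / 2, tolerance = 1e-12)
  expect_equal(len[["c"]], (.5 + .4 - .3) / 2, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2,
                              dimnames = list(c("a", "b"), c("a", "b")))),
               "invalid distance matrix")
})

test_that("neighbor joining recovers generating topologies from additive matrices", {
  set.seed(55)
  for (i in 1:25) {
    sim <- random_additive(sample(4:10, 1))
    est <- nj_tree(sim$dm)
    expect_equal(rf_distance(est, sim$tree), 0, info = paste("case", i))
    # recovered branch lengths reproduce the additive distances
    expect_equal(ape::cophenetic.phylo(est)[rownames(sim$dm), colnames(sim$dm)],
                 sim$dm, tolerance = 1e-9)
  }
})

test_that("neighbor joining is deterministic and agrees with an independent NJ", {
  set.seed(56)
  sim <- random_additive(8)
  expect_identical(write_newick(nj_tree(sim$dm)),
                   write_newick(nj_tree(sim$dm)))
  for (i in 1:5) {
    n <- sample(5:9, 1)
    d <- as.matrix(stats::dist(matrix(runif(n * 4), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_equal(rf_distance(nj_tree(d), ape::nj(d)), 0)
  }
})

test_that("outgroup rooting splits the outgroup branch at its midpoint", {
  t4 <- parse_newick("((A:1,B:1):1,(C:2,D:1):1);")
  rt <- root_tree(t4, "A")
  expect_true(ape::is.rooted(rt))
  root <- ape::Ntip(rt) + 1L
  kids <- rt$edge[rt$edge[, 1] == root, 2]
  a <- which(rt$tip.label == "A")
  expect_true(a %in% kids)
  # A's pendant edge of length 1 is halved on both sides of the root
  expect_equal(rt$edge.length[rt$edge[, 2] == a], 0.5)
  expect_equal(rt$edge.length[rt$edge[, 1] == root & rt$edge[, 2] != a], 0.5)
  expect_error(root_tree(t4, "Z"), "outgroup not found")
  # rooting, unrooting and re-rooting is stable
  rt2 <- root_tree(ape::unroot(rt), "A")
  expect_equal(rf_distance(rt, rt2), 0)
  expect_equal(sort(rt2$edge.length), sort(rt$edge.length))
})

test_that("newick round trips preserve topology and branch lengths", {
  t <- parse_newick("(A:1,B:2);")
  expect_equal(sort(t$tip.label), c("A", "B"))
  expect_equal(sort(t$edge.length), c(1, 2))
  set.seed(57)
  for (i in 1:10) {
    tr <- ape::rtree(10)
    back <- parse_newick(write_newick(tr))
    expect_equal(rf_distance(tr, back), 0)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
  expect_error(parse_newick("((A,B);"), "malformed newick")
  expect_error(parse_newick("(A:1,A:2);"), "malformed newick")
})

test_that("Robinson-Foulds distance counts discordant bipartitions", {
  q1 <- parse_newick("((A,B),(C,D));")
  q2 <- parse_newick("((A,C),(B,D));")
  star <- parse_newick("(A,B,C,D);")
  expect_equal(rf_distance(q1, q1), 0)
  expect_equal(rf_distance(q1, q2), 2)
  expect_equal(rf_distance(star, q1), 1)
  expect_error(rf_distance(q1, parse_newick("((A,B),(C,E));")),
               "leaf set mismatch")
})

test_that("tree annotation pairs every leaf with an architecture call", {
  t4 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  calls <- tibble::tibble(record_id = c("A", "B", "C", "D"),
                          label = c("SINGLE", "TWO_DOMAIN", "TWO_DOMAIN",
                                    "THREE_DOMAIN"))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- annotate_tree(t4, calls, path)
  expect_equal(nrow(out$annotation), 4)
  expect_equal(out$annotation$architecture[out$annotation$leaf == "D"],
               "THREE_DOMAIN")
  expect_equal(out$newick, write_newick(t4))   # labels unchanged
  side <- utils::read.delim(path)
  expect_equal(nrow(side), 4)
  expect_error(annotate_tree(t4, calls[1:3, ]), "unannotated leaf: D")
  expect_error(annotate_tree(t4, calls[0, ]), "unannotated leaf: A, B, C, D")
})
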