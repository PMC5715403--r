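# Distance phylogenetics: p-distances, neighbor joining, outgroup rooting,
# Newick exchange, and Robinson-Foulds comparison.
#
# Trees are `ape::phylo` objects throughout. The NJ estimator is implemented
# here with explicit determinism rules (lexicographic tie-breaks, negative
# branch lengths clamped to zero) so runs are bit-reproducible; it is exact
# on additive distance matrices.

#' Pairwise distances from a protein alignment
#'
#' Pairwise deletion: for each pair, only columns where both rows are gap-free
#' are compared. `p` is the mismatch fraction; the Poisson correction maps it
#' to an expected number of substitutions per site, `d = -ln(1 - p)`.
#'
#' @param alignment Named character vector or record tibble of equal-length
#'   aligned sequences.
#' @param correction `"POISSON"` (default) or `"NONE"`.
#' @return Symmetric numeric matrix with zero diagonal, labelled by row ids.
#' @export
pdistance <- function(alignment, correction = c("POISSON", "NONE")) {
  correction <- match.arg(correction)
  seqs <- alignment_seqs(alignment)
  if (length(seqs) < 2) stop("need >= 2 rows")
  if (length(unique(nchar(seqs))) != 1) stop("not an alignment: ragged rows")
  ids <- names(seqs)
  m <- seq_matrix(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(comp)) stop("incomparable pair: ", ids[i], ", ", ids[j])
      p <- mean(m[i, comp] != m[j, comp])
      if (correction == "POISSON") {
        if (p >= 1) stop("saturated distance: ", ids[i], ", ", ids[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative NJ with the rate-corrected join criterion
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`. Deterministic: among tied minimal
#' pairs the one whose sorted pair of cluster labels (a cluster is labelled
#' by its lexicographically smallest leaf) is smallest is joined; negative
#' estimated branch lengths are clamped to zero.
#'
#' @param dm Symmetric numeric matrix with labelled dimnames (or `dist`).
#' @return Unrooted `ape::phylo` tree (for two taxa, the single edge is
#'   represented as two half-length pendant edges).
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || !is.numeric(dm) || nrow(dm) != ncol(dm) ||
      max(abs(dm - t(dm))) > 1e-8 || any(abs(diag(dm)) > 1e-12)) {
    stop("invalid distance matrix")
  }
  labs <- rownames(dm)
  if (is.null(labs) || anyDuplicated(labs)) stop("invalid distance matrix")
  if (any(grepl("[(),:;]", labs))) stop("invalid taxon label")
  n <- nrow(dm)
  if (n < 2) stop("need >= 2 taxa")
  frag <- labs      # newick fragment per active cluster
  key <- labs       # smallest member leaf label, for tie-breaking
  d <- dm
  while (length(frag) > 3) {
    nn <- length(frag)
    r <- rowSums(d)
    best <- NULL
    for (a in seq_len(nn - 1)) {
      for (b in (a + 1):nn) {
        q <- (nn - 2) * d[a, b] - r[a] - r[b]
        ka <- sort(c(key[a], key[b]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (ka[1] < best$key[1] ||
              (ka[1] == best$key[1] && ka[2] < best$key[2])))) {
          best <- list(a = a, b = b, q = q, key = ka)
        }
      }
    }
    a <- best$a; b <- best$b
    va <- d[a, b] / 2 + (r[a] - r[b]) / (2 * (nn - 2))
    vb <- d[a, b] - va
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)",
                       frag[a], max(0, va), frag[b], max(0, vb))
    others <- setdiff(seq_len(nn), c(a, b))
    newd <- (d[a, others] + d[b, others] - d[a, b]) / 2
    d2 <- rbind(cbind(d[others, others, drop = FALSE], newd),
                c(newd, 0))
    frag <- c(frag[others], newfrag)
    key <- c(key[others], min(key[a], key[b]))
    d <- d2
  }
  newick <- if (length(frag) == 2) {
    sprintf("(%s:%.12g,%s:%.12g);", frag[1], max(0, d[1, 2] / 2),
            frag[2], max(0, d[1, 2] / 2))
  } else {
    va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
            frag[1], max(0, va), frag[2], max(0, vb), frag[3], max(0, vc))
  }
  ape::read.tree(text = newick)
}

#' Root a tree on an outgroup leaf
#'
#' Places the root at the midpoint of the branch leading to the outgroup
#' leaf, so the outgroup is one child of the root and the rest of the tree
#' the other.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup_label Leaf label to root on.
#' @return Rooted `ape::phylo` tree.
#' @export
root_tree <- function(tree, outgroup_label) {
  stopifnot(inherits(tree, "phylo"))
  if (!outgroup_label %in% tree$tip.label) {
    stop("outgroup not found: ", outgroup_label)
  }
  t <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2) {
    ape::unroot(tree)
  } else {
    tree
  }
  tip <- which(t$tip.label == outgroup_label)
  e <- which(t$edge[, 2] == tip)
  len <- t$edge.length[e]
  phytools::reroot(t, tip, position = len / 2)
}

#' Serialize a tree to a Newick string
#' @param tree An `ape::phylo` tree.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Parse a Newick string
#'
#' @param text Newick string.
#' @return An `ape::phylo` tree. Unbalanced parentheses or duplicate leaf
#'   labels raise a "malformed newick" error.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(
    withCallingHandlers(
      ape::read.tree(text = text),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) stop("malformed newick")
  if (anyDuplicated(tree$tip.label)) {
    stop("malformed newick: duplicate leaf labels")
  }
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' (unrooted) trees. Polytomies are allowed.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label)) stop("leaf set mismatch")
  u1 <- if (ape::is.rooted(t1)) ape::unroot(t1) else t1
  u2 <- if (ape::is.rooted(t2)) ape::unroot(t2) else t2
  as.integer(phangorn::RF.dist(u1, u2, check.labels = TRUE))
}

#' Annotate tree leaves with architecture calls
#'
#' Emits the tree's Newick string (leaf labels unchanged) plus a sidecar
#' table pairing each leaf with its architecture label -- the overlay used to
#' read architecture evolution off the phylogeny.
#'
#' @param tree An `ape::phylo` tree.
#' @param calls Tibble with `record_id` and `label` covering every leaf.
#' @param path Optional path; when given, the sidecar is written as TSV.
#' @return List with `newick` (string) and `annotation` (tibble `leaf`,
#'   `architecture` in tree tip order).
#' @export
annotate_tree <- function(tree, calls, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  idx <- match(tree$tip.label, calls$record_id)
  if (anyNA(idx)) {
    stop("unannotated leaf: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  annotation <- tibble::tibble(leaf = tree$tip.label,
                               architecture = calls$label[idx])
  if (!is.null(path)) {
    utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(newick = write_newick(tree), annotation = annotation)
}
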