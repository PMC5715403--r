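# Progressive multiple alignment.
#
# A deliberately small progressive aligner: a guide order from shared k-mer
# distances, then profile-profile Needleman-Wunsch merges with sum-of-pairs
# BLOSUM62 column scores and a linear gap penalty. It exists so the block
# selection and tree stages can be exercised end-to-end without external
# aligners; externally produced alignments can always be ingested with
# `read_fasta(..., gaps = TRUE)`.

#' Progressive multiple sequence alignment
#'
#' @param records Record tibble (>= 2 rows).
#' @param gap Linear gap penalty per column (negative; default -8).
#' @param kmer k-mer size for guide distances (default 3).
#' @return Named character vector of aligned sequences (gap `-`), in input
#'   order, all of equal length; ungapping any row recovers its input
#'   sequence.
#' @export
align_progressive <- function(records, gap = -8, kmer = 3L) {
  if (is.null(records) || nrow(records) < 2) stop("nothing to align")
  n <- nrow(records)
  seqs <- records$sequence
  ids <- records$id
  d <- kmer_distances(seqs, kmer)
  # Agglomerate by average linkage; ties broken on the lexicographically
  # smallest (then second-smallest) member-label pair, so the merge order --
  # and hence the alignment -- is deterministic.
  profiles <- lapply(seqs, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  members <- as.list(seq_len(n))
  keys <- ids
  active <- rep(TRUE, n)
  while (sum(active) > 1) {
    idx <- which(active)
    best <- NULL
    for (a in idx) for (b in idx) {
      if (a >= b) next
      ka <- sort(c(keys[a], keys[b]))
      if (is.null(best) || d[a, b] < best$d - 1e-12 ||
          (abs(d[a, b] - best$d) <= 1e-12 &&
           (ka[1] < best$key[1] ||
            (ka[1] == best$key[1] && ka[2] < best$key[2])))) {
        best <- list(a = a, b = b, d = d[a, b], key = ka)
      }
    }
    a <- best$a; b <- best$b
    merged <- align_profiles(profiles[[a]], profiles[[b]], gap)
    profiles[[a]] <- merged
    na <- length(members[[a]]); nb <- length(members[[b]])
    for (j in which(active)) {
      if (j == a || j == b) next
      d[a, j] <- d[j, a] <- (na * d[a, j] + nb * d[b, j]) / (na + nb)
    }
    members[[a]] <- c(members[[a]], members[[b]])
    keys[a] <- min(keys[a], keys[b])
    active[b] <- FALSE
  }
  root <- which(active)
  prof <- profiles[[root]]
  ord <- order(members[[root]])
  out <- apply(prof[ord, , drop = FALSE], 1, paste, collapse = "")
  stats::setNames(out, ids)
}

kmer_distances <- function(seqs, k) {
  sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - shared / min(length(sets[[i]]), length(sets[[j]]))
  }
  d
}

# Needleman-Wunsch on two profiles (character matrices, rows = sequences).
# Column score = mean pairwise BLOSUM62 over residue pairs (gap pairs score
# 0); aligning a column against a gap costs `gap`. Traceback preference:
# diagonal, then up (gap in B), then left (gap in A).
align_profiles <- function(pa, pb, gap) {
  sub <- blosum62()
  la <- ncol(pa); lb <- ncol(pb)
  S <- matrix(0, la, lb)
  for (i in seq_len(la)) {
    ca <- pa[, i]
    ca <- ca[ca != "-"]
    for (j in seq_len(lb)) {
      cb <- pb[, j]
      cb <- cb[cb != "-"]
      if (length(ca) && length(cb)) {
        S[i, j] <- mean(sub[ca, cb, drop = FALSE])
      }
    }
  }
  M <- matrix(-Inf, la + 1, lb + 1)
  M[1, ] <- gap * (0:lb)
  M[, 1] <- gap * (0:la)
  tb <- matrix(0L, la + 1, lb + 1)  # 1 diag, 2 up, 3 left
  tb[1, -1] <- 3L; tb[-1, 1] <- 2L
  for (i in 2:(la + 1)) {
    for (j in 2:(lb + 1)) {
      cand <- c(M[i - 1, j - 1] + S[i - 1, j - 1],
                M[i - 1, j] + gap,
                M[i, j - 1] + gap)
      w <- which.max(cand)   # ties -> lowest index (diag first)
      M[i, j] <- cand[w]
      tb[i, j] <- w
    }
  }
  # traceback
  i <- la + 1; j <- lb + 1
  cols <- list()
  gapa <- rep("-", nrow(pa)); gapb <- rep("-", nrow(pb))
  while (i > 1 || j > 1) {
    mv <- tb[i, j]
    if (mv == 1L) {
      cols[[length(cols) + 1L]] <- c(pa[, i - 1], pb[, j - 1])
      i <- i - 1; j <- j - 1
    } else if (mv == 2L) {
      cols[[length(cols) + 1L]] <- c(pa[, i - 1], gapb)
      i <- i - 1
    } else {
      cols[[length(cols) + 1L]] <- c(gapa, pb[, j - 1])
      j <- j - 1
    }
  }
  do.call(cbind, rev(cols))
}
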