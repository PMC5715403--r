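# Internal helpers shared across modules.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue alphabet accepted on read: 20 canonical letters plus X (unknown).
AA_ALPHABET <- c(AA20, "X")

#' Round half away from zero to integer percentages
#'
#' Base `round()` rounds half to even; frequency tables here mirror the usual
#' presentation of percentages, where 0.5 rounds up.
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Largest-remainder apportionment of n among proportions
#'
#' Deterministically converts a proportion vector into integer counts summing
#' to `n`: floors are assigned first, then the remaining units go to the
#' largest fractional remainders (ties broken by position).
#' @keywords internal
#' @noRd
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-8) stop("invalid proportions: must sum to 1")
  raw <- n * p
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(left)]] <- k[ord[seq_len(left)]] + 1
  }
  as.integer(k)
}

# Split sequence strings into a character matrix (rows = sequences).
seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
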