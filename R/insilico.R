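# Small deterministic sequence computations: theoretical protein mass,
# primer-defined in-silico PCR (used to reproduce the NifX-like-domain
# truncation arithmetic: a 1404-nt full-length CDS gives 468 aa, the 1008-bp
# truncated coding region 336 aa), translation, and exponential growth-rate
# constants.

# Average residue masses (Da), i.e. amino-acid masses minus one water.
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Theoretical average molecular mass of a protein
#'
#' Sum of standard average residue masses plus one water. Average (not
#' monoisotopic) masses are used, matching how a theoretical mass is compared
#' with gel-filtration estimates.
#'
#' @param sequence Protein sequence over the 20 canonical letters (no `X`).
#' @return Mass in Da.
#' @examples
#' average_mass("G")  # 75.07
#' @export
average_mass <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    stop("mass undefined: empty sequence")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(chars %in% names(RESIDUE_MASS))) {
    stop("mass undefined: sequence contains non-canonical residues")
  }
  sum(RESIDUE_MASS[chars]) + WATER_MASS
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

count_matches <- function(template, site) {
  # overlapping fixed-string occurrences
  starts <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(site, substring(template, from), fixed = TRUE)
    if (hit == -1) break
    starts <- c(starts, from + as.integer(hit) - 1L)
    from <- from + as.integer(hit)
  }
  starts
}

#' In-silico PCR on a linear template
#'
#' The 3'-terminal `anneal_len` bases of the forward primer must occur
#' exactly once on the template plus strand, and likewise the reverse
#' complement of the reverse primer's 3'-terminal bases. Annealing is then
#' extended 5'-ward as far as the primer continues to match the template;
#' any remaining 5' extension is a tail, appended to the product as in PCR
#' but excluded from the template coordinates.
#'
#' @param template Plus-strand nucleotide string (A/C/G/T).
#' @param forward,reverse Primer sequences, 5' to 3' (the reverse primer
#'   anneals to the plus strand's complement).
#' @param anneal_len Exact-match seed length at the primer 3' end (>= 12;
#'   default 15).
#' @return An `amplicon`: list with `sequence` (product, tails included),
#'   `start`, `end` (1-based inclusive plus-strand coordinates of the
#'   annealed span) and `length` (`end - start + 1`, tails excluded).
#' @export
insilico_pcr <- function(template, forward, reverse, anneal_len = 15L) {
  stopifnot(anneal_len >= 12)
  for (x in c(template, forward, reverse)) {
    if (!is.character(x) || !nzchar(x) || grepl("[^ACGT]", x)) {
      stop("invalid nucleotide sequence")
    }
  }
  fw_site <- substring(forward, nchar(forward) - anneal_len + 1L)
  fw_hits <- count_matches(template, fw_site)
  if (length(fw_hits) != 1) stop("primer site not unique: forward")
  rv_site <- revcomp(substring(reverse, nchar(reverse) - anneal_len + 1L))
  rv_hits <- count_matches(template, rv_site)
  if (length(rv_hits) != 1) stop("primer site not unique: reverse")

  # extend forward annealing 5'-ward
  s <- fw_hits
  fw_extra <- nchar(forward) - anneal_len
  while (fw_extra > 0 && s > 1 &&
         substring(forward, fw_extra, fw_extra) ==
         substring(template, s - 1L, s - 1L)) {
    s <- s - 1L
    fw_extra <- fw_extra - 1L
  }
  fw_tail <- substring(forward, 1L, fw_extra)

  # extend reverse annealing 3'-ward on the plus strand
  e <- rv_hits + anneal_len - 1L
  rv_plus <- revcomp(reverse)   # reverse primer as plus-strand sequence
  rv_extra <- nchar(reverse) - anneal_len
  while (rv_extra > 0 && e < nchar(template) &&
         substring(rv_plus, nchar(rv_plus) - rv_extra + 1L,
                   nchar(rv_plus) - rv_extra + 1L) ==
         substring(template, e + 1L, e + 1L)) {
    e <- e + 1L
    rv_extra <- rv_extra - 1L
  }
  rv_tail_plus <- if (rv_extra > 0) {
    substring(rv_plus, nchar(rv_plus) - rv_extra + 1L)
  } else {
    ""
  }

  if (e <= s) stop("primer sites do not define a product")
  structure(list(
    sequence = paste0(fw_tail, substring(template, s, e), rv_tail_plus),
    start = as.integer(s), end = as.integer(e),
    length = as.integer(e - s + 1L)), class = "amplicon")
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds Nucleotide string, length divisible by 3, no internal stop
#'   codon; a trailing stop is removed.
#' @return Protein sequence string.
#' @examples
#' translate_cds("ATGGGT")  # "MG"
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (!nzchar(cds) || nchar(cds) %% 3 != 0) stop("incomplete codon")
  if (grepl("[^ACGT]", cds)) stop("invalid nucleotide sequence")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- Biostrings::GENETIC_CODE[codons]
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa))) {
    stop("premature stop at codon ", stops[stops < length(aa)][1])
  }
  if (length(stops)) aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Exponential growth rate constant from doubling time
#'
#' `rate = ln(2) / t_d`.
#'
#' @param t_d Doubling time in hours (> 0).
#' @return Growth rate constant per hour.
#' @export
growth_rate <- function(t_d) {
  if (!is.numeric(t_d) || any(t_d <= 0)) stop("invalid doubling time")
  log(2) / t_d
}

#' Synthetic CDS template for primer-defined truncation
#'
#' Builds a synthetic coding sequence (standard code, no internal stops) of
#' `cds_codons` codons together with a primer pair whose product coding
#' region covers the first `product_codons` codons -- the construction used
#' to exercise the C-terminal-domain truncation arithmetic (full-length 1404
#' nt / 468 aa versus a 1008-bp / 336-aa truncated product) without the real
#' accession sequence. The reverse primer carries a stop codon and restriction
#' tail, the forward primer a restriction tail, as is conventional.
#'
#' @param cds_codons Number of codons in the full CDS (default 468).
#' @param product_codons Codons retained in the truncated product (336).
#' @param anneal_len Primer annealing length (default 18).
#' @param seed RNG seed for the random codons.
#' @return List with `cds`, `forward`, `reverse`, `anneal_len`.
#' @export
synthetic_truncation_template <- function(cds_codons = 468L,
                                          product_codons = 336L,
                                          anneal_len = 18L, seed = 1L) {
  stopifnot(product_codons < cds_codons, anneal_len %% 3 == 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  repeat {
    cds <- paste0("ATG", paste(sample(sense, cds_codons - 1L, replace = TRUE),
                               collapse = ""))
    nt_product <- 3L * product_codons
    fw_site <- substring(cds, 1L, anneal_len)
    rv_site <- substring(cds, nt_product - anneal_len + 1L, nt_product)
    # primer seeds must be unique on the template for a clean product, and
    # the base after the truncation point must not extend the reverse
    # primer's stop-codon tail annealing
    if (length(count_matches(cds, fw_site)) == 1 &&
        length(count_matches(cds, rv_site)) == 1 &&
        substring(cds, nt_product + 1L, nt_product + 1L) != "T") break
  }
  list(cds = cds,
       forward = paste0("CCCCAT", fw_site),
       reverse = paste0("GGGCTCGAGTCA", revcomp(rv_site)),
       anneal_len = as.integer(anneal_len))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
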