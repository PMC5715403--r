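# Database curation: the fingerprint filter, the rejected-record post-mortem,
# and per-taxon architecture frequency tables.

#' Curate a candidate database with the motif fingerprint
#'
#' Scores every record with [match_fingerprint()]; records presenting all
#' fingerprint motifs are retained, the rest removed. In the published NifB
#' curation this step reduced 390 candidates to 289.
#'
#' @param records Record tibble.
#' @param fingerprint A `nifb_fingerprint` (default [nifb_fingerprint()]).
#' @return A `curation_report`: list with `n_input`, `n_retained`,
#'   `n_removed`, `reduction_fraction` (reported to full precision, rounded
#'   to 3 decimals on print), `per_record` (list of `fingerprint_result`s),
#'   `retained`/`removed` (record tibbles) and `removed_reclassified`
#'   (`NA` until [reclassify_rejected()] is run).
#' @export
curate <- function(records, fingerprint = nifb_fingerprint()) {
  if (is.null(records) || nrow(records) == 0) stop("empty dataset")
  per_record <- lapply(seq_len(nrow(records)), function(i) {
    match_fingerprint(records[i, ], fingerprint)
  })
  passed <- vapply(per_record, `[[`, logical(1), "passed")
  structure(list(
    n_input = nrow(records),
    n_retained = sum(passed),
    n_removed = sum(!passed),
    reduction_fraction = sum(!passed) / nrow(records),
    per_record = per_record,
    retained = records[passed, ],
    removed = records[!passed, ],
    removed_reclassified = NA_integer_
  ), class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf(
    "<curation_report> %d input, %d retained, %d removed (reduction %.3f)\n",
    x$n_input, x$n_retained, x$n_removed, x$reduction_fraction))
  if (!is.na(x$removed_reclassified)) {
    cat(sprintf("  removed records with a NifX-like domain: %d\n",
                x$removed_reclassified))
  }
  invisible(x)
}

#' Re-examine rejected records for a NifX-like domain
#'
#' Most candidates excluded by the fingerprint lack the AdoMet Cx3Cx2C motif
#' but carry a NifX domain: they are mis-annotated NifX proteins, not NifB.
#' This runs NifX-like homology detection over each removed record's full
#' length and counts the positives.
#'
#' @param report A `curation_report` from [curate()].
#' @param panel A [reference_panel()].
#' @return Integer count of removed records with a NifX-like detection
#'   (store it in `report$removed_reclassified`).
#' @export
reclassify_rejected <- function(report, panel = reference_panel()) {
  stopifnot(inherits(report, "curation_report"))
  removed <- report$removed
  if (nrow(removed) == 0) return(0L)
  hits <- vapply(seq_len(nrow(removed)), function(i) {
    !is.null(detect_homology_domain(removed[i, ], panel, "NIFX_LIKE"))
  }, logical(1))
  sum(hits)
}

#' Per-taxon architecture frequency table
#'
#' Counts and within-row integer percentages of the three NifB architectures
#' for each (superkingdom, group) pair. `NOT_NIFB` calls are excluded; calls
#' without a taxonomy entry are tallied in an `unassigned` row. Percentages
#' round half up, mirroring the usual presentation (so rows may total
#' 100 +/- 1).
#'
#' @param calls Tibble with `record_id` and `label` (e.g. from
#'   [classify_architectures()]).
#' @param taxonomy Taxonomy tibble (`record_id`, `superkingdom`, `group`).
#' @return Tibble with one row per taxon: counts `n_single`, `n_two_domain`,
#'   `n_three_domain`, `total`, and percentages `pct_single`,
#'   `pct_two_domain`, `pct_three_domain`.
#' @export
architecture_frequencies <- function(calls, taxonomy) {
  keep <- calls[calls$label != "NOT_NIFB",
                c("record_id", "label"), drop = FALSE]
  idx <- match(keep$record_id, taxonomy$record_id)
  keep$superkingdom <- ifelse(is.na(idx), "unassigned",
                              taxonomy$superkingdom[idx])
  keep$group <- ifelse(is.na(idx), "unassigned", taxonomy$group[idx])
  tab <- dplyr::summarise(
    dplyr::group_by(keep, .data$superkingdom, .data$group),
    n_single = sum(.data$label == "SINGLE"),
    n_two_domain = sum(.data$label == "TWO_DOMAIN"),
    n_three_domain = sum(.data$label == "THREE_DOMAIN"),
    .groups = "drop")
  tab$total <- tab$n_single + tab$n_two_domain + tab$n_three_domain
  tab$pct_single <- round_half_up(100 * tab$n_single / tab$total)
  tab$pct_two_domain <- round_half_up(100 * tab$n_two_domain / tab$total)
  tab$pct_three_domain <- round_half_up(100 * tab$n_three_domain / tab$total)
  tab
}

#' Write a curation report's per-record motif summary as TSV
#'
#' @param report A `curation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(report, path) {
  rows <- tibble::tibble(
    record_id = vapply(report$per_record, `[[`, character(1), "record_id"),
    passed = vapply(report$per_record, `[[`, logical(1), "passed"),
    missing_motifs = vapply(report$per_record, function(r) {
      paste(r$missing, collapse = ",")
    }, character(1)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
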