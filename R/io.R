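# FASTA and taxonomy I/O: the plumbing every pipeline stage relies on.
#
# Protein records travel as a tibble with columns `id`, `description`,
# `sequence`. Sequences are uppercase strings over the 20 canonical amino-acid
# letters plus 'X' (unknown residue); ambiguity codes (B, Z, J, U, O) are
# rejected on read because the motif scanner's semantics for them would be
# undefined. Alignments use the same container with '-' allowed.

#' Read protein sequences from a FASTA file
#'
#' Parses FASTA text into a validated protein record table. Sequences are
#' uppercased, trailing `*` stop markers are stripped, and record order is
#' preserved. The record id is the header token up to the first whitespace;
#' the remainder of the header line becomes the description.
#'
#' @param path Path to a FASTA file.
#' @param gaps Allow `-` gap characters (for aligned FASTA). Default `FALSE`.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a descr", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, gaps = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records in ", path)
  if (!hdr[1]) stop("malformed FASTA: sequence before first header in ", path)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- vapply(split(lines[!hdr], grp[!hdr]),
                     function(x) paste(x, collapse = ""), character(1))
  # headers with no sequence lines at all
  seqs <- character(length(headers))
  seqs[as.integer(names(sequence))] <- sequence
  seqs <- toupper(gsub("\\s", "", seqs))
  seqs <- sub("\\*+$", "", seqs)
  records <- tibble::tibble(id = id, description = description,
                            sequence = seqs)
  validate_records(records, gaps = gaps)
  records
}

#' @keywords internal
#' @noRd
validate_records <- function(records, gaps = FALSE) {
  if (nrow(records) == 0) stop("no records")
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop("duplicate identifier: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(records$id))) stop("empty identifier")
  if (any(!nzchar(records$sequence))) {
    stop("empty sequence for record: ",
         paste(records$id[!nzchar(records$sequence)], collapse = ", "))
  }
  allowed <- paste0(c(AA_ALPHABET, if (gaps) "-"), collapse = "")
  bad <- grepl(sprintf("[^%s]", allowed), records$sequence)
  if (any(bad)) {
    stop("invalid residue in record: ",
         paste(records$id[bad], collapse = ", "))
  }
  invisible(records)
}

#' Write protein records to a FASTA file
#'
#' Round-trip stable with [read_fasta()]: reading a written file reproduces
#' the record table exactly.
#'
#' @param records A record tibble (`id`, optional `description`, `sequence`).
#' @param path Output path.
#' @param wrap Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (is.null(records) || nrow(records) == 0) stop("nothing to write")
  stopifnot(wrap >= 1)
  desc <- if ("description" %in% names(records)) records$description else ""
  out <- unlist(lapply(seq_len(nrow(records)), function(i) {
    header <- paste0(">", records$id[i],
                     if (nzchar(desc[i])) paste0(" ", desc[i]) else "")
    s <- records$sequence[i]
    starts <- seq(1, nchar(s), by = wrap)
    c(header, substring(s, starts, pmin(starts + wrap - 1, nchar(s))))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated, header line `record_id`, `superkingdom`, `group`; UTF-8, no
#' quoting. The superkingdom is restricted to `Bacteria` and `Archaea` (the
#' only domains of life with known diazotrophs).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `record_id`, `superkingdom`, `group`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("record_id", "superkingdom", "group")
  if (!all(need %in% names(tab))) {
    stop("malformed taxonomy table: expected columns ",
         paste(need, collapse = ", "))
  }
  tab <- tibble::as_tibble(tab[, need])
  bad <- !tab$superkingdom %in% c("Bacteria", "Archaea")
  if (any(bad)) {
    stop("invalid superkingdom: ",
         paste(unique(tab$superkingdom[bad]), collapse = ", "))
  }
  tab
}

#' Write a taxonomy table
#' @param taxonomy Tibble as returned by [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join protein records to their taxonomy rows
#'
#' Never drops or duplicates a record: records without a taxonomy row are
#' returned in `unmapped`; taxonomy rows referencing no sequence are reported
#' in `orphans` (warning-level, not an error).
#'
#' @param records Protein record tibble.
#' @param taxonomy Taxonomy tibble.
#' @return A list with `mapping` (tibble keyed by `record_id`), `unmapped`
#'   (character vector of record ids lacking taxonomy) and `orphans`
#'   (taxonomy `record_id`s matching no sequence).
#' @export
join_taxonomy <- function(records, taxonomy) {
  hit <- records$id %in% taxonomy$record_id
  mapping <- taxonomy[match(records$id[hit], taxonomy$record_id), ]
  orphans <- setdiff(taxonomy$record_id, records$id)
  if (length(orphans)) {
    warning("taxonomy rows without matching sequence: ",
            paste(orphans, collapse = ", "))
  }
  list(mapping = mapping, unmapped = records$id[!hit], orphans = orphans)
}
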