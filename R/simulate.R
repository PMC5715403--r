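# Ground-truth synthetic protein-family generator.
#
# Emulates the statistical structure the pipeline assumes: sequences carrying
# the ordered six-motif SAM-radical core (wildcard positions and inter-motif
# spacers random), optional NifN-like (N-terminal) and NifX-like (C-terminal)
# homology domains copied from reference templates at a configurable
# identity, NifX-only contaminants lacking the AdoMet Cx3Cx2C motif, and
# per-taxon architecture proportions mirroring the published distribution.
# Every record is emitted together with its ground-truth label and planted
# coordinates, which are the acceptance surface for the classification
# stages.

#' Synthetic reference templates shipped with the package
#'
#' One NifX-like and one NifN-like template sequence, generated once and
#' versioned with the package. They are arbitrary fixed sequences with no
#' biological claim attached (the NifX-like template is screened to contain
#' no Cx3Cx2C occurrence); they serve as homology-domain sources for the
#' generator and as the default [reference_panel()].
#'
#' @return List with record tibbles `nifx` and `nifn`.
#' @export
synthetic_templates <- function() {
  nifx <- read_fasta(system.file("extdata", "synthetic_nifx_ref.fasta",
                                 package = "nifb", mustWork = TRUE))
  nifn <- read_fasta(system.file("extdata", "synthetic_nifn_ref.fasta",
                                 package = "nifb", mustWork = TRUE))
  list(nifx = nifx, nifn = nifn)
}

#' Default per-taxon group configuration
#'
#' Four taxa, 160 genuine NifB records: three bacterial groups dominated by
#' the two-domain architecture (with the Firmicutes carrying all three forms
#' at roughly 55/32/13) and an exclusively single-domain Euryarchaeota group,
#' echoing the published per-phylum distribution.
#'
#' @return Group tibble for [synthetic_config()].
#' @export
default_groups <- function() {
  tibble::tibble(
    superkingdom = c("Bacteria", "Bacteria", "Bacteria", "Archaea"),
    group = c("gamma-proteobacteria", "Firmicutes", "Cyanobacteria",
              "Euryarchaeota"),
    n = c(48L, 45L, 32L, 35L),
    p_single = c(0.08, 0.55, 0.03, 1.0),
    p_two_domain = c(0.90, 0.32, 0.97, 0.0),
    p_three_domain = c(0.02, 0.13, 0.00, 0.0))
}

#' Configuration for the synthetic dataset generator
#'
#' @param seed Integer RNG seed.
#' @param groups Tibble with columns `superkingdom`, `group`, `n`,
#'   `p_single`, `p_two_domain`, `p_three_domain` (per-group architecture
#'   proportions, each row summing to 1).
#' @param contaminant_fraction Fraction of the final dataset that is
#'   NifX-only contaminants, in [0, 1).
#' @param substitution_rate Per-residue substitution noise applied outside
#'   motif literal positions, in [0, 0.3).
#' @param spacer_length_range Integer `c(min, max)` residues between
#'   consecutive motifs (and for terminal flanks/linkers). The minimum must
#'   exceed the longest wildcard run a motif may contain, so that spacers
#'   never fuse two motifs during discovery.
#' @param domain_identity Identity of planted NifX/NifN copies to their
#'   templates, in (0.3, 1].
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, groups = default_groups(),
                             contaminant_fraction = 0.2,
                             substitution_rate = 0,
                             spacer_length_range = c(5L, 15L),
                             domain_identity = 0.8) {
  rowsum <- groups$p_single + groups$p_two_domain + groups$p_three_domain
  if (any(abs(rowsum - 1) > 1e-8)) stop("invalid proportions")
  stopifnot(contaminant_fraction >= 0, contaminant_fraction < 1,
            substitution_rate >= 0, substitution_rate < 0.3,
            length(spacer_length_range) == 2,
            spacer_length_range[1] >= 4,
            spacer_length_range[1] <= spacer_length_range[2],
            domain_identity > 0.3, domain_identity <= 1)
  structure(list(seed = as.integer(seed), groups = groups,
                 contaminant_fraction = contaminant_fraction,
                 substitution_rate = substitution_rate,
                 spacer_length_range = as.integer(spacer_length_range),
                 domain_identity = domain_identity,
                 fingerprint = nifb_fingerprint(),
                 templates = synthetic_templates()),
            class = "synthetic_config")
}

rand_spacer <- function(config) {
  rng <- config$spacer_length_range
  len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Copy a template sequence at the requested identity: a deterministic number
# of positions, chosen at random, are substituted with a different residue.
mutate_to_identity <- function(sequence, identity) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  k <- round((1 - identity) * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(orig) {
      sample(setdiff(AA20, orig), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

# Instantiate one motif pattern: literals fixed, wildcards drawn uniformly.
instantiate_motif <- function(pattern) {
  mask <- pattern$mask
  mask[is.na(mask)] <- sample(AA20, sum(is.na(mask)), replace = TRUE)
  paste(mask, collapse = "")
}

#' Generate one synthetic NifB record
#'
#' Assembles `[NifN-like + linker]? + flank + motif1 + spacer + ... + motif6
#' + flank + [linker + NifX-like]?` per the architecture label, then applies
#' substitution noise outside motif literal positions (so truth labels stay
#' exact). Uses the current RNG state; seed via [generate_dataset()] or
#' `set.seed()` for reproducibility.
#'
#' @param config A [synthetic_config()].
#' @param label `"SINGLE"`, `"TWO_DOMAIN"` or `"THREE_DOMAIN"`.
#' @param id Record identifier.
#' @param ablate Optional motif name to ablate (its literal positions are
#'   overwritten with `A` runs), producing a fingerprint-failing NifB-like
#'   decoy; re-sampled until the fingerprint indeed fails.
#' @return List with `record` (one-row tibble) and `truth` (one-row tibble:
#'   label, motif starts, domain spans).
#' @export
generate_nifb_record <- function(config, label, id = "syn", ablate = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            label %in% c("SINGLE", "TWO_DOMAIN", "THREE_DOMAIN"))
  fp <- config$fingerprint
  repeat {
    parts <- character(0)
    nifn_span <- c(NA_integer_, NA_integer_)
    nifx_span <- c(NA_integer_, NA_integer_)
    if (label == "THREE_DOMAIN") {
      nifn <- mutate_to_identity(config$templates$nifn$sequence[1],
                                 config$domain_identity)
      parts <- c(parts, nifn, rand_spacer(config))
      nifn_span <- c(1L, nchar(nifn))
    }
    core_start <- sum(nchar(parts)) + 1L
    motif_starts <- integer(length(fp))
    core <- rand_spacer(config)
    for (k in seq_along(fp)) {
      motif_starts[k] <- core_start + nchar(core)
      core <- paste0(core, instantiate_motif(fp[[k]]))
      if (k < length(fp)) core <- paste0(core, rand_spacer(config))
    }
    core <- paste0(core, rand_spacer(config))
    parts <- c(parts, core)
    if (label %in% c("TWO_DOMAIN", "THREE_DOMAIN")) {
      nifx <- mutate_to_identity(config$templates$nifx$sequence[1],
                                 config$domain_identity)
      nifx_span <- c(sum(nchar(parts)) + 1L,
                     sum(nchar(parts)) + nchar(nifx))
      parts <- c(parts, nifx)
    }
    seq <- paste(parts, collapse = "")
    spans <- vapply(fp, `[[`, integer(1), "span")
    literal_pos <- unlist(lapply(seq_along(fp), function(k) {
      (motif_starts[k]:(motif_starts[k] + spans[k] - 1L))[!is.na(fp[[k]]$mask)]
    }))
    if (!is.null(ablate)) {
      stopifnot(ablate %in% names(fp))
      k <- match(ablate, names(fp))
      abl_pos <- motif_starts[k]:(motif_starts[k] + spans[k] - 1L)
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      chars[abl_pos] <- "A"
      seq <- paste(chars, collapse = "")
      literal_pos <- setdiff(literal_pos, abl_pos)
    }
    if (config$substitution_rate > 0) {
      chars <- strsplit(seq, "", fixed = TRUE)[[1]]
      u <- stats::runif(length(chars))
      hit <- setdiff(which(u < config$substitution_rate), literal_pos)
      if (length(hit)) {
        chars[hit] <- vapply(chars[hit], function(orig) {
          sample(setdiff(AA20, orig), 1)
        }, character(1))
        seq <- paste(chars, collapse = "")
      }
    }
    ok <- match_fingerprint(seq, fp)$passed
    # ablated decoys must fail the fingerprint; intact records at zero noise
    # pass by construction (noisy records may legitimately fail)
    if (is.null(ablate) || !ok) break
  }
  sam_start <- min(motif_starts)
  sam_end <- max(motif_starts + spans - 1L)
  list(record = tibble::tibble(id = id, description = paste("synthetic", label),
                               sequence = seq),
       truth = tibble::tibble(
         record_id = id, label = if (is.null(ablate)) label else "ABLATED",
         motif_starts = paste(motif_starts, collapse = ","),
         sam_start = sam_start, sam_end = sam_end,
         nifn_start = nifn_span[1], nifn_end = nifn_span[2],
         nifx_start = nifx_span[1], nifx_end = nifx_span[2]))
}

#' Generate one NifX-only contaminant record
#'
#' A mutated copy of the NifX-like template with short random flanks and no
#' planted SAM-radical motifs; rejection-sampled until it fails the six-motif
#' fingerprint, emulating the mis-annotated NifX proteins that the curation
#' filter removes.
#'
#' @param config A [synthetic_config()].
#' @param id Record identifier.
#' @return List with `record` and `truth` (label `CONTAMINANT`).
#' @export
generate_contaminant <- function(config, id = "cont") {
  stopifnot(inherits(config, "synthetic_config"))
  repeat {
    body <- mutate_to_identity(config$templates$nifx$sequence[1],
                               config$domain_identity)
    seq <- paste0(rand_spacer(config), body, rand_spacer(config))
    if (!match_fingerprint(seq, config$fingerprint)$passed) break
  }
  list(record = tibble::tibble(id = id,
                               description = "synthetic CONTAMINANT",
                               sequence = seq),
       truth = tibble::tibble(
         record_id = id, label = "CONTAMINANT",
         motif_starts = "", sam_start = NA_integer_, sam_end = NA_integer_,
         nifn_start = NA_integer_, nifn_end = NA_integer_,
         nifx_start = NA_integer_, nifx_end = NA_integer_))
}

#' Generate a full ground-truth dataset
#'
#' Per-group architecture counts are fixed by largest-remainder rounding of
#' the configured proportions; contaminants are added so they make up
#' `contaminant_fraction` of the final dataset (rounded) and are assigned to
#' groups round-robin. Identical config and seed give byte-identical output
#' files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional directory; when given, writes `records.fasta`,
#'   `taxonomy.tsv` and `truth.tsv`.
#' @return List with tibbles `records`, `taxonomy`, `truth` and the `config`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  groups <- config$groups
  records <- list()
  truths <- list()
  tax <- list()
  for (g in seq_len(nrow(groups))) {
    counts <- largest_remainder(groups$n[g],
                                c(groups$p_single[g], groups$p_two_domain[g],
                                  groups$p_three_domain[g]))
    labels <- rep(c("SINGLE", "TWO_DOMAIN", "THREE_DOMAIN"), counts)
    slug <- tolower(gsub("[^A-Za-z]", "", groups$group[g]))
    for (i in seq_along(labels)) {
      id <- sprintf("%s_%03d", slug, i)
      out <- generate_nifb_record(config, labels[i], id = id)
      records[[length(records) + 1L]] <- out$record
      truths[[length(truths) + 1L]] <- out$truth
      tax[[length(tax) + 1L]] <- tibble::tibble(
        record_id = id, superkingdom = groups$superkingdom[g],
        group = groups$group[g])
    }
  }
  n_genuine <- length(records)
  f <- config$contaminant_fraction
  n_cont <- if (f > 0) as.integer(round(f / (1 - f) * n_genuine)) else 0L
  for (i in seq_len(n_cont)) {
    g <- ((i - 1L) %% nrow(groups)) + 1L
    slug <- tolower(gsub("[^A-Za-z]", "", groups$group[g]))
    id <- sprintf("%s_cont_%03d", slug, i)
    out <- generate_contaminant(config, id = id)
    records[[length(records) + 1L]] <- out$record
    truths[[length(truths) + 1L]] <- out$truth
    tax[[length(tax) + 1L]] <- tibble::tibble(
      record_id = id, superkingdom = groups$superkingdom[g],
      group = groups$group[g])
  }
  res <- list(records = dplyr::bind_rows(records),
              taxonomy = dplyr::bind_rows(tax),
              truth = dplyr::bind_rows(truths),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(res$records, file.path(out_dir, "records.fasta"))
    write_taxonomy(res$taxonomy, file.path(out_dir, "taxonomy.tsv"))
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
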