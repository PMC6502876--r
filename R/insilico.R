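# TestPrime-style in-silico PCR: locate degenerate primer binding sites on
# reference sequences under a mismatch model with a protected 3' zone, predict
# amplicons, and compute per-taxon-group coverage.
#
# Coordinates are 0-based half-open throughout. Only the forward strand of
# each reference record is scanned, with the forward primer as-is and the
# reverse primer as its reverse complement (reference rRNA records are stored
# 5'->3'). Ambiguity codes in the reference are matched literally: a
# reference N is only compatible with a primer N.

#' Matching parameters for in-silico PCR
#'
#' @param max_mismatches Maximum mismatches tolerated per primer site.
#' @param protected_3prime_len Number of 3'-terminal primer positions in which
#'   no mismatch is tolerated (polymerase elongation starts at the 3' end, so
#'   terminal mismatches are far more disruptive than internal ones).
#' @param min_product,max_product Accepted amplicon length window in bp.
#' @return A list of class `match_params`.
#' @export
match_params <- function(max_mismatches = 0L, protected_3prime_len = 0L,
                         min_product = 50L, max_product = 2000L) {
  stopifnot(
    max_mismatches >= 0, protected_3prime_len >= 0,
    min_product <= max_product
  )
  structure(
    list(
      max_mismatches = as.integer(max_mismatches),
      protected_3prime_len = as.integer(protected_3prime_len),
      min_product = as.integer(min_product),
      max_product = as.integer(max_product)
    ),
    class = "match_params"
  )
}

# Mismatch profile of a pattern mask over every offset of a sequence mask.
# Returns an integer vector of length |seq| - |pattern| + 1 (or length 0).
# positions: which pattern positions to count (default all).
mismatch_profile <- function(pattern_mask, seq_mask, positions = seq_along(pattern_mask)) {
  k <- length(pattern_mask)
  n_off <- length(seq_mask) - k + 1L
  if (n_off < 1L) return(integer(0))
  mm <- integer(n_off)
  for (j in positions) {
    mm <- mm + as.integer(bitwAnd(pattern_mask[j], seq_mask[j:(j + n_off - 1L)]) == 0L)
  }
  mm
}

#' Test a primer for annealing at a fixed offset
#'
#' A mismatch is counted at every position where the reference base is not in
#' the IUPAC set of the primer base. The site matches iff total mismatches do
#' not exceed `max_mismatches` and the 3'-protected zone is mismatch-free.
#'
#' @param primer_seq Primer sequence 5'->3' (IUPAC).
#' @param sequence Reference sequence (the scanned strand).
#' @param offset 0-based offset of the primer's leftmost base on the sequence.
#' @param params A [match_params()] object.
#' @param orientation "forward" (3' end is the right end of the footprint) or
#'   "reverse" (the primer anneals as its reverse complement, so its 3' end is
#'   the left end of the footprint).
#' @return A list with `is_match` (logical) and `mismatches` (integer).
#' @export
iupac_match_at <- function(primer_seq, sequence, offset,
                           params = match_params(),
                           orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  primer_seq <- normalize_sequence(primer_seq, "primer")
  sequence <- normalize_sequence(sequence, "reference")
  k <- nchar(primer_seq)
  stopifnot(offset >= 0, offset + k <= nchar(sequence))
  pattern <- if (orientation == "forward") primer_seq else reverse_complement_iupac(primer_seq)
  pmask <- iupac_mask(pattern)
  smask <- iupac_mask(substr(sequence, offset + 1L, offset + k))
  mm <- sum(bitwAnd(pmask, smask) == 0L)
  p <- min(params$protected_3prime_len, k)
  protected_idx <- if (p == 0L) integer(0) else if (orientation == "forward") (k - p + 1L):k else 1L:p
  mm_prot <- sum(bitwAnd(pmask[protected_idx], smask[protected_idx]) == 0L)
  list(is_match = mm <= params$max_mismatches && mm_prot == 0L, mismatches = mm)
}

# All 0-based start offsets where the pattern (already oriented for the
# scanned strand) anneals. three_prime_end: "right" for a forward primer,
# "left" for a reverse-complemented reverse primer.
find_primer_sites <- function(pattern_mask, seq_mask, params, three_prime_end) {
  k <- length(pattern_mask)
  mm <- mismatch_profile(pattern_mask, seq_mask)
  if (length(mm) == 0L) return(integer(0))
  ok <- mm <= params$max_mismatches
  p <- min(params$protected_3prime_len, k)
  if (p > 0L) {
    idx <- if (three_prime_end == "right") (k - p + 1L):k else 1L:p
    ok <- ok & (mismatch_profile(pattern_mask, seq_mask, positions = idx) == 0L)
  }
  which(ok) - 1L
}

#' Predict amplicons of a primer pair on one reference sequence
#'
#' Scans the given strand with the forward primer and with the reverse
#' complement of the reverse primer, and reports every forward/reverse site
#' combination whose product length falls within the parameter window.
#'
#' @param pair A one-row primer tibble (needs `forward_seq`, `reverse_seq`),
#'   e.g. from [primer_pair()].
#' @param sequence Reference sequence (A/C/G/T string).
#' @param params A [match_params()] object.
#' @return A tibble with 0-based half-open `start`, `end` and `length`
#'   columns, sorted by start then end.
#' @export
predict_amplicons <- function(pair, sequence, params = match_params()) {
  stopifnot(is.data.frame(pair), nrow(pair) == 1)
  if (is.na(pair$forward_seq) || is.na(pair$reverse_seq)) {
    rlang::abort(sprintf(
      "pair '%s' has no primer sequences; in-silico PCR unsupported", pair$name
    ))
  }
  sequence <- normalize_sequence(sequence, "reference")
  smask <- iupac_mask(sequence)
  fmask <- iupac_mask(pair$forward_seq)
  rmask <- iupac_mask(reverse_complement_iupac(pair$reverse_seq))
  f_sites <- find_primer_sites(fmask, smask, params, "right")
  r_sites <- find_primer_sites(rmask, smask, params, "left")
  empty <- tibble::tibble(start = integer(0), end = integer(0), length = integer(0))
  if (length(f_sites) == 0L || length(r_sites) == 0L) return(empty)
  k_r <- length(rmask)
  combos <- expand.grid(start = f_sites, r_start = r_sites,
                        KEEP.OUT.ATTRS = FALSE)
  combos$end <- combos$r_start + k_r
  combos$length <- combos$end - combos$start
  keep <- combos$length >= params$min_product & combos$length <= params$max_product
  out <- combos[keep, c("start", "end", "length"), drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  tibble::as_tibble(out)
}

#' Default taxon-group definitions for PNA communities
#'
#' Each group is decided from the semicolon-delimited taxonomy path alone via
#' a regular expression. EUB (total eubacteria) matches everything in domain
#' Bacteria; the nitrogen-cycle guilds match their marker lineages.
#'
#' @return A tibble with columns `group` and `pattern`.
#' @export
taxon_groups <- function() {
  tibble::tribble(
    ~group,        ~pattern,
    "EUB",         "^Bacteria",
    "AOB",         "Nitrosomonas|Nitrosospira|Nitrosococcus",
    "AnAOB",       "Brocadi|Kuenenia|Jettenia|Scalindua|Anammoxoglobus",
    "Nitrobacter", "Nitrobacter",
    "Nitrospira",  ";Nitrospira",
    "DNB",         "Thauera|Paracoccus|Denitratisoma"
  )
}

#' Per-taxon-group primer coverage (in-silico PCR)
#'
#' For every primer pair and taxon group: `eligible` counts group members
#' whose record spans both primer loci (full-length test; truncated records
#' are excluded from the denominator), `matched` counts eligible members
#' yielding at least one predicted amplicon, and `coverage = matched /
#' eligible`. Coverage is `NA` (undefined, with a warning) when a group has
#' no eligible member — absence of references is not zero coverage.
#'
#' @param pairs Primer registry tibble (rows with sequences).
#' @param refdb Reference tibble with columns `id`, `sequence`, `taxonomy`.
#' @param groups Taxon-group tibble (`group`, `pattern`); see [taxon_groups()].
#' @param params A [match_params()] object.
#' @return A tidy tibble: `pair`, `group`, `eligible`, `matched`, `coverage`.
#' @export
primer_coverage <- function(pairs, refdb, groups = taxon_groups(),
                            params = match_params()) {
  stopifnot(is.data.frame(pairs), is.data.frame(refdb), nrow(refdb) > 0)
  validate_registry(pairs)
  pos <- positional_labels(pairs$name)
  seq_len_db <- nchar(refdb$sequence)

  per_pair <- purrr::map(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    amplified <- purrr::map_lgl(
      refdb$sequence,
      function(s) nrow(predict_amplicons(pair, s, params)) > 0
    )
    # eligibility: a match, or record long enough to span both primer loci
    min_span <- nchar(pair$forward_seq) + nchar(pair$reverse_seq)
    if (!is.na(pos$reverse_pos[i])) min_span <- max(min_span, pos$reverse_pos[i])
    eligible <- amplified | seq_len_db >= min_span
    purrr::map_dfr(seq_len(nrow(groups)), function(g) {
      in_group <- stringr::str_detect(refdb$taxonomy, groups$pattern[g])
      n_elig <- sum(in_group & eligible)
      n_match <- sum(in_group & amplified)
      tibble::tibble(
        pair = pair$name, group = groups$group[g],
        eligible = n_elig, matched = n_match,
        coverage = if (n_elig == 0) NA_real_ else n_match / n_elig
      )
    })
  })
  out <- dplyr::bind_rows(per_pair)
  if (anyNA(out$coverage)) {
    undef <- unique(out$group[is.na(out$coverage)])
    rlang::warn(sprintf(
      "coverage undefined (no eligible reference) for group(s): %s",
      paste(undef, collapse = ", ")
    ))
  }
  out
}

#' Coverage in wide (pair x group) form
#'
#' @param coverage_tbl Output of [primer_coverage()] (or any tibble with
#'   `pair`, `group`, `coverage`).
#' @return A tibble, one row per pair, one column per group.
#' @export
coverage_matrix <- function(coverage_tbl) {
  tidyr::pivot_wider(
    dplyr::select(coverage_tbl, "pair", "group", "coverage"),
    names_from = "group", values_from = "coverage"
  )
}

#' Read a reference database (FASTA + taxonomy TSV)
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param taxonomy_path Two-column TSV `id<TAB>taxonomy` with SILVA-style
#'   semicolon-delimited rank paths.
#' @return Tibble with columns `id`, `sequence`, `taxonomy`.
#' @export
read_reference_db <- function(fasta_path, taxonomy_path) {
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  tax <- readr::read_tsv(
    taxonomy_path,
    col_names = c("id", "taxonomy"),
    col_types = readr::cols(.default = readr::col_character())
  )
  db <- tibble::tibble(
    id = sub("\\s.*$", "", names(seqs)),
    sequence = as.character(seqs)
  )
  db <- dplyr::inner_join(db, tax, by = "id")
  if (nrow(db) == 0) rlang::abort("no sequence ids shared between FASTA and taxonomy TSV")
  db
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' @param refdb Tibble with `id`, `sequence`, `taxonomy`.
#' @param fasta_path,taxonomy_path Output paths.
#' @return Invisibly, the input.
#' @export
write_reference_db <- function(refdb, fasta_path, taxonomy_path) {
  rlang::check_installed("Biostrings")
  seqs <- Biostrings::DNAStringSet(stats::setNames(refdb$sequence, refdb$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    dplyr::select(refdb, "id", "taxonomy"),
    taxonomy_path, col_names = FALSE
  )
  invisible(refdb)
}
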