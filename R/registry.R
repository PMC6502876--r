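# Primer registry: named degenerate primer pairs with hypervariable-region
# labels, printed amplicon lengths and literature hit counts. The registry is
# a plain tibble (one row per pair) so it composes with dplyr verbs.

REGISTRY_COLUMNS <- c(
  "name", "forward_seq", "reverse_seq", "region",
  "printed_length", "target_group", "gene", "hits"
)

#' Construct a one-row primer-pair tibble
#'
#' @param name Pair name, conventionally `<pos>f-<pos>r` in E. coli 16S
#'   numbering (e.g. "1055f-1392r").
#' @param forward_seq,reverse_seq IUPAC sequences written 5'->3' (either may
#'   be `NA` when only the name is known from the literature).
#' @param region Hypervariable-region label such as "V7-V8", or `NA`.
#' @param printed_length Reported amplicon length in bp, or `NA`.
#' @param target_group Taxon group the pair targets (e.g. "EUB", "AnAOB").
#' @param gene Marker gene label ("16S", "amoA", "hzs", "nirS", ...).
#' @param hits Literature hit count, or `NA`.
#' @return A one-row tibble with the registry columns.
#' @export
primer_pair <- function(name, forward_seq = NA_character_,
                        reverse_seq = NA_character_, region = NA_character_,
                        printed_length = NA_integer_, target_group = NA_character_,
                        gene = "16S", hits = NA_integer_) {
  norm <- function(s) {
    if (is.na(s) || !nzchar(s)) NA_character_ else normalize_sequence(s)
  }
  tibble::tibble(
    name = name,
    forward_seq = norm(forward_seq),
    reverse_seq = norm(reverse_seq),
    region = region,
    printed_length = as.integer(printed_length),
    target_group = target_group,
    gene = gene,
    hits = as.integer(hits)
  )
}

#' Parse a positional primer-pair name
#'
#' Pair names follow the `<pos>f-<pos>r` convention where the numbers are
#' E. coli 16S positions ("1055f-1392r" -> 1055, 1392). Non-digit prefixes
#' before the numeric core are stripped, so "Amx809f-Amx1066r" parses to
#' (809, 1066).
#'
#' @param name Character vector of pair names.
#' @return A tibble with columns `name`, `forward_pos`, `reverse_pos`.
#' @export
#' @examples
#' parse_positional_name("1055f-1392r")
parse_positional_name <- function(name) {
  res <- positional_labels(name)
  bad <- which(is.na(res$forward_pos))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "cannot parse positional primer name(s): %s (expected '<digits>f-<digits>r')",
      paste(sQuote(name[bad]), collapse = ", ")
    ))
  }
  res
}

# Lenient vectorized parser: NA positions where the convention does not apply.
positional_labels <- function(name) {
  pattern <- "^[A-Za-z]*([0-9]+)[fF]-[A-Za-z]*([0-9]+)[rR]$"
  m <- stringr::str_match(name, pattern)
  tibble::tibble(
    name = name,
    forward_pos = as.integer(m[, 2]),
    reverse_pos = as.integer(m[, 3])
  )
}

#' Amplicon length implied by positional primer names
#'
#' Computes `reverse_pos - forward_pos` from the pair name. The printed
#' length, when present, is retained untouched; a `length_discrepancy` flag
#' (with a warning) marks rows where the two disagree — positional names are
#' a naming convention, not exact amplicon coordinates.
#'
#' @param pairs A primer registry tibble (needs columns `name` and, if
#'   available, `printed_length`).
#' @return The input with columns `forward_pos`, `reverse_pos`,
#'   `positional_length` and `length_discrepancy` added.
#' @export
amplicon_length_positional <- function(pairs) {
  stopifnot(is.data.frame(pairs), "name" %in% names(pairs))
  pos <- positional_labels(pairs$name)
  if (anyNA(pos$forward_pos)) {
    rlang::abort(sprintf(
      "positional length unsupported for pair(s) without parseable names: %s",
      paste(sQuote(pairs$name[is.na(pos$forward_pos)]), collapse = ", ")
    ))
  }
  out <- dplyr::mutate(
    pairs,
    forward_pos = pos$forward_pos,
    reverse_pos = pos$reverse_pos,
    positional_length = pos$reverse_pos - pos$forward_pos
  )
  printed <- if ("printed_length" %in% names(out)) out$printed_length else NA_integer_
  out$length_discrepancy <- !is.na(printed) & printed != out$positional_length
  if (any(out$length_discrepancy)) {
    rlang::warn(sprintf(
      "positional length differs from printed length for: %s",
      paste(out$name[out$length_discrepancy], collapse = ", ")
    ))
  }
  out
}

validate_registry <- function(registry) {
  missing <- setdiff(c("name", "forward_seq", "reverse_seq"), names(registry))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "primer registry is missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  dup <- unique(registry$name[duplicated(registry$name)])
  if (length(dup) > 0) {
    rlang::abort(sprintf(
      "duplicate primer pair name(s): %s", paste(dup, collapse = ", ")
    ))
  }
  invisible(registry)
}

#' Read a primer registry from TSV
#'
#' Expected columns: `name`, `forward_seq`, `reverse_seq`, `region`,
#' `printed_length`, `target_group`, `gene`, `hits`. Sequence cells may be
#' empty (names-only literature entries); non-empty sequences are normalized
#' (uppercase, U->T) and validated as IUPAC.
#'
#' @param path Path to a tab-separated registry file.
#' @return A tibble, one row per primer pair.
#' @export
read_primer_registry <- function(path) {
  registry <- readr::read_tsv(
    path,
    col_types = readr::cols(
      name = readr::col_character(),
      forward_seq = readr::col_character(),
      reverse_seq = readr::col_character(),
      region = readr::col_character(),
      printed_length = readr::col_integer(),
      target_group = readr::col_character(),
      gene = readr::col_character(),
      hits = readr::col_integer()
    )
  )
  validate_registry(registry)
  norm <- function(x, side) {
    purrr::map2_chr(x, registry$name, function(s, nm) {
      if (is.na(s) || !nzchar(s)) return(NA_character_)
      normalize_sequence(s, what = sprintf("%s primer of %s", side, nm))
    })
  }
  registry$forward_seq <- norm(registry$forward_seq, "forward")
  registry$reverse_seq <- norm(registry$reverse_seq, "reverse")
  registry
}

#' Packaged registry of universal eubacterial 16S primer pairs
#'
#' The eight universal 16S rRNA gene primer pairs reported in use across PNA
#' quantification studies, with their hypervariable regions, reported
#' amplicon lengths and literature hit counts. Sequences are not part of the
#' registry (the published survey lists names only).
#'
#' @return A tibble with 8 rows.
#' @export
universal_primers <- function() {
  read_primer_registry(
    system.file("extdata", "universal_primers.tsv", package = "primerbias",
                mustWork = TRUE)
  )
}

#' Packaged registry of microbial group-specific primer pairs
#'
#' Group-specific pairs commonly used for AOB, AnAOB, Nitrobacter, Nitrospira
#' and denitrifiers, targeting 16S rRNA or functional genes (amoA, hzs, nirS).
#'
#' @return A tibble, one row per pair.
#' @export
group_specific_primers <- function() {
  read_primer_registry(
    system.file("extdata", "group_specific_primers.tsv", package = "primerbias",
                mustWork = TRUE)
  )
}
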