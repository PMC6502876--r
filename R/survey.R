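# Literature-survey computations: one record per (study, target group, primer
# pair) usage; hit counting, ranking, and per-group primer-diversity shares.
# A study can contribute zero or many records per group, so hits are usages,
# not studies.

STUDY_COLUMNS <- c("study", "year", "system", "target_group", "pair", "gene")

#' Read a study-record table from TSV
#'
#' One row per recorded primer-pair usage: columns `study`, `year`, `system`
#' (PNA/PN/A), `target_group`, `pair`, `gene`.
#'
#' @param path TSV path.
#' @return A validated tibble.
#' @export
read_study_records <- function(path) {
  rec <- readr::read_tsv(path, col_types = readr::cols(
    study = readr::col_character(),
    year = readr::col_integer(),
    system = readr::col_character(),
    target_group = readr::col_character(),
    pair = readr::col_character(),
    gene = readr::col_character()
  ))
  validate_study_records(rec)
}

validate_study_records <- function(records) {
  missing <- setdiff(c("study", "target_group", "pair"), names(records))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "study records missing column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  dup <- duplicated(records[, c("study", "target_group", "pair")])
  if (any(dup)) {
    rlang::abort("duplicated (study, target_group, pair) usage records")
  }
  records
}

#' Expand a registry's hit counts into synthetic study records
#'
#' The published survey reports per-pair hit totals, not the underlying
#' per-study rows. This deterministic expansion fabricates one record per hit
#' (synthetic study ids) so that record-level operations reproduce the
#' registry's totals exactly. Records are synthetic stand-ins; only the
#' counts are faithful.
#'
#' @param registry Registry tibble with `name`, `target_group`, `gene`, `hits`.
#' @return A study-record tibble with `sum(hits)` rows.
#' @export
hits_to_records <- function(registry) {
  reg <- dplyr::filter(registry, !is.na(.data$hits) & .data$hits > 0)
  rec <- tidyr::uncount(
    tibble::tibble(
      target_group = reg$target_group, pair = reg$name, gene = reg$gene,
      hits = reg$hits
    ),
    weights = .data$hits
  )
  rec |>
    dplyr::group_by(.data$pair) |>
    dplyr::mutate(study = sprintf("synthetic_study_%s_%02d", .data$pair,
                                  dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(year = NA_integer_, system = "PNA") |>
    dplyr::select(dplyr::all_of(STUDY_COLUMNS))
}

#' Count primer-pair hits
#'
#' A hit is one recorded usage of a primer pair by one study. Counts are
#' computed within a target-group scope or over all records; the counts sum
#' to the number of in-scope records (conservation).
#'
#' @param records Study-record tibble.
#' @param scope A `target_group` label, or `"ALL"` for every record.
#' @return Tibble `pair`, `hits`, sorted by pair name.
#' @export
count_hits <- function(records, scope = "ALL") {
  validate_study_records(records)
  if (!identical(scope, "ALL")) {
    records <- dplyr::filter(records, .data$target_group == scope)
  }
  records |>
    dplyr::count(.data$pair, name = "hits") |>
    dplyr::arrange(.data$pair)
}

#' Rank primer pairs by hit count
#'
#' @param hit_tbl Tibble with `pair` and `hits` (from [count_hits()]).
#' @return The same tibble in stable descending hit order, ties broken
#'   alphabetically by pair name.
#' @export
rank_by_hits <- function(hit_tbl) {
  dplyr::arrange(hit_tbl, dplyr::desc(.data$hits), .data$pair)
}

#' Primer-usage diversity per target group
#'
#' For each target group: the number of distinct primer pairs in use and the
#' group's share of all hits (percent; shares sum to 100).
#'
#' @param records Study-record tibble.
#' @return Tibble `target_group`, `n_pairs`, `hits`, `share_pct`, ordered by
#'   increasing primer diversity (`n_pairs`, ties by group name).
#' @export
group_usage_distribution <- function(records) {
  validate_study_records(records)
  total <- nrow(records)
  records |>
    dplyr::group_by(.data$target_group) |>
    dplyr::summarise(
      n_pairs = dplyr::n_distinct(.data$pair),
      hits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(share_pct = 100 * .data$hits / total) |>
    dplyr::arrange(.data$n_pairs, .data$target_group)
}
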