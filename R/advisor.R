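# Decision-tree framework for planning PCR-based PNA studies, encoded as an
# inspectable rule table (data, not code branches): each rule maps one
# objective field/value to a method choice, guidance, required check or
# warning. Branches of the framework for which no explicit recommendation is
# documented are carried with provenance "unspecified" rather than guessed.

#' A fully specified study objective
#'
#' Every field must be set explicitly; there are no defaults at the API level
#' because the framework's advice is conditional on all of them.
#'
#' @param question Ecological question: `"presence"` (is the target organism
#'   there), `"richness"` (how many different organisms) or `"evenness"`
#'   (how many of each group).
#' @param quantity `"relative"` (relative abundance) or `"absolute"`
#'   (copies/mL).
#' @param intent `"compare_with_other_studies"` or `"characterize_dynamics"`.
#' @param degenerate_primers Will degenerate primers be used?
#' @param normalization_to_total_EUB Is normalization of group abundances to
#'   total eubacterial abundance requested?
#' @return A one-row tibble of class `study_objective`.
#' @export
study_objective <- function(question, quantity, intent, degenerate_primers,
                            normalization_to_total_EUB) {
  question <- rlang::arg_match(question, c("presence", "richness", "evenness"))
  quantity <- rlang::arg_match(quantity, c("relative", "absolute"))
  intent <- rlang::arg_match(
    intent, c("compare_with_other_studies", "characterize_dynamics")
  )
  stopifnot(rlang::is_bool(degenerate_primers),
            rlang::is_bool(normalization_to_total_EUB))
  out <- tibble::tibble(
    question = question, quantity = quantity, intent = intent,
    degenerate_primers = degenerate_primers,
    normalization_to_total_EUB = normalization_to_total_EUB
  )
  class(out) <- c("study_objective", class(out))
  out
}

#' All enumerable study objectives
#'
#' The objective space is finite (3 questions x 2 quantities x 2 intents x
#' 2 x 2 booleans = 48 cases).
#'
#' @return A 48-row tibble of objectives.
#' @export
enumerate_objectives <- function() {
  tidyr::expand_grid(
    question = c("presence", "richness", "evenness"),
    quantity = c("relative", "absolute"),
    intent = c("compare_with_other_studies", "characterize_dynamics"),
    degenerate_primers = c(FALSE, TRUE),
    normalization_to_total_EUB = c(FALSE, TRUE)
  )
}

#' The decision-rule table
#'
#' @return Tibble with columns `field`, `value`, `action` (method, guidance,
#'   check or warning), `payload` and `provenance` (stated vs unspecified).
#' @export
decision_rules <- function() {
  readr::read_tsv(
    system.file("extdata", "decision_rules.tsv", package = "primerbias",
                mustWork = TRUE),
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Recommend a PCR-based study design for an objective
#'
#' Applies the [decision_rules()] table to a fully specified
#' [study_objective()]: a deterministic, total function of the objective.
#' Relative quantification maps to 16S amplicon sequencing and absolute
#' quantification to qPCR; comparison with other studies requires the same
#' primer pairs as those studies; dynamics studies require in-silico coverage
#' evaluation and interpretation against a within-reactor reference sample;
#' a gel-electrophoresis product check is required except for degenerate
#' primers; and requesting normalization to total eubacteria always draws a
#' warning.
#'
#' @param objective A [study_objective()].
#' @param rules A rule table; defaults to the packaged one.
#' @return A list of class `recommendation`: `method`, `guidance`, `checks`,
#'   `warnings` and the tibble of `applied` rules.
#' @export
recommend <- function(objective, rules = decision_rules()) {
  stopifnot(inherits(objective, "study_objective"), nrow(objective) == 1)
  obj <- as.list(objective)
  applies <- purrr::map_lgl(seq_len(nrow(rules)), function(i) {
    f <- rules$field[i]
    if (f == "any") return(TRUE)
    identical(as.character(obj[[f]]), rules$value[i])
  })
  applied <- rules[applies, ]
  pick <- function(action) applied$payload[applied$action == action &
                                             applied$provenance == "stated"]
  method <- pick("method")
  structure(
    list(
      method = method,
      guidance = pick("guidance"),
      checks = pick("check"),
      warnings = pick("warning"),
      unspecified = applied$payload[applied$provenance == "unspecified"],
      applied = applied
    ),
    class = "recommendation"
  )
}

#' @export
print.recommendation <- function(x, ...) {
  cat("Recommended method:", x$method, "\n")
  if (length(x$guidance)) cat("Guidance:\n", paste(" -", x$guidance, collapse = "\n"), "\n")
  if (length(x$checks)) cat("Required checks:\n", paste(" -", x$checks, collapse = "\n"), "\n")
  if (length(x$warnings)) cat("Warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Tidy a recommendation into one row per advised item
#'
#' @param x A `recommendation`.
#' @param ... Unused.
#' @return Tibble with `action` and `payload`.
#' @method tidy recommendation
#' @export
tidy.recommendation <- function(x, ...) {
  tibble::tibble(
    action = c(rep("method", length(x$method)),
               rep("guidance", length(x$guidance)),
               rep("check", length(x$checks)),
               rep("warning", length(x$warnings))),
    payload = c(x$method, x$guidance, x$checks, x$warnings)
  )
}

#' Recommendations for every enumerable objective
#'
#' @param rules A rule table; defaults to the packaged one.
#' @return The 48 objectives with list-columns `method`, `n_guidance`,
#'   `has_gel_check`, `has_normalization_warning` summarizing each
#'   recommendation.
#' @export
recommend_all <- function(rules = decision_rules()) {
  objectives <- enumerate_objectives()
  recs <- purrr::map(seq_len(nrow(objectives)), function(i) {
    recommend(
      study_objective(
        objectives$question[i], objectives$quantity[i], objectives$intent[i],
        objectives$degenerate_primers[i], objectives$normalization_to_total_EUB[i]
      ),
      rules = rules
    )
  })
  dplyr::mutate(
    objectives,
    method = purrr::map_chr(recs, "method"),
    n_guidance = purrr::map_int(recs, ~ length(.x$guidance)),
    has_gel_check = purrr::map_lgl(recs, ~ any(grepl("gel electrophoresis", .x$checks))),
    has_insilico_check = purrr::map_lgl(recs, ~ any(grepl("in-silico", .x$checks))),
    has_normalization_warning = purrr::map_lgl(recs, ~ length(.x$warnings) > 0),
    recommendation = recs
  )
}
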