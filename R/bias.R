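# Propagation of primer coverage into quantification bias: theoretical qPCR
# abundances, EUB-normalized relative abundances, percentage dissimilarity
# between primer pairs (Bray-Curtis x 100), and ANOVA significance tests.

#' Mock community compositions
#'
#' Returns a community as a tibble of true 16S rRNA gene copy numbers per mL.
#' The `"pna_hypothetical"` preset is the worked example used throughout the
#' package: 1.00e10 copies/mL total eubacteria, 4.00e9 AnAOB, and 2.00e9 each
#' for AOB, Nitrobacter and Nitrospira.
#'
#' @param preset Name of a packaged preset, or `NULL` when `abundances` is
#'   given.
#' @param abundances Named numeric vector (group -> copies/mL) for a custom
#'   community.
#' @param scale Multiplier applied to all abundances.
#' @return Tibble with columns `group` and `abundance`.
#' @export
mock_community <- function(preset = "pna_hypothetical", abundances = NULL,
                           scale = 1) {
  if (!is.null(abundances)) {
    if (any(abundances < 0)) rlang::abort("abundances must be non-negative")
    comm <- tibble::tibble(group = names(abundances),
                           abundance = unname(abundances))
  } else {
    comm <- switch(preset,
      pna_hypothetical = tibble::tibble(
        group = c("EUB", "AnAOB", "AOB", "Nitrobacter", "Nitrospira"),
        abundance = c(1.00e10, 4.00e9, 2.00e9, 2.00e9, 2.00e9)
      ),
      rlang::abort(sprintf("unknown community preset '%s'", preset))
    )
  }
  comm$abundance <- comm$abundance * scale
  comm
}

#' Reported SILVA132 coverage of the three most-used eubacterial primer pairs
#'
#' The published TestPrime (SILVA132) coverage values for primer pairs
#' 1055f-1392r, 338f-518r and 341f-543r over EUB, AOB, AnAOB, Nitrobacter and
#' Nitrospira, as fractions. These are fixed published inputs: the in-silico
#' engine in this package operates on its own reference collections and is
#' not expected to reproduce database-specific percentages.
#'
#' @return Tidy tibble: `pair`, `group`, `coverage`.
#' @export
reported_eub_coverage <- function() {
  readr::read_tsv(
    system.file("extdata", "silva132_coverage.tsv", package = "primerbias",
                mustWork = TRUE),
    col_types = readr::cols(
      pair = readr::col_character(),
      group = readr::col_character(),
      coverage = readr::col_double()
    )
  )
}

#' Theoretical measured abundance under primer coverage bias
#'
#' What a perfectly efficient qPCR would report: for each primer pair and
#' taxon group, `measured = coverage x true abundance`. Linear in the
#' community (scaling all true abundances scales all measurements) and
#' monotone in coverage.
#'
#' @param coverage_tbl Tidy coverage tibble (`pair`, `group`, `coverage`).
#' @param community Tibble from [mock_community()] (`group`, `abundance`).
#' @return Tibble `pair`, `group`, `coverage`, `abundance`, `measured`.
#' @export
theoretical_abundance <- function(coverage_tbl, community) {
  stopifnot(all(c("pair", "group", "coverage") %in% names(coverage_tbl)))
  missing <- setdiff(unique(coverage_tbl$group), community$group)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "no community abundance for group(s): %s", paste(missing, collapse = ", ")
    ))
  }
  out <- dplyr::inner_join(
    dplyr::select(coverage_tbl, "pair", "group", "coverage"),
    community, by = "group"
  )
  dplyr::mutate(out, measured = .data$coverage * .data$abundance)
}

#' Relative abundance normalized to measured total eubacteria
#'
#' Divides each group's measured abundance by the same primer set's measured
#' EUB abundance — the normalization commonly applied to qPCR data. Because
#' group-specific and EUB primers have independent coverages, the quotient can
#' exceed 1; a warning is raised when it does, and when a pair's EUB
#' measurement is zero the pair's relative abundances are `NA` (undefined)
#' rather than dropped.
#'
#' @param measurements Tibble from [theoretical_abundance()] or measured data
#'   (`pair`, `group`, `measured`).
#' @param eub_group Label of the normalizing total-bacteria group.
#' @return The non-EUB rows with a `relative` column (fraction) added.
#' @export
relative_abundance <- function(measurements, eub_group = "EUB") {
  stopifnot(all(c("pair", "group", "measured") %in% names(measurements)))
  eub <- dplyr::filter(measurements, .data$group == eub_group)
  if (!all(unique(measurements$pair) %in% eub$pair)) {
    rlang::abort(sprintf("missing %s measurement for some primer pair", eub_group))
  }
  eub <- dplyr::select(eub, "pair", eub_measured = "measured")
  zero <- eub$pair[eub$eub_measured == 0]
  if (length(zero) > 0) {
    rlang::warn(sprintf(
      "zero %s measurement for pair(s) %s; relative abundance undefined",
      eub_group, paste(zero, collapse = ", ")
    ))
  }
  out <- measurements |>
    dplyr::filter(.data$group != eub_group) |>
    dplyr::left_join(eub, by = "pair") |>
    dplyr::mutate(
      relative = dplyr::if_else(.data$eub_measured == 0, NA_real_,
                                .data$measured / .data$eub_measured)
    ) |>
    dplyr::select(-"eub_measured")
  over <- !is.na(out$relative) & out$relative > 1
  if (any(over)) {
    rlang::warn(sprintf(
      "relative abundance exceeds 1 for %d combination(s) (group primer coverage higher than %s primer coverage); normalization to total eubacteria is unreliable",
      sum(over), eub_group
    ))
  }
  out
}

#' Percentage dissimilarity between two measurement vectors
#'
#' Bray-Curtis dissimilarity scaled to 0-100:
#' `100 * sum(|x_i - y_i|) / sum(x_i + y_i)`. Zero for identical vectors, 100
#' for positive vectors with disjoint support, and invariant to a common
#' positive rescaling. This is the two-sample total dissimilarity that a
#' SIMPER analysis decomposes.
#'
#' @param x,y Non-negative numeric vectors of equal length.
#' @return A percentage in `[0, 100]`, or `NA` (with a warning) when both
#'   vectors are all zero.
#' @export
#' @examples
#' percent_dissimilarity(4.45e9, 7.00e9) # 22.27
percent_dissimilarity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (any(x < 0) || any(y < 0)) rlang::abort("abundances must be non-negative")
  denom <- sum(x + y)
  if (denom == 0) {
    rlang::warn("both vectors are all-zero; dissimilarity undefined")
    return(NA_real_)
  }
  100 * sum(abs(x - y)) / denom
}

#' Pairwise percentage dissimilarity between primer pairs
#'
#' For every sample and every unordered combination of primer pairs, computes
#' the percentage dissimilarity between their replicate measurement vectors
#' (replicates aligned by the `replicate` column). With `k` primer pairs this
#' yields `choose(k, 2)` comparisons per sample; a single pair yields none.
#'
#' @param measurements Tibble with columns `pair`, `measured`, optionally
#'   `sample` (a single sample is assumed otherwise) and `replicate`.
#' @return Tibble `sample`, `pair_x`, `pair_y`, `comparison`, `dissimilarity`.
#' @export
pairwise_dissimilarity <- function(measurements) {
  stopifnot(all(c("pair", "measured") %in% names(measurements)))
  m <- measurements
  if (!"sample" %in% names(m)) m$sample <- "sample1"
  if (!"replicate" %in% names(m)) m$replicate <- 1L
  out <- m |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(function(d, key) {
      pairs <- sort(unique(d$pair))
      if (length(pairs) < 2) {
        return(tibble::tibble(pair_x = character(0), pair_y = character(0),
                              dissimilarity = numeric(0)))
      }
      combos <- utils::combn(pairs, 2)
      vecs <- lapply(pairs, function(p) {
        dd <- d[d$pair == p, ]
        dd$measured[order(dd$replicate)]
      })
      names(vecs) <- pairs
      purrr::map_dfr(seq_len(ncol(combos)), function(j) {
        a <- combos[1, j]; b <- combos[2, j]
        tibble::tibble(
          pair_x = a, pair_y = b,
          dissimilarity = percent_dissimilarity(vecs[[a]], vecs[[b]])
        )
      })
    }) |>
    dplyr::ungroup()
  dplyr::mutate(out, comparison = paste(.data$pair_x, .data$pair_y, sep = " vs "),
                .before = "dissimilarity")
}

new_pb_anova <- function(table, design) {
  structure(list(table = table, design = design), class = "pb_anova")
}

#' @export
print.pb_anova <- function(x, ...) {
  cat(sprintf("%s ANOVA\n", x$design))
  print(x$table)
  invisible(x)
}

#' Tidy an ANOVA fit
#'
#' @param x A `pb_anova` object.
#' @param ... Unused.
#' @return Tibble with `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value` (NA for the residual row).
#' @method tidy pb_anova
#' @export
tidy.pb_anova <- function(x, ...) x$table

#' One-row summary of an ANOVA fit
#'
#' @param x A `pb_anova` object.
#' @param ... Unused.
#' @return One-row tibble with the design, residual df and the minimum
#'   main-effect p-value.
#' @method glance pb_anova
#' @export
glance.pb_anova <- function(x, ...) {
  eff <- x$table[x$table$term != "Residuals", ]
  tibble::tibble(
    design = x$design,
    df.residual = x$table$df[x$table$term == "Residuals"],
    statistic.max = suppressWarnings(max(eff$statistic, na.rm = TRUE)),
    p.value.min = suppressWarnings(min(eff$p.value, na.rm = TRUE))
  )
}

# F and p with explicit degenerate handling: a zero effect SS is F = 0, p = 1
# even when the residual MS is also zero; a positive effect over a zero
# residual is infinitely significant.
f_and_p <- function(ss_eff, df_eff, ms_res, df_res) {
  if (ss_eff == 0) return(c(statistic = 0, p.value = 1))
  if (ms_res == 0) return(c(statistic = Inf, p.value = 0))
  f <- (ss_eff / df_eff) / ms_res
  c(statistic = f, p.value = stats::pf(f, df_eff, df_res, lower.tail = FALSE))
}

#' Two-way ANOVA without replication (randomized-block layout)
#'
#' Classical additive decomposition for a complete two-factor table with one
#' observation per cell: `SS_A` with `a - 1` df, `SS_B` with `b - 1` df, and a
#' residual with `(a - 1)(b - 1)` df; no interaction term is estimable.
#' Computed on the raw (untransformed) values.
#'
#' @param data Tibble in long form.
#' @param value,factor_a,factor_b Column names (strings) of the response and
#'   the two factors.
#' @return A `pb_anova` object; see [tidy.pb_anova()].
#' @export
anova_two_way_no_rep <- function(data, value, factor_a, factor_b) {
  a_lev <- unique(data[[factor_a]])
  b_lev <- unique(data[[factor_b]])
  a <- length(a_lev); b <- length(b_lev)
  if (a < 2 || b < 2) rlang::abort("both factors need at least 2 levels")
  if (nrow(data) != a * b ||
      nrow(unique(data[, c(factor_a, factor_b)])) != a * b) {
    rlang::abort("table must be complete with exactly one observation per cell")
  }
  y <- matrix(NA_real_, a, b, dimnames = list(a_lev, b_lev))
  y[cbind(match(data[[factor_a]], a_lev), match(data[[factor_b]], b_lev))] <-
    data[[value]]
  grand <- mean(y)
  ss_a <- b * sum((rowMeans(y) - grand)^2)
  ss_b <- a * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_a - ss_b
  ss_res <- max(ss_res, 0) # guard tiny negative rounding
  df_a <- a - 1L; df_b <- b - 1L; df_res <- df_a * df_b
  ms_res <- ss_res / df_res
  fa <- f_and_p(ss_a, df_a, ms_res, df_res)
  fb <- f_and_p(ss_b, df_b, ms_res, df_res)
  tab <- tibble::tibble(
    term = c(factor_a, factor_b, "Residuals"),
    df = c(df_a, df_b, df_res),
    sumsq = c(ss_a, ss_b, ss_res),
    meansq = c(ss_a / df_a, ss_b / df_b, ms_res),
    statistic = unname(c(fa["statistic"], fb["statistic"], NA_real_)),
    p.value = unname(c(fa["p.value"], fb["p.value"], NA_real_))
  )
  new_pb_anova(tab, "two-way (no replication)")
}

#' One-way ANOVA on replicate vectors
#'
#' Standard between/within decomposition. Each group needs at least two
#' replicates; when every group is a constant vector the within-group variance
#' is zero and the F statistic is undefined (`NA`, with a warning).
#'
#' @param data Tibble in long form.
#' @param value,group Column names (strings) of the response and the grouping
#'   factor.
#' @return A `pb_anova` object; see [tidy.pb_anova()].
#' @export
anova_one_way <- function(data, value, group) {
  g <- factor(data[[group]])
  y <- data[[value]]
  n_i <- table(g)
  if (nlevels(g) < 2) rlang::abort("need at least 2 groups")
  if (any(n_i < 2)) {
    rlang::abort(sprintf(
      "group(s) with fewer than 2 replicates: %s",
      paste(names(n_i)[n_i < 2], collapse = ", ")
    ))
  }
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ss_between <- sum(as.numeric(n_i) * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  ms_w <- ss_within / df_w
  if (ms_w == 0) {
    rlang::warn("zero within-group variance; F statistic undefined")
    fp <- c(statistic = NA_real_, p.value = NA_real_)
  } else {
    fp <- f_and_p(ss_between, df_b, ms_w, df_w)
  }
  tab <- tibble::tibble(
    term = c(group, "Residuals"),
    df = c(df_b, df_w),
    sumsq = c(ss_between, ss_within),
    meansq = c(ss_between / df_b, ms_w),
    statistic = unname(c(fp["statistic"], NA_real_)),
    p.value = unname(c(fp["p.value"], NA_real_))
  )
  new_pb_anova(tab, "one-way")
}
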