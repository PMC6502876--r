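# Synthetic ground-truth generators: reference databases with planted
# primer-binding-site intactness at controlled per-group fractions, mock
# communities, noisy qPCR-style replicate tables, and literature-survey
# fixtures. Every generator is a pure function of (spec, seed).

# run code under a seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one concrete realization of an IUPAC pattern
realize_iupac <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  paste(vapply(IUPAC_SETS[chars], function(s) sample(s, 1), character(1)),
        collapse = "")
}

# substitute k bases of a planted site so it cannot anneal: each substituted
# base is chosen OUTSIDE the primer's IUPAC set at that position, inside the
# 3'-proximal end of the site, so the site fails under exact matching and
# under any mismatch model that protects >= 1 terminal base.
ablate_site <- function(site, primer_pattern, k, three_prime_end) {
  chars <- strsplit(site, "", fixed = TRUE)[[1]]
  pat <- strsplit(primer_pattern, "", fixed = TRUE)[[1]]
  len <- length(chars)
  order_idx <- if (three_prime_end == "right") rev(seq_len(len)) else seq_len(len)
  mutable <- order_idx[vapply(order_idx, function(i) pat[i] != "N", logical(1))]
  if (length(mutable) < k) {
    rlang::abort("primer too degenerate to ablate: fewer non-N positions than substitutions")
  }
  for (i in mutable[seq_len(k)]) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), IUPAC_SETS[[pat[i]]]), 1)
  }
  paste(chars, collapse = "")
}

#' Default taxonomy path templates for the synthetic reference generator
#'
#' SILVA-style semicolon-delimited rank paths, one lineage per nitrogen-cycle
#' guild, chosen so that the default [taxon_groups()] patterns classify them
#' unambiguously.
#'
#' @return Named character vector (group -> taxonomy path).
#' @export
synthetic_taxonomy_templates <- function() {
  c(
    AOB = "Bacteria;Proteobacteria;Betaproteobacteria;Nitrosomonadales;Nitrosomonadaceae;Nitrosomonas",
    AnAOB = "Bacteria;Planctomycetes;Brocadiae;Brocadiales;Brocadiaceae;Candidatus_Brocadia",
    Nitrobacter = "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Nitrobacteraceae;Nitrobacter",
    Nitrospira = "Bacteria;Nitrospirae;Nitrospira;Nitrospirales;Nitrospiraceae;Nitrospira",
    DNB = "Bacteria;Proteobacteria;Betaproteobacteria;Rhodocyclales;Rhodocyclaceae;Thauera",
    OTHER = "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus"
  )
}

#' Generate a reference database with planted primer-site coverage
#'
#' Builds `n_per_group` random reference sequences per taxon group and plants
#' one forward and one reverse binding site per primer pair in every sequence,
#' in disjoint blocks. For each (pair, group), exactly `round(f * n)` group
#' members keep both sites intact (`f` from `coverage`); in the remaining
#' members both sites receive `ablation_k` substitutions in the 3'-proximal
#' zone, chosen outside the primer's IUPAC set, so that ablated sequences fail
#' to amplify under exact matching and under any mismatch model with a
#' protected 3' zone.
#'
#' EUB membership spans all groups, so EUB coverage is not planted directly:
#' it equals the sequence-weighted mean of the per-group fractions, and the
#' returned truth table includes that derived EUB row.
#'
#' @param pairs Registry tibble with primer sequences.
#' @param coverage Tibble `pair`, `group`, `coverage` of target fractions in
#'   `[0, 1]` for concrete (disjoint) groups.
#' @param n_per_group Sequences per group.
#' @param seq_length Length of every reference sequence (bp).
#' @param gap Bases between the planted forward and reverse sites (product
#'   length is `gap` plus both primer lengths).
#' @param ablation_k Substitutions per ablated site.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param taxonomy Named vector of group -> taxonomy path; see
#'   [synthetic_taxonomy_templates()].
#' @return A list with `refdb` (tibble `id`, `sequence`, `taxonomy`) and
#'   `truth` (tibble `pair`, `group`, `coverage` of realized fractions,
#'   including the derived EUB row).
#' @export
generate_reference_db <- function(pairs, coverage, n_per_group = 200,
                                  seq_length = 800, gap = 60, ablation_k = 2,
                                  seed = 1,
                                  taxonomy = synthetic_taxonomy_templates()) {
  stopifnot(all(c("pair", "group", "coverage") %in% names(coverage)))
  if (any(coverage$coverage < 0 | coverage$coverage > 1)) {
    rlang::abort("target coverage fractions must lie in [0, 1]")
  }
  pairs <- dplyr::filter(pairs, .data$name %in% unique(coverage$pair))
  if (any(is.na(pairs$forward_seq)) || any(is.na(pairs$reverse_seq))) {
    rlang::abort("all planted pairs need primer sequences")
  }
  groups <- unique(coverage$group)
  unknown <- setdiff(groups, names(taxonomy))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("no taxonomy template for group(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  np <- nrow(pairs)
  f_len <- nchar(pairs$forward_seq)
  r_len <- nchar(pairs$reverse_seq)
  block <- f_len + gap + r_len
  margin <- 30L
  spacer <- 20L
  starts <- margin + cumsum(c(0L, (block + spacer)[-np]))
  if (margin + sum(block) + spacer * (np - 1L) + margin > seq_length) {
    rlang::abort("planted primer sites do not fit: increase seq_length or reduce gap")
  }

  with_local_seed(seed, {
    refdb <- purrr::map_dfr(groups, function(g) {
      n_intact <- integer(np)
      for (i in seq_len(np)) {
        f <- coverage$coverage[coverage$pair == pairs$name[i] & coverage$group == g]
        f <- if (length(f) == 0) 1 else f
        n_intact[i] <- as.integer(round(f * n_per_group))
      }
      seqs <- vapply(seq_len(n_per_group), function(j) {
        s <- strsplit(random_dna(seq_length), "", fixed = TRUE)[[1]]
        for (i in seq_len(np)) {
          fwd_site <- realize_iupac(pairs$forward_seq[i])
          rev_pattern <- reverse_complement_iupac(pairs$reverse_seq[i])
          rev_site <- realize_iupac(rev_pattern)
          if (j > n_intact[i]) {
            fwd_site <- ablate_site(fwd_site, pairs$forward_seq[i], ablation_k, "right")
            rev_site <- ablate_site(rev_site, rev_pattern, ablation_k, "left")
          }
          fs <- starts[i]
          rs <- starts[i] + f_len[i] + gap
          s[fs:(fs + f_len[i] - 1L)] <- strsplit(fwd_site, "", fixed = TRUE)[[1]]
          s[rs:(rs + r_len[i] - 1L)] <- strsplit(rev_site, "", fixed = TRUE)[[1]]
        }
        paste(s, collapse = "")
      }, character(1))
      tibble::tibble(
        id = sprintf("%s_%04d", g, seq_len(n_per_group)),
        sequence = seqs,
        taxonomy = unname(taxonomy[g])
      )
    })

    truth <- coverage |>
      dplyr::mutate(coverage = round(.data$coverage * n_per_group) / n_per_group)
    eub <- truth |>
      dplyr::group_by(.data$pair) |>
      dplyr::summarise(coverage = mean(.data$coverage), .groups = "drop") |>
      dplyr::mutate(group = "EUB") |>
      dplyr::select("pair", "group", "coverage")
    list(refdb = refdb, truth = dplyr::bind_rows(truth, eub))
  })
}

#' Simulate qPCR replicate measurements under primer coverage bias
#'
#' Replicate `r` of (pair, group) is `coverage x abundance x e`, with `e` a
#' lognormal multiplicative error of mean 1 and coefficient of variation `cv`
#' (copy-number error is multiplicative on the log scale). `cv = 0` reduces
#' exactly to [theoretical_abundance()].
#'
#' @param coverage_tbl Tidy coverage tibble (`pair`, `group`, `coverage`).
#' @param community Tibble from [mock_community()].
#' @param cv Coefficient of variation of the multiplicative error (>= 0).
#' @param replicates Technical replicates per (pair, group); qPCR runs are
#'   conventionally triplicates.
#' @param seed Integer seed for reproducibility.
#' @return Tibble `pair`, `group`, `replicate`, `expected`, `measured`.
#' @export
simulate_qpcr <- function(coverage_tbl, community, cv = 0.1, replicates = 3,
                          seed = 1) {
  stopifnot(cv >= 0, replicates >= 1)
  theo <- theoretical_abundance(coverage_tbl, community)
  out <- tidyr::expand_grid(
    dplyr::select(theo, "pair", "group", expected = "measured"),
    replicate = seq_len(replicates)
  )
  sdlog <- sqrt(log(1 + cv^2))
  with_local_seed(seed, {
    noise <- if (cv == 0) 1 else stats::rlnorm(nrow(out), meanlog = -sdlog^2 / 2,
                                               sdlog = sdlog)
    dplyr::mutate(out, measured = .data$expected * noise)
  })
}

#' Generate a synthetic literature-survey record table
#'
#' Fabricates study records with a configurable number of distinct primer
#' pairs per target group and hits per pair, for exercising the survey
#' operations with known ground truth (e.g. planting the observed diversity
#' ordering AOB < DNB < NOB < AnAOB).
#'
#' @param group_pair_counts Named integer vector: distinct pairs per group.
#' @param mean_hits_per_pair Mean usage count per pair (>= 1; counts are
#'   1 + Poisson(mean - 1)).
#' @param seed Integer seed.
#' @return A study-record tibble.
#' @export
generate_survey_records <- function(group_pair_counts = c(
                                      AOB = 3, DNB = 8, NOB = 15, AnAOB = 24
                                    ),
                                    mean_hits_per_pair = 2, seed = 1) {
  stopifnot(mean_hits_per_pair >= 1)
  with_local_seed(seed, {
    purrr::imap_dfr(as.list(group_pair_counts), function(k, g) {
      pairs <- sprintf("%s_pair_%02d", g, seq_len(k))
      hits <- 1L + stats::rpois(k, mean_hits_per_pair - 1)
      purrr::map2_dfr(pairs, hits, function(p, h) {
        tibble::tibble(
          study = sprintf("synthetic_study_%s_%02d", p, seq_len(h)),
          year = sample(2006:2016, h, replace = TRUE),
          system = sample(c("PNA", "PN", "A"), h, replace = TRUE),
          target_group = g, pair = p, gene = "16S"
        )
      })
    })
  })
}
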