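test_that("single-site matching honours mismatch budget and 3' protection", {
  params00 <- match_params(0, 0)
  expect_identical(
    iupac_match_at("ACGT", "TTACGTTT", 2, params00),
    list(is_match = TRUE, mismatches = 0L)
  )
  # degenerate primer base covers the reference base
  expect_true(iupac_match_at("AYG", "ACG", 0, params00)$is_match)
  # one substitution inside the 3'-terminal 3 bases: counted and fatal even
  # with a 1-mismatch budget
  res <- iupac_match_at("ACGTAA", "ACGTAT", 0, match_params(1, 3))
  expect_identical(res, list(is_match = FALSE, mismatches = 1L))
  # the same budget tolerates a 5'-side substitution
  res5 <- iupac_match_at("ACGTAA", "TCGTAA", 0, match_params(1, 3))
  expect_identical(res5, list(is_match = TRUE, mismatches = 1L))
  # reverse orientation: the primer anneals as its reverse complement and its
  # 3' end is the left end of the footprint
  rev <- iupac_match_at("ACGTAA", reverse_complement_iupac("ACGTAA"), 0,
                        match_params(1, 3), orientation = "reverse")
  expect_identical(rev, list(is_match = TRUE, mismatches = 0L))
  rev_bad <- iupac_match_at("ACGTAA", "GTACGT", 0, match_params(1, 3),
                            orientation = "reverse")
  expect_false(rev_bad$is_match)
})

test_that("predict_amplicons finds planted products and nothing else", {
  set.seed(5)
  pair <- test_pair()
  s <- seq_with_sites(pair, total_len = 600, fwd_at = 100, product_len = 200)
  amp <- predict_amplicons(pair, s)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$start, 100L)
  expect_identical(amp$length, 200L)
  expect_identical(amp$end, 300L)

  # reference lacking the reverse site -> no product
  only_fwd <- splice_at(random_acgt(400), one_realization(pair$forward_seq), 50)
  expect_identical(nrow(predict_amplicons(pair, only_fwd)), 0L)

  # product window filters
  expect_identical(
    nrow(predict_amplicons(pair, s, match_params(min_product = 300))), 0L
  )

  # names-only pairs are unsupported
  expect_error(
    predict_amplicons(universal_primers()[1, ], s),
    "no primer sequences"
  )
})

test_that("engine agrees with the exhaustive-expansion oracle on random instances", {
  set.seed(301)
  for (i in 1:50) {
    pair <- primer_pair(
      sprintf("rnd%df-rnd%dr", i, i),
      forward_seq = random_degenerate_primer(sample(12:20, 1)),
      reverse_seq = random_degenerate_primer(sample(12:20, 1))
    )
    s <- random_acgt(500)
    # plant sites in most instances so the comparison exercises hits too
    if (i %% 4 != 0) {
      s <- splice_at(s, one_realization(pair$forward_seq), sample(0:150, 1))
      s <- splice_at(s, one_realization(reverse_complement_iupac(pair$reverse_seq)),
                     sample(250:450, 1))
    }
    if (i %% 7 == 0) { # occasionally a second forward site
      s <- splice_at(s, one_realization(pair$forward_seq), sample(160:240, 1))
    }
    params <- match_params(0, 0, min_product = 50, max_product = 2000)
    expect_identical(
      as.data.frame(predict_amplicons(pair, s, params)),
      as.data.frame(oracle_amplicons(pair, s, params))
    )
  }
})

test_that("coverage counts matched over eligible per group", {
  pair <- test_pair()
  spec <- tibble::tibble(
    pair = pair$name,
    group = c("AOB", "AnAOB"),
    coverage = c(0.8, 0)
  )
  db <- generate_reference_db(pair, spec, n_per_group = 100, seed = 21)
  res <- suppressWarnings(primer_coverage(pair, db$refdb))
  get <- function(g) res$coverage[res$group == g]
  expect_identical(get("AOB"), 0.8)
  # ablated in ALL group members -> coverage 0, not NA
  expect_identical(get("AnAOB"), 0)
  expect_identical(res$eligible[res$group == "AnAOB"], 100L)
  # groups without any reference are undefined, not zero
  expect_warning(primer_coverage(pair, db$refdb), "undefined")
  expect_true(is.na(get("DNB")))
  # EUB coverage equals the sequence-weighted mean of per-group coverages
  concrete <- res[res$group %in% c("AOB", "AnAOB"), ]
  expect_equal(
    get("EUB"),
    sum(concrete$coverage * concrete$eligible) / sum(concrete$eligible)
  )
})

test_that("coverage is monotone in the mismatch budget and protection", {
  set.seed(77)
  pair <- test_pair()
  # half the sites carry one internal substitution
  seqs <- vapply(1:40, function(j) {
    s <- seq_with_sites(pair, 600, 100, 200)
    if (j > 20) substr(s, 105, 105) <- setdiff(c("A", "C", "G", "T"),
                                               substr(s, 105, 105))[1]
    s
  }, character(1))
  db <- tibble::tibble(
    id = sprintf("s%02d", 1:40), sequence = seqs,
    taxonomy = synthetic_taxonomy_templates()[["AOB"]]
  )
  groups <- taxon_groups()[taxon_groups()$group == "AOB", ]
  cov_at <- function(mm, prot) {
    primer_coverage(pair, db, groups, match_params(mm, prot))$coverage
  }
  expect_lte(cov_at(0, 0), cov_at(1, 0))
  expect_lte(cov_at(1, 0), cov_at(2, 0))
  # protection can only remove matches
  expect_gte(cov_at(1, 0), cov_at(1, 19))
})

test_that("matching is strand-consistent", {
  set.seed(88)
  pair <- test_pair()
  spec <- tibble::tibble(pair = pair$name, group = "AOB", coverage = 0.6)
  db <- generate_reference_db(pair, spec, n_per_group = 30, seed = 3)
  groups <- taxon_groups()[taxon_groups()$group == "AOB", ]
  fwd_cov <- primer_coverage(pair, db$refdb, groups)$coverage
  # reverse-complement every reference and swap primer roles
  swapped <- primer_pair(pair$name, pair$reverse_seq, pair$forward_seq)
  db_rc <- dplyr::mutate(
    db$refdb,
    sequence = vapply(sequence, reverse_complement_iupac, character(1),
                      USE.NAMES = FALSE)
  )
  expect_identical(primer_coverage(swapped, db_rc, groups)$coverage, fwd_cov)
})

test_that("coverage_matrix is a pure reshape", {
  tbl <- tibble::tibble(
    pair = rep(c("p1", "p2"), each = 2),
    group = rep(c("AOB", "AnAOB"), 2),
    coverage = c(0.1, 0.2, 0.3, 0.4)
  )
  wide <- coverage_matrix(tbl)
  expect_identical(names(wide), c("pair", "AOB", "AnAOB"))
  expect_identical(wide$AnAOB, c(0.2, 0.4))
  # permuting group order permutes columns only
  wide2 <- coverage_matrix(tbl[c(2, 1, 4, 3), ])
  expect_identical(names(wide2), c("pair", "AnAOB", "AOB"))
  expect_identical(wide2$AOB, wide$AOB)
})

test_that("reference db round-trips through FASTA + taxonomy TSV", {
  skip_if_not_installed("Biostrings")
  pair <- test_pair()
  spec <- tibble::tibble(pair = pair$name, group = "AnAOB", coverage = 1)
  db <- generate_reference_db(pair, spec, n_per_group = 5, seed = 9)
  fa <- withr::local_tempfile(fileext = ".fasta")
  tx <- withr::local_tempfile(fileext = ".tsv")
  write_reference_db(db$refdb, fa, tx)
  back <- read_reference_db(fa, tx)
  expect_identical(as.data.frame(back), as.data.frame(db$refdb))
})
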