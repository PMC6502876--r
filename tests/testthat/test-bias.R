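hypothetical <- mock_community("pna_hypothetical")

test_that("theoretical abundance is coverage times true abundance", {
  cov <- reported_eub_coverage()
  theo <- theoretical_abundance(cov, hypothetical)
  pick <- function(p, g) theo$measured[theo$pair == p & theo$group == g]
  # 0.830 coverage on 4.00e9 AnAOB copies/mL
  expect_equal(pick("1055f-1392r", "AnAOB"), 3.32e9)
  # zero coverage annihilates any abundance; full coverage is the identity
  expect_identical(pick("338f-518r", "AnAOB"), 0)
  one <- theoretical_abundance(
    tibble::tibble(pair = "p", group = "EUB", coverage = 1), hypothetical
  )
  expect_identical(one$measured, 1e10)
  # linear in the community
  theo2 <- theoretical_abundance(cov, mock_community(scale = 2.5))
  expect_equal(theo2$measured, 2.5 * theo$measured)
  # missing community entry is a keyed error
  expect_error(
    theoretical_abundance(
      tibble::tibble(pair = "p", group = "DNB", coverage = 0.5), hypothetical
    ),
    "DNB"
  )
})

test_that("relative abundance normalizes per pair to measured EUB", {
  cov <- reported_eub_coverage()
  theo <- theoretical_abundance(cov, hypothetical)
  rel <- relative_abundance(theo)
  expect_false("EUB" %in% rel$group)
  # AnAOB/EUB with the most-used pair: 3.32e9 / 4.45e9
  r <- rel$relative[rel$pair == "1055f-1392r" & rel$group == "AnAOB"]
  expect_equal(r, 3.32e9 / 4.45e9)
  expect_equal(round(r, 3), 0.746)
  # measured 0 -> relative 0
  expect_identical(rel$relative[rel$pair == "338f-518r" & rel$group == "AnAOB"], 0)
  # group coverage above EUB coverage at equal true abundance exceeds 1
  cov2 <- tibble::tibble(
    pair = "p", group = c("EUB", "AnAOB"), coverage = c(0.4, 0.9)
  )
  comm2 <- mock_community(abundances = c(EUB = 1e9, AnAOB = 1e9))
  expect_warning(
    rel2 <- relative_abundance(theoretical_abundance(cov2, comm2)),
    "exceeds 1"
  )
  expect_equal(rel2$relative, 2.25)
  # rescaling the whole community leaves relative abundance unchanged
  rel3 <- relative_abundance(theoretical_abundance(cov2 |>
    dplyr::slice(1:2), mock_community(abundances = c(EUB = 7e9, AnAOB = 7e9)))) |>
    suppressWarnings()
  expect_equal(rel3$relative, rel2$relative)
  # zero EUB measurement is flagged undefined, not dropped
  cov0 <- tibble::tibble(pair = "p", group = c("EUB", "AOB"), coverage = c(0, 0.5))
  expect_warning(
    rel0 <- relative_abundance(theoretical_abundance(cov0, hypothetical)),
    "undefined"
  )
  expect_true(is.na(rel0$relative))
})

test_that("percentage dissimilarity matches the Bray-Curtis oracle and its axioms", {
  # hand-computed: |4.45 - 7.00| / (4.45 + 7.00) x 100
  expect_equal(percent_dissimilarity(4.45e9, 7.00e9),
               100 * abs(4.45 - 7.00) / (4.45 + 7.00))
  expect_equal(round(percent_dissimilarity(4.45e9, 7.00e9), 2), 22.27)
  expect_identical(percent_dissimilarity(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_identical(percent_dissimilarity(c(1, 0), c(0, 1)), 100)
  expect_warning(d0 <- percent_dissimilarity(c(0, 0), c(0, 0)), "all-zero")
  expect_true(is.na(d0))
  expect_error(percent_dissimilarity(c(-1, 2), c(1, 2)), "non-negative")

  set.seed(19)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    x <- stats::runif(n, 0, 10)
    y <- stats::runif(n, 0, 10)
    d <- percent_dissimilarity(x, y)
    expect_gte(d, 0); expect_lte(d, 100)
    expect_equal(d, percent_dissimilarity(y, x))
    expect_equal(percent_dissimilarity(x, x), 0)
    c_ <- stats::runif(1, 0.1, 50)
    expect_equal(percent_dissimilarity(c_ * x, c_ * y), d)
  }
})

test_that("percentage dissimilarity agrees with vegan's Bray-Curtis", {
  skip_if_not_installed("vegan")
  set.seed(23)
  for (i in 1:20) {
    x <- stats::runif(5, 0, 10); y <- stats::runif(5, 0, 10)
    expect_equal(
      percent_dissimilarity(x, y),
      100 * as.numeric(vegan::vegdist(rbind(x, y), method = "bray"))
    )
  }
})

test_that("pairwise dissimilarity covers all unordered pair combinations", {
  set.seed(31)
  m <- tidyr::expand_grid(
    sample = c("TUD1", "TUD2"),
    pair = c("pp1", "pp2", "pp3"),
    replicate = 1:3
  )
  m$measured <- stats::runif(nrow(m), 1e8, 1e10)
  d <- pairwise_dissimilarity(m)
  expect_identical(nrow(d), 6L) # C(3,2) per sample
  # entries match elementwise calls
  for (j in seq_len(nrow(d))) {
    sub <- m[m$sample == d$sample[j], ]
    x <- sub$measured[sub$pair == d$pair_x[j]][order(sub$replicate[sub$pair == d$pair_x[j]])]
    y <- sub$measured[sub$pair == d$pair_y[j]][order(sub$replicate[sub$pair == d$pair_y[j]])]
    expect_equal(d$dissimilarity[j], percent_dissimilarity(x, y))
  }
  # duplicated measurement vectors -> all zero
  m2 <- m
  m2$measured <- stats::runif(6, 1, 10)[
    as.integer(factor(paste(m2$sample, m2$replicate)))
  ]
  d2 <- pairwise_dissimilarity(m2)
  expect_true(all(d2$dissimilarity == 0))
  # a single pair yields an empty combination set, not an error
  d1 <- pairwise_dissimilarity(m[m$pair == "pp1", ])
  expect_identical(nrow(d1), 0L)
})

test_that("two-way ANOVA without replication matches the classical decomposition", {
  # textbook randomized-block layout, cross-checked against stats::aov
  set.seed(47)
  tbl <- tidyr::expand_grid(a = paste0("A", 1:3), b = paste0("B", 1:4))
  tbl$y <- stats::rnorm(12, mean = rep(1:3, each = 4), sd = 1)
  fit <- anova_two_way_no_rep(tbl, "y", "a", "b")
  ref <- summary(stats::aov(y ~ a + b, data = tbl))[[1]]
  td <- tidy(fit)
  expect_equal(td$df, c(2L, 3L, 6L))
  expect_equal(td$sumsq, ref[["Sum Sq"]], tolerance = 1e-10)
  expect_equal(td$statistic[1:2], ref[["F value"]][1:2], tolerance = 1e-10)
  expect_equal(td$p.value[1:2], ref[["Pr(>F)"]][1:2], tolerance = 1e-10)

  # identical rows: no row effect at all
  flat <- tidyr::expand_grid(a = c("r1", "r2"), b = paste0("c", 1:3))
  flat$y <- rep(c(1, 5, 2), times = 2)
  td_flat <- tidy(anova_two_way_no_rep(flat, "y", "a", "b"))
  expect_identical(td_flat$statistic[td_flat$term == "a"], 0)
  expect_identical(td_flat$p.value[td_flat$term == "a"], 1)

  # permuting factor levels leaves F unchanged
  perm <- tbl[sample(nrow(tbl)), ]
  expect_equal(tidy(anova_two_way_no_rep(perm, "y", "a", "b"))$statistic,
               td$statistic)

  # missing cells are an error, not imputed
  expect_error(anova_two_way_no_rep(tbl[-1, ], "y", "a", "b"), "complete")
})

test_that("the worked bias example yields a significant main effect", {
  theo <- theoretical_abundance(reported_eub_coverage(), hypothetical)
  fit <- anova_two_way_no_rep(theo, "measured", "pair", "group")
  expect_lt(glance(fit)$p.value.min, 0.01)
})

test_that("one-way ANOVA matches the two-sample t-test identity and flags degeneracy", {
  set.seed(53)
  d <- tibble::tibble(
    g = rep(c("x", "y"), each = 6),
    v = c(stats::rnorm(6, 0), stats::rnorm(6, 1))
  )
  fit <- anova_one_way(d, "v", "g")
  tt <- stats::t.test(v ~ g, data = d, var.equal = TRUE)
  td <- tidy(fit)
  expect_equal(td$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(td$p.value[1], tt$p.value, tolerance = 1e-10)

  # all-constant groups: zero within-variance, F undefined and flagged
  const <- tibble::tibble(g = rep(c("x", "y"), each = 3), v = rep(2, 6))
  expect_warning(fit0 <- anova_one_way(const, "v", "g"), "undefined")
  expect_true(is.na(tidy(fit0)$statistic[1]))

  # groups with a single replicate are an error
  expect_error(anova_one_way(d[-(1:5), ], "v", "g"), "fewer than 2")
})

test_that("a 2-fold primer effect at 5% CV is detected in nearly all runs", {
  detected <- vapply(1:200, function(i) {
    sim <- simulate_qpcr(
      tibble::tibble(pair = c("pp1", "pp2"), group = "EUB",
                     coverage = c(0.5, 1.0)),
      mock_community(abundances = c(EUB = 1e9)),
      cv = 0.05, replicates = 3, seed = 1000 + i
    )
    tidy(anova_one_way(sim, "measured", "pair"))$p.value[1] < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})
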