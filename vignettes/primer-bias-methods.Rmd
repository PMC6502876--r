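---
title: "Primer coverage bias in PNA community quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer coverage bias in PNA community quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primerbias)
library(dplyr)
```

## The problem

Partial nitritation anammox (PNA) reactors host a characteristic consortium:
ammonium-oxidizing bacteria (AOB), anaerobic ammonium-oxidizing bacteria
(AnAOB), nitrite oxidizers (Nitrobacter, Nitrospira) and denitrifiers (DNB).
PCR-based methods — qPCR and 16S rRNA amplicon sequencing — are the standard
tools for quantifying these guilds, and both stand or fall with the primer
pair. A primer pair only ever reports the fraction of a guild whose 16S rRNA
gene it can actually anneal to and amplify: its *coverage*. Different
published studies use different primer pairs with very different coverages,
so their absolute and relative abundance numbers are not directly comparable,
and normalizing a group-specific measurement to a "total bacteria" (EUB)
measurement taken with an independently biased primer pair can mislead
badly.

`primerbias` makes this chain of reasoning computable: a degenerate-primer
in-silico PCR engine measures coverage per taxon group against a reference
collection; a propagation layer turns coverage plus a known community into
the theoretical measurements a perfectly efficient qPCR would report; a
dissimilarity and ANOVA layer quantifies how strongly primer choice moves
those measurements; a survey layer counts primer usage across studies; and a
decision-tree rule engine encodes study-design recommendations.

## In-silico PCR model

A degenerate primer is an IUPAC string; position $i$ of the primer is
compatible with a reference base $b$ when $b$ is in the IUPAC set of the
primer's code. The engine scans only the forward strand of each reference
record (rRNA gene records are stored 5'→3' by convention), using the forward
primer as given and the reverse primer as its reverse complement. A site
anneals when

* the number of incompatible positions is at most `max_mismatches`, and
* no incompatible position falls within the `protected_3prime_len` terminal
  bases of the primer's 3' end (elongation starts there, so terminal
  mismatches are disproportionately fatal; note that for a reverse primer the
  3' end is the *left* end of its footprint on the scanned strand).

An amplicon is any forward site paired with any downstream reverse site whose
product length falls in `[min_product, max_product]`. Coordinates are 0-based
and half-open throughout, which keeps length arithmetic free of off-by-one
cases. Ambiguity codes in the *reference* are matched literally: a reference
`N` satisfies only a primer `N`. Defaults are `max_mismatches = 0`,
`protected_3prime_len = 0` and a 50–2000 bp product window: published
TestPrime-style analyses rarely report their settings, and exact matching is
the most conservative choice; every parameter is user-settable, and the test
suite plants binding sites so that its expectations hold under any protected
mismatch setting.

Coverage for a (pair, group) is `matched / eligible`, where eligible group
members are those whose record spans both primer loci (a record must either
amplify or at least be long enough to contain both footprints — and reach the
positional window when the pair name carries E. coli coordinates). Truncated
records therefore leave the denominator rather than masquerading as
non-targets, and a group with no eligible members yields an *undefined*
coverage (`NA`, flagged), never a silent zero.

The engine is verified against an exhaustive-expansion oracle: expand both
degenerate primers into every concrete sequence (at degeneracy ≤ 1024) and
substring-scan. The two routes share no code.

## Propagating coverage into quantification bias

For true abundance $A_g$ (16S gene copies/mL) and coverage $c_{p,g}$, the
theoretical measurement is $M_{p,g} = c_{p,g} A_g$ — linear in the community
and monotone in coverage. Relative abundance divides by the same pair's EUB
measurement, $M_{p,g}/M_{p,\mathrm{EUB}}$; because the group and EUB primers
have independent coverages this quotient can exceed 1, which is exactly why
the package warns whenever it does and why the decision framework warns
against the normalization altogether. Relative abundances are kept as
fractions internally and only rendered as percentages in figures, avoiding
unit drift.

Percentage dissimilarity between the measurement vectors of two primer pairs
is Bray–Curtis scaled to 0–100:
$D(x,y) = 100\,\sum_i |x_i - y_i| \big/ \sum_i (x_i + y_i)$.
SIMPER analyses report per-taxon contributions to exactly this total; for a
two-sample comparison the total *is* Bray–Curtis, which is why the package
implements the total directly (and cross-checks it against `vegan`). It is
symmetric, bounded, zero only on identical vectors, and invariant to a common
positive rescaling; two all-zero vectors have undefined dissimilarity
(flagged `NA`).

Significance testing uses classical ANOVA on raw (untransformed)
measurements. The pair × group theoretical table has one observation per
cell, so the two-way decomposition without replication applies
($\mathrm{SS}_A$, $\mathrm{SS}_B$, residual with $(a-1)(b-1)$ df, no
interaction estimable) and the headline check reads the minimum of the two
main-effect p-values — the weakest reproducible reading when the original
report does not say which effect it tested. With the packaged SILVA132
coverages and the hypothetical community the group effect gives
p ≈ 0.0064. Degenerate inputs are handled explicitly: a zero effect sum of
squares is reported as F = 0, p = 1 in the two-way layout, while a one-way
table with zero within-group variance flags F as undefined rather than
dividing by zero.

```{r anova}
theo <- theoretical_abundance(reported_eub_coverage(), mock_community())
glance(anova_two_way_no_rep(theo, "measured", "pair", "group"))
```

## What the synthetic generator emulates — and what it does not

`generate_reference_db()` stands in for a curated 16S database. Per group it
draws `n_per_group` i.i.d. random sequences (default length 800 nt — long
enough to hold several planted site blocks, far shorter than a real 16S gene
is not an issue because only the sites matter) and plants one forward and one
reverse binding site per primer pair in disjoint blocks, 60 nt apart by
default (a ~100 bp product, comfortably inside the default window). For a
target fraction $f$, exactly `round(f·n)` members keep intact sites; the rest
receive 2 substitutions per site, placed in the 3'-proximal zone and chosen
*outside* the primer's IUPAC set, so an ablated site fails under exact
matching and under any mismatch model with at least one protected terminal
base — the planted truth is invariant to reasonable `match_params` choices.
Every generator is a pure function of its seed.

EUB (domain Bacteria) spans all groups, so its coverage cannot be planted
independently: it is the sequence-weighted mean of the per-group fractions,
and the emitted truth table carries that derived row. The qPCR simulator
multiplies each theoretical measurement by lognormal noise with mean 1 and a
chosen coefficient of variation (copy-number error is multiplicative on the
log scale), defaulting to technical triplicates at CV 0.1; CV 0 reduces
exactly to the theoretical values.

What passing tests on this material shows: the matching engine, the coverage
arithmetic, the propagation algebra and the statistics behave exactly as
specified on data with known truth. What it does not show: agreement with
any particular curated database release. Published coverage percentages
depend on the database version and on unreported matching settings, so the
package treats them as *inputs* (`reported_eub_coverage()`), never as
targets for the engine. Real 16S genes also have conserved/variable
structure, correlated lineages, chimeras and length variation that i.i.d.
backgrounds do not emulate — coverage on real data should be computed on a
real reference export, which `read_reference_db()` accepts in FASTA +
taxonomy-TSV form.

## Literature survey semantics

A *hit* is one recorded usage of a primer pair by one study for one target
group; a study may contribute zero or many hits per group. Ranking is by
descending hits with alphabetical tie-break (deterministic output). The full
multi-study usage table exists only as supplementary material in the
literature, so the package ships the faithful eight-pair universal-primer
transcription (with hit counts summing to 31) plus two synthetic routes:
`hits_to_records()` expands hit counts into per-study records (labelled
synthetic), and `generate_survey_records()` fabricates a survey with
configurable per-group pair diversity — e.g. the observed ordering
AOB < DNB < NOB < AnAOB.

## The decision framework as data

Study-design recommendations are a rule *table*
(`inst/extdata/decision_rules.tsv`), not code branches, so the wiring can be
inspected and diffed: each row maps one objective field/value to a method
choice, guidance item, required check or warning. The stated rules are:
relative quantification → 16S amplicon sequencing, absolute → qPCR;
comparison with other studies → use their exact primer pairs; dynamics
studies → evaluate primers in silico and interpret against a within-reactor
reference sample; gel-electrophoresis product verification except for
degenerate primers; an in-silico coverage check always; and a warning
whenever normalization to total EUB is requested. Branches of the framework
for which no explicit recommendation is documented (the per-question
branches: presence / richness / evenness) are carried with provenance
`"unspecified"` and excluded from stated guidance rather than guessed. The
objective space is finite (48 cases) and `recommend()` is a deterministic,
total function over it.

## Numerical and design choices

* Positional pair names (`1055f-1392r`) are parsed by stripping non-digit
  prefixes; the implied length `reverse − forward` is only a convention, so a
  printed length always wins and a disagreement raises a flag (one pair in
  the packaged registry, 519f-907r: 388 vs 391).
* `U` is normalized to `T` and matching is case-insensitive; invalid
  characters error with their positions.
* Planted-coverage counts use `round(f·n)` (R's round-half-even); the truth
  table applies the same rounding, so recovery comparisons are exact.
* Problem sizes used by the packaged checks: 200 sequences per group for
  coverage recovery, 50 random primer/sequence instances for the oracle
  comparison, 1000 random vector pairs for the dissimilarity axioms, and
  10,000 simulated replicates (mean within 3 standard errors at CV 0.1) for
  the pipeline calibration.

## Limitations

No thermodynamics: annealing is a combinatorial mismatch model, not a melting
model; primer dimers, amplification efficiency and sequencing chemistry are
out of scope. The survey fixtures reproduce counts, not bibliographies. The
engine's percentages on synthetic collections say nothing about any specific
database release — they are designed to be exactly right about planted truth,
which is the property a bias analysis needs.
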