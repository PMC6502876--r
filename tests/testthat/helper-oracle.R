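# Shared fixtures and the exhaustive-expansion oracle the in-silico engine is
# checked against. The oracle expands both degenerate primers to every
# concrete realization and substring-scans: deliberately naive, and
# independent of the engine's bitmask path. Exact matching only.

oracle_sites <- function(patterns, sequence) {
  k <- nchar(patterns[1])
  L <- nchar(sequence)
  if (L < k) return(integer(0))
  offs <- 0:(L - k)
  hits <- substring(sequence, offs + 1, offs + k) %in% patterns
  offs[hits]
}

oracle_amplicons <- function(pair, sequence, params = match_params()) {
  fwd <- expand_degenerate(pair$forward_seq)
  rev_rc <- expand_degenerate(reverse_complement_iupac(pair$reverse_seq))
  f <- oracle_sites(fwd, sequence)
  r <- oracle_sites(rev_rc, sequence)
  k_r <- nchar(pair$reverse_seq)
  out <- expand.grid(start = f, r_start = r, KEEP.OUT.ATTRS = FALSE)
  out$end <- out$r_start + k_r
  out$length <- out$end - out$start
  out <- out[out$length >= params$min_product & out$length <= params$max_product,
             c("start", "end", "length"), drop = FALSE]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

# a random degenerate primer with bounded total degeneracy
random_degenerate_primer <- function(len = 18, p_degenerate = 0.15,
                                     max_degeneracy = 1024) {
  codes <- names(primerbias:::IUPAC_SETS)
  deg_codes <- setdiff(codes, c("A", "C", "G", "T"))
  repeat {
    chars <- ifelse(
      stats::runif(len) < p_degenerate,
      sample(deg_codes, len, replace = TRUE),
      sample(c("A", "C", "G", "T"), len, replace = TRUE)
    )
    s <- paste(chars, collapse = "")
    if (degeneracy(s) <= max_degeneracy) return(s)
  }
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# pick one concrete realization of a degenerate pattern
one_realization <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(vapply(primerbias:::IUPAC_SETS[chars], function(s) sample(s, 1),
               character(1)), collapse = "")
}

# splice a string into a sequence at a 0-based offset
splice_at <- function(sequence, insert, offset) {
  paste0(substr(sequence, 1, offset),
         insert,
         substr(sequence, offset + nchar(insert) + 1, nchar(sequence)))
}

# fixed synthetic primer pair used across engine tests (degenerate on purpose)
test_pair <- function(name = "syn100f-syn300r") {
  primer_pair(
    name,
    forward_seq = "ACGGTYCACGTAGCWAGCT",
    reverse_seq = "TGCCATRCACGTTCGATTG",
    target_group = "AOB"
  )
}

# reference sequence carrying one intact site pair: forward at `fwd_at`,
# product of `product_len` bp
seq_with_sites <- function(pair, total_len = 600, fwd_at = 100,
                           product_len = 200) {
  s <- random_acgt(total_len)
  fwd <- one_realization(pair$forward_seq)
  rev_rc <- one_realization(reverse_complement_iupac(pair$reverse_seq))
  s <- splice_at(s, fwd, fwd_at)
  rev_at <- fwd_at + product_len - nchar(rev_rc)
  splice_at(s, rev_rc, rev_at)
}
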