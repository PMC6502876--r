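# IUPAC nucleotide algebra: the primitive layer under degenerate-primer
# matching. Codes are represented internally as 4-bit masks (A=1, C=2, G=4,
# T=8) so that "reference base is compatible with primer base" is a single
# bitwAnd() != 0 test.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# bit mask per code, in a fixed vector indexed by code letter
.iupac_masks <- local({
  base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(IUPAC_SETS, function(b) sum(base_bits[b]), integer(1))
})

#' Normalize a nucleotide string to uppercase IUPAC DNA
#'
#' Uppercases and converts U to T (primer and reference sequences derived
#' from rRNA are often written as RNA). Errors on any character outside the
#' 15 IUPAC nucleotide codes, reporting the offending positions.
#'
#' @param sequence A nucleotide character scalar.
#' @param what Label used in error messages.
#' @return The normalized string.
#' @export
normalize_sequence <- function(sequence, what = "sequence") {
  if (!rlang::is_string(sequence)) {
    rlang::abort(sprintf("%s must be a single character string", what))
  }
  s <- chartr("u", "U", toupper(sequence))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "%s contains non-IUPAC character(s) %s at position(s) %s",
      what,
      paste(unique(chars[bad]), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  s
}

# integer mask vector for a normalized sequence
iupac_mask <- function(sequence) {
  unname(.iupac_masks[strsplit(sequence, "", fixed = TRUE)[[1]]])
}

#' Per-position degeneracy of an IUPAC string
#'
#' @param sequence IUPAC nucleotide string.
#' @return Integer: the product of per-position code cardinalities, i.e. the
#'   number of concrete A/C/G/T sequences the pattern stands for.
#' @export
degeneracy <- function(sequence) {
  s <- normalize_sequence(sequence)
  if (nchar(s) == 0) return(1L)
  d <- prod(lengths(IUPAC_SETS[strsplit(s, "", fixed = TRUE)[[1]]]))
  if (d <= .Machine$integer.max) as.integer(d) else d
}

#' Expand a degenerate IUPAC string to all concrete sequences
#'
#' Enumerates every A/C/G/T string compatible with the pattern. The result
#' has exactly `degeneracy(sequence)` elements.
#'
#' @param sequence IUPAC nucleotide string.
#' @return Character vector of concrete sequences (sorted, unique).
#' @export
#' @examples
#' expand_degenerate("ACR") # "ACA" "ACG"
expand_degenerate <- function(sequence) {
  s <- normalize_sequence(sequence)
  if (nchar(s) == 0) return("")
  sets <- IUPAC_SETS[strsplit(s, "", fixed = TRUE)[[1]]]
  grid <- expand.grid(sets, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  sort(do.call(paste0, grid))
}

#' Reverse complement of an IUPAC string
#'
#' Complements degenerate codes correctly (R<->Y, K<->M, B<->V, D<->H; S, W
#' and N are self-complementary) and reverses. An involution: applying it
#' twice returns the input.
#'
#' @param sequence IUPAC nucleotide string.
#' @return The reverse complement, same length, uppercase.
#' @export
#' @examples
#' reverse_complement_iupac("AAR") # "YTT"
reverse_complement_iupac <- function(sequence) {
  s <- normalize_sequence(sequence)
  if (nchar(s) == 0) return("")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}
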