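#' Default COI primer sets
#'
#' The three primer sets used throughout the package examples: MFZR, ZFZR and
#' LFCR. All three amplify largely overlapping windows of the 5' COI barcode
#' region (~150 bp amplicons), which is what makes cross-marker contig merging
#' possible. Primer sequences are written 5'->3' in primer orientation and may
#' contain IUPAC degeneracy codes.
#'
#' @return A tibble with columns `marker`, `fwd_primer`, `rev_primer`.
#' @examples
#' default_markers()
#' @export
default_markers <- function() {
  tibble::tibble(
    marker     = c("MFZR", "ZFZR", "LFCR"),
    fwd_primer = c(
      "TCCACTAATCACAARGATATTGGTAC",
      "AGATATTGGAACWTTATATTTTATTTTTGG",
      "RKTCAACMAATCATAAAGATATTGG"
    ),
    rev_primer = c(
      "WACTAATCAATTWCCAAATCCTCC",
      "WACTAATCAATTWCCAAATCCTCC",
      "CCBCCRATTAWAATKGGTATHAC"
    )
  )
}

# IUPAC code -> set of matching bases
iupac_table <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"),
    H = c("A", "C", "T"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "T")
  )
}

is_iupac <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% names(iupac_table()))
}

is_acgt <- function(x) {
  !grepl("[^ACGT]", x)
}

#' Reverse-complement of a nucleotide string (IUPAC-aware)
#' @param x A character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming mismatches between an IUPAC pattern and an ACGT string of equal
# length; a position matches when the observed base is in the pattern's set.
iupac_mismatches <- function(pattern, x) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(x), "")[[1]]
  stopifnot(length(p) == length(s))
  tab <- iupac_table()
  sum(!purrr::map2_lgl(p, s, function(pc, sc) sc %in% tab[[pc]]))
}

validate_markers <- function(markers) {
  stopifnot(is.data.frame(markers),
            all(c("marker", "fwd_primer", "rev_primer") %in% names(markers)))
  if (nrow(markers) < 1) stop("marker set must contain at least one marker")
  if (anyDuplicated(markers$marker)) stop("marker names must be unique")
  ok <- vapply(markers$fwd_primer, is_iupac, logical(1)) &
    vapply(markers$rev_primer, is_iupac, logical(1))
  if (!all(ok)) {
    stop("non-IUPAC characters in primers of marker(s): ",
         paste(markers$marker[!ok], collapse = ", "))
  }
  invisible(markers)
}
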