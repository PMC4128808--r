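#' The 20 standard amino acids, alphabetical by three-letter code
#'
#' Fixed residue alphabet used throughout the package. All contact-type
#' indexing is defined relative to this ordering.
#'
#' @format Character vector of 20 three-letter residue codes.
#' @export
AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Ambiguous / non-standard codes that disqualify a chain during curation.
AMBIGUOUS_AA3 <- c("ASX", "GLX", "XLE", "XAA", "UNK")

#' Names of the 210 unordered residue-pair contact types
#'
#' Row-major upper triangle (diagonal included) over [AA3]: ALA-ALA,
#' ALA-ARG, ..., ALA-VAL, ARG-ARG, ..., VAL-VAL. This is the canonical
#' column order of every contact-vector table written by the package.
#'
#' @return Character vector of length 210, e.g. `"ALA-GLY"`.
#' @export
contact_type_names <- function() {
  out <- character(210L)
  k <- 0L
  for (a in seq_len(20L)) {
    for (b in a:20L) {
      k <- k + 1L
      out[k] <- paste0(AA3[a], "-", AA3[b])
    }
  }
  out
}

#' Map unordered residue-type pairs to contact-type indices
#'
#' The index is symmetric in its arguments and bijective over the 210
#' unordered pairs of the 20 standard residue types.
#'
#' @param a,b Vectors of residue codes (three-letter) or integer indices
#'   into [AA3] (1..20). Recycled to common length.
#' @return Integer vector of 1-based contact-type indices in 1..210.
#' @export
contact_type_index <- function(a, b) {
  ia <- aa_index(a)
  ib <- aa_index(b)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  # offset of row `lo` in the row-major upper triangle (diagonal included):
  # rows 1..lo-1 hold 20, 19, ... entries
  (lo - 1L) * 21L - (lo * (lo - 1L)) %/% 2L + (hi - lo) + 1L
}

# residue code(s) -> 1..20; errors on anything outside the standard alphabet
aa_index <- function(x) {
  if (is.numeric(x)) {
    ix <- as.integer(x)
    if (any(ix < 1L | ix > 20L)) stop("residue index out of range 1..20")
    return(ix)
  }
  ix <- match(toupper(as.character(x)), AA3)
  if (anyNA(ix)) {
    bad <- unique(x[is.na(ix)])
    stop("nonstandard residue code(s): ", paste(bad, collapse = ", "))
  }
  ix
}
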