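`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_domain <- function(...) stop(sprintf(...), call. = FALSE)

#' Three-letter codes of the 20 standard amino acids
#' @noRd
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

#' Single-letter ribonucleotide codes
#' @noRd
NT1 <- c("A", "C", "G", "U")

#' Atomic masses (amu) by element symbol
#' @noRd
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06)

#' Derive an element symbol from a PDB atom name.
#'
#' Strips digits and primes, takes the leading letter; two-letter elements
#' other than the organic set do not occur in standard residues.
#' @noRd
element_from_name <- function(name) {
  s <- gsub("[0-9']", "", trimws(name))
  substr(s, 1L, 1L)
}

#' Euclidean distance between rows of two coordinate matrices
#' @noRd
cross_dist <- function(a, b) {
  # a: n x 3, b: m x 3 -> n x m
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
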