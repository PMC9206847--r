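#' Standard alphabets
#'
#' Ordered alphabets used by the natural-vector machinery. The DNA alphabet
#' treats T and U as a single letter (U is mapped to T on input); the protein
#' alphabet is the 20 amino acids in the conventional one-letter order used
#' for the 250-dimensional protein vector.
#'
#' @return Character vector of single letters (or k-mers for
#'   [kmer_alphabet()]), in canonical order.
#' @export
dna_alphabet <- function() c("A", "C", "G", "T")

#' @rdname dna_alphabet
#' @export
protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' @rdname dna_alphabet
#' @param k word length; the k-mer alphabet is all 4^k DNA words in
#'   lexicographic order.
#' @export
kmer_alphabet <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 1, k == round(k))
  words <- dna_alphabet()
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      words <- as.vector(t(outer(words, dna_alphabet(), paste0)))
    }
  }
  sort(words)
}

check_alphabet <- function(alphabet) {
  if (!is.character(alphabet) || length(alphabet) < 1) {
    stop("alphabet must be a non-empty character vector", call. = FALSE)
  }
  if (anyDuplicated(alphabet)) {
    stop("alphabet letters must be distinct", call. = FALSE)
  }
  invisible(alphabet)
}
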