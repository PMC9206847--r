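#' Indicator vectors of letter occupancy
#'
#' `indicator()` returns the binary occupancy vector of a single letter along
#' a sequence; `pair_indicator()` the occupancy of either of two distinct
#' letters. Positions are 1-based. Characters outside the alphabet occupy
#' positions but match no letter.
#'
#' @param seq a single residue string (already normalized, see
#'   [read_fasta()]), or a one-row `nv_sequences`.
#' @param letter,k,l single letters of the alphabet.
#' @param alphabet ordered alphabet; defaults to [dna_alphabet()].
#' @return integer vector of 0/1 of length `nchar(seq)`.
#' @examples
#' indicator("ACGGTAGTCC", "A")       # 1 0 0 0 0 1 0 0 0 0
#' pair_indicator("ACGGTAGTCC", "A", "C")
#' @export
indicator <- function(seq, letter, alphabet = dna_alphabet()) {
  ch <- seq_chars(seq)
  if (!letter %in% alphabet) {
    stop("letter '", letter, "' is not in the alphabet", call. = FALSE)
  }
  as.integer(ch == letter)
}

#' @rdname indicator
#' @export
pair_indicator <- function(seq, k, l, alphabet = dna_alphabet()) {
  if (identical(k, l)) {
    stop("k and l must differ; use indicator() for a single letter",
         call. = FALSE)
  }
  for (x in c(k, l)) {
    if (!x %in% alphabet) {
      stop("letter '", x, "' is not in the alphabet", call. = FALSE)
    }
  }
  ch <- seq_chars(seq)
  as.integer(ch == k | ch == l)
}

#' Scalar natural-vector components
#'
#' Building blocks of the natural vector for one sequence: the count
#' \eqn{n_k}, the mean 1-based position \eqn{\mu_k}, the normalized j-th
#' central moment of position \eqn{D_j^k = \sum_i (i-\mu_k)^j w_k(s_i) /
#' (n_k^{j-1} n^{j-1})}, and the positional covariance of two letters
#' \eqn{Cov(k,l) = \sum_i (i-\mu_k)(i-\mu_l) w_{kl}(s_i) /
#' (n \sqrt{n_k} \sqrt{n_l})}, where n is the full sequence length and
#' \eqn{w_{kl}} indicates positions carrying either letter. By construction
#' `nv_covariance(seq, k, k)` equals `central_moment(seq, k, 2)`.
#'
#' When a letter is absent from the sequence its mean position, central
#' moment and covariances are defined as 0 (see the package vignette).
#'
#' @inheritParams indicator
#' @param j moment order (j = 2 feeds the standard vectors).
#' @return a single numeric value.
#' @examples
#' nv_count("ACGGTAGTCC", "A")          # 2
#' mean_position("ACGGTAGTCC", "A")     # 3.5
#' central_moment("ACGGTAGTCC", "A", 2) # 0.625
#' nv_covariance("ACGGTAGTCC", "A", "C")
#' @export
nv_count <- function(seq, letter, alphabet = dna_alphabet()) {
  sum(indicator(seq, letter, alphabet))
}

#' @rdname nv_count
#' @export
mean_position <- function(seq, letter, alphabet = dna_alphabet()) {
  p <- which(indicator(seq, letter, alphabet) == 1L)
  if (length(p) == 0) return(0)
  mean(p)
}

#' @rdname nv_count
#' @export
central_moment <- function(seq, letter, j = 2, alphabet = dna_alphabet()) {
  stopifnot(j >= 1, j == round(j))
  w <- indicator(seq, letter, alphabet)
  n <- length(w)
  p <- which(w == 1L)
  if (length(p) == 0) return(0)
  nk <- length(p)
  sum((p - mean(p))^j) / (nk^(j - 1) * n^(j - 1))
}

#' @rdname nv_count
#' @export
nv_covariance <- function(seq, k, l, alphabet = dna_alphabet()) {
  ch <- seq_chars(seq)
  n <- length(ch)
  pk <- which(ch == k)
  pl <- which(ch == l)
  for (x in c(k, l)) {
    if (!x %in% alphabet) {
      stop("letter '", x, "' is not in the alphabet", call. = FALSE)
    }
  }
  if (length(pk) == 0 || length(pl) == 0) return(0)
  mk <- mean(pk)
  ml <- mean(pl)
  pp <- if (identical(k, l)) pk else c(pk, pl)
  sum((pp - mk) * (pp - ml)) / (n * sqrt(length(pk)) * sqrt(length(pl)))
}

#' Natural vector of a sequence
#'
#' Computes the natural vector over an arbitrary ordered alphabet L: per
#' letter the count, the mean 1-based position, and the normalized second
#' central moment of positions, followed (when `covariance = TRUE`) by the
#' positional covariance of every unordered letter pair in canonical order
#' (pairs enumerated as (L1,L2), (L1,L3), ..., matching AC, AG, AT, CG, CT,
#' GT for DNA). The flattened dimension is 3|L| + |L|(|L|-1)/2: 18 for DNA,
#' 250 for the 20-letter protein alphabet. `natural_vector_12()` and
#' `natural_vector_18()` are the DNA shorthands.
#'
#' Non-alphabet characters occupy positions (contribute to the length n) but
#' match no letter. Letters absent from the sequence get mean position,
#' moment and covariances of 0 and are listed in the `absent` attribute.
#'
#' @inheritParams indicator
#' @param covariance include the pairwise covariance block.
#' @return numeric vector of class `natural_vector` with named components
#'   (`nA`, ..., `muA`, ..., `D2A`, ..., `covAC`, ...) and attributes
#'   `alphabet`, `n` (sequence length), `absent` (letters with zero count)
#'   and `non_alphabet` (count of characters matching no letter).
#' @examples
#' natural_vector_18("ACGGTAGTCC")
#' natural_vector("MKV", alphabet = protein_alphabet())  # 250-dimensional
#' @export
natural_vector <- function(seq, alphabet = dna_alphabet(), covariance = TRUE) {
  check_alphabet(alphabet)
  ch <- seq_chars(seq)
  nv_from_tokens(ch, alphabet, covariance)
}

#' @rdname natural_vector
#' @export
natural_vector_12 <- function(seq) {
  natural_vector(seq, dna_alphabet(), covariance = FALSE)
}

#' @rdname natural_vector
#' @export
natural_vector_18 <- function(seq) {
  natural_vector(seq, dna_alphabet(), covariance = TRUE)
}

#' k-mer natural vector
#'
#' Generalizes the natural vector to overlapping k-mers: each of the 4^k DNA
#' words (lexicographic order) is treated as a letter occurring at the
#' 1-based start index of each of its occurrences, and the effective sequence
#' length in all formulas is n - k + 1 (the number of windows). For k = 1
#' this is exactly [natural_vector_18()]. Dimension 3*4^k + 4^k(4^k-1)/2
#' (168 for k = 2). Windows containing a non-ACGT character match no word.
#'
#' @inheritParams indicator
#' @param k word length (>= 1); the sequence must be at least k long.
#' @inheritParams natural_vector
#' @return see [natural_vector()].
#' @export
kmer_natural_vector <- function(seq, k, covariance = TRUE) {
  stopifnot(k >= 1, k == round(k))
  s <- one_string(seq)
  n <- nchar(s)
  if (n < k) stop("sequence shorter than k", call. = FALSE)
  starts <- seq_len(n - k + 1)
  tokens <- substring(s, starts, starts + k - 1)
  nv_from_tokens(tokens, kmer_alphabet(k), covariance)
}

# Core computation on a token vector (letters or k-mers) over an ordered
# alphabet; positions are 1-based token indices.
nv_from_tokens <- function(tokens, alphabet, covariance = TRUE) {
  n <- length(tokens)
  if (n == 0) stop("empty sequence", call. = FALSE)
  L <- length(alphabet)
  pos <- split(seq_len(n), factor(tokens, levels = alphabet))
  counts <- lengths(pos)
  mu <- vapply(pos, function(p) if (length(p)) mean(p) else 0, numeric(1))
  d2 <- vapply(seq_len(L), function(i) {
    p <- pos[[i]]
    if (length(p) == 0) return(0)
    sum((p - mu[[i]])^2) / (length(p) * n)
  }, numeric(1))
  out <- c(counts, mu, d2)
  names(out) <- c(paste0("n", alphabet), paste0("mu", alphabet),
                  paste0("D2", alphabet))
  if (covariance && L >= 2) {
    idx <- utils::combn(L, 2)
    cv <- vapply(seq_len(ncol(idx)), function(j) {
      i1 <- idx[1, j]; i2 <- idx[2, j]
      p1 <- pos[[i1]]; p2 <- pos[[i2]]
      if (length(p1) == 0 || length(p2) == 0) return(0)
      pp <- c(p1, p2)
      sum((pp - mu[[i1]]) * (pp - mu[[i2]])) /
        (n * sqrt(length(p1)) * sqrt(length(p2)))
    }, numeric(1))
    names(cv) <- paste0("cov", alphabet[idx[1, ]], alphabet[idx[2, ]])
    out <- c(out, cv)
  }
  structure(out,
            alphabet = alphabet,
            n = n,
            absent = alphabet[counts == 0],
            non_alphabet = n - sum(counts),
            class = "natural_vector")
}

#' @export
print.natural_vector <- function(x, digits = 6, ...) {
  ab <- attr(x, "alphabet")
  cat("<natural_vector> |L| = ", length(ab), ", dim = ", length(x),
      ", n = ", attr(x, "n"), "\n", sep = "")
  print(round(unclass_nv(x), digits))
  abs_ <- attr(x, "absent")
  if (length(abs_)) cat("absent letters:", paste(abs_, collapse = " "), "\n")
  invisible(x)
}

unclass_nv <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(names = names(y))
  y
}

#' Vectorize a set of sequences
#'
#' Applies [natural_vector()] (or [kmer_natural_vector()]) to every sequence
#' in a set and stacks the results into a matrix, one row per sequence, in
#' the canonical component order.
#'
#' @param seqs an `nv_sequences` data frame (see [read_fasta()]).
#' @param kind `"18"` (default), `"12"`, `"protein"`, `"kmer"`, or
#'   `"custom"` with an explicit `alphabet`.
#' @param k word length when `kind = "kmer"`.
#' @param alphabet explicit alphabet when `kind = "custom"`.
#' @return numeric matrix with sequence ids as row names; attribute
#'   `absent` is a named list of absent-letter flags per sequence.
#' @export
vectorize <- function(seqs, kind = c("18", "12", "protein", "kmer", "custom"),
                      k = 2, alphabet = NULL) {
  kind <- match.arg(kind)
  vs <- lapply(seqs$residues, function(s) {
    switch(kind,
           "18" = natural_vector_18(s),
           "12" = natural_vector_12(s),
           protein = natural_vector(s, protein_alphabet()),
           kmer = kmer_natural_vector(s, k),
           custom = natural_vector(s, check_alphabet(alphabet)))
  })
  m <- do.call(rbind, lapply(vs, unclass_nv))
  rownames(m) <- seqs$id
  attr(m, "absent") <- stats::setNames(lapply(vs, attr, "absent"), seqs$id)
  m
}

#' Read and write natural-vector tables
#'
#' One row per sequence: `id`, `n` (sequence length) and the canonical
#' components with headed columns. Values are written with 17 significant
#' digits so the table round-trips bit-exactly.
#'
#' @param vectors numeric matrix as returned by [vectorize()].
#' @param path output (input) CSV file.
#' @param n optional per-sequence lengths (recovered from the count block
#'   plus non-alphabet characters is not possible, so pass them if wanted).
#' @return `write_vector_table()` returns `path` invisibly;
#'   `read_vector_table()` the matrix with ids as row names.
#' @export
write_vector_table <- function(vectors, path, n = NULL) {
  df <- data.frame(id = rownames(vectors), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(n)) df$n <- n
  num <- as.data.frame(lapply(as.data.frame(vectors, check.names = FALSE),
                              function(col) sprintf("%.17g", col)),
                       check.names = FALSE)
  df <- cbind(df, num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_vector_table
#' @export
read_vector_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = "#")
  ids <- df$id
  df$id <- NULL
  df$n <- NULL
  m <- as.matrix(df)
  rownames(m) <- ids
  m
}

# ---- internal helpers -------------------------------------------------------

one_string <- function(seq) {
  if (inherits(seq, "nv_sequences") || (is.data.frame(seq) && "residues" %in% names(seq))) {
    stopifnot(nrow(seq) == 1)
    return(seq$residues[[1]])
  }
  stopifnot(is.character(seq), length(seq) == 1)
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  seq
}

seq_chars <- function(seq) {
  strsplit(one_string(seq), "", fixed = TRUE)[[1]]
}
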