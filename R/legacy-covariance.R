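#' Subset-averaged positional covariance (older definition)
#'
#' Reference implementation of the earlier covariance between two letters'
#' position lists, kept for comparison with the pair-indicator definition of
#' [nv_covariance()]. Given the sorted position lists `A` (length n) and `B`
#' (length m) of two letters in a sequence of total length `N`:
#' with m = n, the value is the paired sample covariance of the two sorted
#' lists divided by n, then by N; with m != n, every size-min(n, m) subset of
#' the longer list is taken in sorted order, paired index-wise with the
#' shorter list, the equal-length formula applied, and the exact average over
#' all C(max, min) subsets divided by N is returned. The combinatorial
#' enumeration is capped: exceeding `max_enumerations` raises an error naming
#' the required count rather than approximating silently.
#'
#' @param A,B positive integer position vectors (any order; treated as sets).
#' @param N total sequence length.
#' @param max_enumerations cap on the number of subsets enumerated.
#' @return a single numeric value.
#' @examples
#' legacy_covariance(c(1, 2), c(3, 4), N = 4)  # 0.0625
#' @export
legacy_covariance <- function(A, B, N, max_enumerations = 1e5) {
  A <- sort(as.numeric(A))
  B <- sort(as.numeric(B))
  stopifnot(length(A) >= 1, length(B) >= 1, N >= 1)
  if (length(A) > length(B)) { tmp <- A; A <- B; B <- tmp }
  if (length(A) == length(B)) return(legacy_cov_equal(A, B, N))
  legacy_cov_unequal(A, B, N, max_enumerations)
}

#' @rdname legacy_covariance
#' @export
legacy_cov_equal <- function(A, B, N) {
  A <- sort(as.numeric(A))
  B <- sort(as.numeric(B))
  n <- length(A)
  if (length(B) != n) stop("position lists must have equal length", call. = FALSE)
  sum((A - mean(A)) * (B - mean(B))) / n / N
}

#' @rdname legacy_covariance
#' @export
legacy_cov_unequal <- function(A, B, N, max_enumerations = 1e5) {
  A <- sort(as.numeric(A))
  B <- sort(as.numeric(B))
  n <- length(A)
  m <- length(B)
  if (n >= m) stop("legacy_cov_unequal() requires |A| < |B|", call. = FALSE)
  count <- choose(m, n)
  if (count > max_enumerations) {
    stop("subset enumeration C(", m, ",", n, ") = ", format(count),
         " exceeds max_enumerations = ", format(max_enumerations),
         call. = FALSE)
  }
  subs <- utils::combn(B, n)  # columns already sorted ascending
  inner <- apply(subs, 2, function(b) {
    sum((A - mean(A)) * (b - mean(b))) / n
  })
  mean(inner) / N
}

#' Legacy covariance of two letters in a sequence
#'
#' Convenience wrapper extracting the 1-based position lists of two letters
#' and applying [legacy_covariance()] with N the full sequence length.
#'
#' @inheritParams nv_covariance
#' @inheritParams legacy_covariance
#' @export
legacy_covariance_seq <- function(seq, k, l, alphabet = dna_alphabet(),
                                  max_enumerations = 1e5) {
  ch <- seq_chars(seq)
  for (x in c(k, l)) {
    if (!x %in% alphabet) {
      stop("letter '", x, "' is not in the alphabet", call. = FALSE)
    }
  }
  A <- which(ch == k)
  B <- which(ch == l)
  if (length(A) == 0 || length(B) == 0) {
    stop("letter with zero occurrences", call. = FALSE)
  }
  legacy_covariance(A, B, length(ch), max_enumerations)
}
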