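#' The worked-example sequence
#'
#' The 10-nucleotide sequence ACGGTAGTCC whose 12- and 18-dimensional
#' natural vectors are known in closed form; used throughout the tests and
#' documentation as a desk-checkable input.
#'
#' @return a one-row `nv_sequences` with id `"paper_example"`.
#' @export
worked_example <- function() {
  nv_sequences("paper_example", "ACGGTAGTCC", alphabet_kind = "dna")
}

#' Specify a synthetic sequence family
#'
#' A family is a set of i.i.d.-letter sequences with a common base
#' composition, optionally with a positional bias: within the stated segment
#' of each sequence one letter's weight is multiplied and the per-position
#' weights renormalized. The bias perturbs mean positions and covariances,
#' not just counts, so all blocks of the natural vector are exercised.
#' Each spec carries its own seed: the same spec always generates the same
#' sequences, byte for byte.
#'
#' @param name family (group) name.
#' @param n_sequences number of sequences to generate (>= 1).
#' @param length_range integer vector `c(min, max)`; lengths are drawn
#'   uniformly.
#' @param weights per-letter sampling probabilities in [dna_alphabet()]
#'   order; must sum to 1 (tolerance 1e-8).
#' @param bias optional list `list(letter =, start_frac =, end_frac =,
#'   multiplier =)` enriching `letter` by `multiplier` inside the fractional
#'   segment.
#' @param seed integer RNG seed for this family's private stream.
#' @return a `family_spec` list.
#' @export
family_spec <- function(name, n_sequences, length_range,
                        weights = c(0.25, 0.25, 0.25, 0.25),
                        bias = NULL, seed = 1) {
  stopifnot(is.character(name), nzchar(name), n_sequences >= 1,
            length(length_range) == 2, length_range[1] >= 1,
            length_range[1] <= length_range[2],
            length(weights) == 4, all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1", call. = FALSE)
  if (!is.null(bias)) {
    stopifnot(bias$letter %in% dna_alphabet(),
              bias$start_frac >= 0, bias$end_frac <= 1,
              bias$start_frac < bias$end_frac, bias$multiplier > 0)
  }
  structure(list(name = name, n_sequences = as.integer(n_sequences),
                 length_range = as.integer(length_range),
                 weights = weights, bias = bias, seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate synthetic labeled sequence families
#'
#' Deterministic generator of labeled families for testing the full
#' pipeline without any downloads: letters are drawn i.i.d. per the family's
#' composition (with optional positional enrichment), using one seeded
#' Mersenne-Twister stream per family. The surrounding RNG state is left
#' untouched.
#'
#' @param specs a single [family_spec()] or a list of them.
#' @return list with `sequences` (an `nv_sequences`; ids are
#'   `<family>_<i>`) and `labels` (data frame `id`, `group`).
#' @export
generate_families <- function(specs) {
  if (inherits(specs, "family_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "family_spec")))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  ab <- dna_alphabet()
  seqs <- list()
  labs <- list()
  for (sp in specs) {
    set.seed(sp$seed)
    for (i in seq_len(sp$n_sequences)) {
      len <- sp$length_range[1] +
        sample.int(sp$length_range[2] - sp$length_range[1] + 1L, 1) - 1L
      if (is.null(sp$bias)) {
        ch <- sample(ab, len, replace = TRUE, prob = sp$weights)
      } else {
        lo <- floor(sp$bias$start_frac * len) + 1
        hi <- ceiling(sp$bias$end_frac * len)
        wb <- sp$weights
        wb[match(sp$bias$letter, ab)] <- wb[match(sp$bias$letter, ab)] * sp$bias$multiplier
        wb <- wb / sum(wb)
        ch <- character(len)
        plain <- setdiff(seq_len(len), lo:hi)
        ch[plain] <- sample(ab, length(plain), replace = TRUE, prob = sp$weights)
        ch[lo:hi] <- sample(ab, hi - lo + 1, replace = TRUE, prob = wb)
      }
      id <- paste0(sp$name, "_", i)
      seqs[[id]] <- paste(ch, collapse = "")
      labs[[id]] <- sp$name
    }
  }
  list(sequences = nv_sequences(names(seqs), unlist(seqs), "dna"),
       labels = data.frame(id = names(labs), group = unlist(labs),
                           row.names = NULL, stringsAsFactors = FALSE))
}
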