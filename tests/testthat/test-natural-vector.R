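example_seq <- "ACGGTAGTCC"

test_that("indicator and pair indicator match the worked example", {
  expect_equal(indicator(example_seq, "A"), c(1,0,0,0,0,1,0,0,0,0))
  expect_equal(indicator(example_seq, "C"), c(0,1,0,0,0,0,0,0,1,1))
  expect_equal(indicator("AAAA", "G"), rep(0L, 4))
  expect_equal(pair_indicator(example_seq, "A", "C"), c(1,1,0,0,0,1,0,0,1,1))
  expect_equal(pair_indicator(example_seq, "G", "T"), c(0,0,1,1,1,0,1,1,0,0))
  expect_error(indicator(example_seq, "X"), "alphabet")
  expect_error(pair_indicator(example_seq, "A", "A"), "differ")
})

test_that("pair indicator is the elementwise OR of single indicators", {
  set.seed(42)
  for (rep in 1:20) {
    s <- rand_dna(sample(5:100, 1))
    for (p in list(c("A","C"), c("G","T"), c("C","G"))) {
      expect_equal(pair_indicator(s, p[1], p[2]),
                   as.integer(indicator(s, p[1]) | indicator(s, p[2])))
      expect_equal(pair_indicator(s, p[1], p[2]),
                   pair_indicator(s, p[2], p[1]))
    }
  }
})

test_that("scalar components reproduce the worked-example values", {
  expect_equal(nv_count(example_seq, "A"), 2)
  expect_equal(nv_count(example_seq, "C"), 3)
  expect_equal(mean_position(example_seq, "A"), 3.5)
  expect_equal(mean_position(example_seq, "C"), 7)
  expect_equal(mean_position("A", "A"), 1)
  expect_equal(central_moment(example_seq, "A", 2), 0.625)
  expect_equal(central_moment(example_seq, "G", 2), 13 / 45)
  # a single occurrence has zero positional spread
  expect_equal(central_moment("GATT", "G", 2), 0)
  expect_error(nv_count("", "A"), "empty")
})

test_that("covariance matches a literal two-loop evaluation", {
  naive_cov <- function(seq, k, l) {
    ch <- strsplit(seq, "")[[1]]; n <- length(ch)
    pk <- which(ch == k); pl <- which(ch == l)
    mk <- mean(pk); ml <- mean(pl)
    s <- 0
    for (i in seq_len(n)) {
      if (ch[i] == k || ch[i] == l) s <- s + (i - mk) * (i - ml)
    }
    s / (n * sqrt(length(pk)) * sqrt(length(pl)))
  }
  expect_equal(nv_covariance("ACGT", "A", "C"), naive_cov("ACGT", "A", "C"))
  expect_equal(round(nv_covariance(example_seq, "A", "C"), 2), 2.06)
  expect_equal(round(nv_covariance(example_seq, "C", "T"), 3), 1.735)
  set.seed(7)
  for (rep in 1:20) {
    s <- rand_dna(sample(8:60, 1))
    if (nv_count(s, "G") == 0 || nv_count(s, "T") == 0) next
    expect_equal(nv_covariance(s, "G", "T"), naive_cov(s, "G", "T"),
                 tolerance = 1e-12)
  }
})

test_that("Cov(k,k) equals the second central moment, and Cov is symmetric", {
  set.seed(11)
  for (rep in 1:30) {
    s <- rand_dna(sample(10:300, 1), probs = c(0.4, 0.3, 0.2, 0.1))
    for (k in dna_alphabet()) {
      expect_rel(nv_covariance(s, k, k), central_moment(s, k, 2))
    }
    expect_equal(nv_covariance(s, "A", "T"), nv_covariance(s, "T", "A"))
  }
})

test_that("the 12- and 18-dimensional vectors match the printed example", {
  v12 <- natural_vector_12(example_seq)
  expect_length(v12, 12)
  expect_equal(round(unname(nv_vals(v12)), 3),
               c(2, 3, 3, 2, 3.5, 7, 4.667, 6.5, 0.625, 1.267, 0.289, 0.225))
  v18 <- natural_vector_18(example_seq)
  expect_length(v18, 18)
  expect_equal(unname(nv_vals(v18)[1:12]), unname(nv_vals(v12)))
  expect_equal(round(unname(nv_vals(v18)[13:18]), 2),
               c(2.06, 0.86, 0.85, 1.56, 1.74, 0.54))
  expect_equal(names(v18)[13:18],
               c("covAC", "covAG", "covAT", "covCG", "covCT", "covGT"))
})

test_that("homopolymer vector matches the direct moment formula", {
  v <- natural_vector_12(strrep("A", 10))
  expect_equal(unname(nv_vals(v)),
               c(10, 0, 0, 0, 5.5, 0, 0, 0, sum((1:10 - 5.5)^2) / 100, 0, 0, 0))
  expect_equal(attr(v, "absent"), c("C", "G", "T"))
})

test_that("every component matches the naive positional oracle", {
  set.seed(123)
  for (rep in 1:25) {
    s <- rand_dna(sample(10:200, 1),
                  probs = as.vector(stats::rmultinom(1, 20, rep(1, 4))) / 20 + 0.01)
    expect_rel(nv_vals(natural_vector_18(s)), naive_nv18(s))
  }
  # sequences missing a letter follow the zero-count convention in both paths
  expect_rel(nv_vals(natural_vector_18("ACGACG")), naive_nv18("ACGACG"))
  # order matters: reversal is not an invariance
  expect_false(isTRUE(all.equal(nv_vals(natural_vector_18("AC")),
                                nv_vals(natural_vector_18("CA")))))
})

test_that("self-concatenation agrees with the oracle", {
  set.seed(5)
  for (rep in 1:5) {
    s <- rand_dna(sample(10:80, 1))
    ss <- paste0(s, s)
    v <- natural_vector_18(ss)
    expect_rel(nv_vals(v), naive_nv18(ss))
    expect_equal(nv_vals(v)[1:4], 2 * nv_vals(natural_vector_18(s))[1:4])
  }
})

test_that("non-alphabet characters occupy positions but match no letter", {
  v <- natural_vector_18("ACGN")
  expect_equal(attr(v, "n"), 4)
  expect_equal(attr(v, "non_alphabet"), 1)
  expect_equal(unname(nv_vals(v)[c("nA", "nC", "nG", "nT")]), c(1, 1, 1, 0))
  # the placeholder keeps downstream positions and denominators intact
  expect_equal(unname(nv_vals(natural_vector_18("ANC"))[["covAC"]]),
               nv_covariance("ANC", "A", "C"))
})

test_that("generalized vectors have dimension 3|L| + C(|L|,2)", {
  dims <- c(1, 2, 4, 16, 20)
  for (L in dims) {
    ab <- if (L == 20) protein_alphabet() else
      if (L == 16) kmer_alphabet(2) else dna_alphabet()[seq_len(L)]
    s <- paste(rep(ab[[1]], 5), collapse = "")
    expect_length(natural_vector(s, alphabet = ab), 3 * L + choose(L, 2))
  }
  expect_length(natural_vector("MKVL", alphabet = protein_alphabet()), 250)
  # DNA alphabet reduces to the 18-dimensional vector
  expect_equal(natural_vector(example_seq, dna_alphabet()),
               natural_vector_18(example_seq))
  # |L| = 1: no covariance block at all
  expect_length(natural_vector("AAA", alphabet = "A"), 3)
})

test_that("k-mer vectors use start positions and effective length n-k+1", {
  expect_equal(nv_vals(kmer_natural_vector(example_seq, 1)),
               nv_vals(natural_vector_18(example_seq)))
  v2 <- kmer_natural_vector(example_seq, 2)
  expect_length(v2, 3 * 16 + choose(16, 2))  # 168
  # counts block equals a sliding-window tally
  tally <- table(factor(substring(example_seq, 1:9, 2:10),
                        levels = kmer_alphabet(2)))
  expect_equal(unname(nv_vals(v2)[1:16]), as.vector(tally))
  expect_equal(attr(v2, "n"), 9)
  v_aa <- kmer_natural_vector("AAAA", 2)
  expect_equal(unname(nv_vals(v_aa)[["nAA"]]), 3)
  expect_equal(sum(nv_vals(v_aa)[1:16]), 3)
  expect_error(kmer_natural_vector("AC", 3), "shorter")
})

test_that("vector tables round-trip bit-exactly through CSV", {
  seqs <- nv_sequences(c("s1", "s2", "s3"),
                       c(example_seq, "ACGACGACG", "TTTTGGGCCA"))
  v <- vectorize(seqs)
  f <- withr::local_tempfile(fileext = ".csv")
  write_vector_table(v, f, n = nchar(seqs$residues))
  back <- read_vector_table(f)
  expect_identical(back, structure(v, absent = NULL))
  expect_equal(ncol(vectorize(seqs, kind = "12")), 12)
})
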