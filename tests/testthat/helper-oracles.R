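# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity position by position (or by exhaustive geometry)
# and never call the package's own fast paths.

rand_dna <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# literal positional evaluation of the 18 components: indicator loops only
naive_nv18 <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  letters4 <- c("A", "C", "G", "T")
  w <- function(k) as.integer(ch == k)
  nk <- sapply(letters4, function(k) sum(w(k)))
  mu <- sapply(letters4, function(k) {
    if (nk[[k]] == 0) return(0)
    wk <- w(k)
    s <- 0
    for (i in seq_len(n)) s <- s + i * wk[i] / nk[[k]]
    s
  })
  d2 <- sapply(letters4, function(k) {
    if (nk[[k]] == 0) return(0)
    wk <- w(k)
    s <- 0
    for (i in seq_len(n)) s <- s + (i - mu[[k]])^2 * wk[i] / (nk[[k]] * n)
    s
  })
  pairs <- combn(letters4, 2)
  cv <- apply(pairs, 2, function(p) {
    k <- p[1]; l <- p[2]
    if (nk[[k]] == 0 || nk[[l]] == 0) return(0)
    wkl <- as.integer(ch == k | ch == l)
    s <- 0
    for (i in seq_len(n)) {
      s <- s + (i - mu[[k]]) * (i - mu[[l]]) * wkl[i] /
        (n * sqrt(nk[[k]]) * sqrt(nk[[l]]))
    }
    s
  })
  out <- c(nk, mu, d2, cv)
  names(out) <- c(paste0("n", letters4), paste0("mu", letters4),
                  paste0("D2", letters4),
                  paste0("cov", pairs[1, ], pairs[2, ]))
  out
}

# strip natural_vector attributes, keeping component names
nv_vals <- function(v) {
  y <- unclass(v)
  attributes(y) <- list(names = names(y))
  y
}

expect_rel <- function(actual, expected, tol = 1e-12) {
  err <- abs(actual - expected) / pmax(abs(expected), 1)
  expect_lt(max(err), tol)
}

# ---- exact 2-D convex hull intersection oracle (integer coordinates) -------

orient2 <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

on_seg <- function(p, q, r) {
  # collinear r within the bounding box of segment pq
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segs_intersect <- function(p1, p2, p3, p4) {
  d1 <- orient2(p3, p4, p1)
  d2 <- orient2(p3, p4, p2)
  d3 <- orient2(p1, p2, p3)
  d4 <- orient2(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

hull_vertices <- function(P) {
  P <- unique(P)
  if (nrow(P) <= 2) return(P)
  h <- chull(P)
  P[h, , drop = FALSE]
}

hull_edges <- function(V) {
  k <- nrow(V)
  if (k == 1) return(list(list(V[1, ], V[1, ])))
  lapply(seq_len(k), function(i) list(V[i, ], V[i %% k + 1, ]))
}

point_in_hull_2d <- function(pt, V) {
  k <- nrow(V)
  if (k == 1) return(all(pt == V[1, ]))
  if (k == 2) return(orient2(V[1, ], V[2, ], pt) == 0 && on_seg(V[1, ], V[2, ], pt))
  signs <- sapply(seq_len(k), function(i) orient2(V[i, ], V[i %% k + 1, ], pt))
  all(signs >= 0) || all(signs <= 0)
}

# TRUE iff the convex hulls of integer point sets A and B intersect
# (touching counts as intersecting)
hulls_intersect_oracle <- function(A, B) {
  VA <- hull_vertices(A)
  VB <- hull_vertices(B)
  for (ea in hull_edges(VA)) {
    for (eb in hull_edges(VB)) {
      if (segs_intersect(ea[[1]], ea[[2]], eb[[1]], eb[[2]])) return(TRUE)
    }
  }
  point_in_hull_2d(VA[1, ], VB) || point_in_hull_2d(VB[1, ], VA)
}
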