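tri_A <- rbind(c(0, 0), c(2, 0), c(0, 2))
tri_B <- rbind(c(1, 1), c(3, 1), c(1, 3))

test_that("hull disjointness verdicts on hand-checkable instances", {
  # identical point sets share every point
  expect_equal(hulls_disjoint(tri_A, tri_A)$status, "intersecting")
  # separated 1-D intervals
  expect_equal(hulls_disjoint(matrix(c(0, 1)), matrix(c(2, 3)))$status,
               "disjoint")
  # overlapping triangles (checked against the geometric oracle)
  expect_true(hulls_intersect_oracle(tri_A, tri_B))
  res <- hulls_disjoint(tri_A, tri_B)
  expect_equal(res$status, "intersecting")
  # intersecting certificate: convex coefficients coincide on a common point
  cert <- res$certificate
  expect_true(all(cert$lambda >= -1e-6) && all(cert$beta >= -1e-6))
  expect_equal(sum(cert$lambda), 1, tolerance = 1e-6)
  expect_equal(sum(cert$beta), 1, tolerance = 1e-6)
  expect_equal(drop(t(tri_A) %*% cert$lambda), drop(t(tri_B) %*% cert$beta),
               tolerance = 1e-5)
  expect_error(hulls_disjoint(tri_A, tri_B[, 1, drop = FALSE]), "dimension")
})

test_that("adding an interior point never changes a verdict", {
  set.seed(31)
  for (rep in 1:10) {
    A <- matrix(sample(-5:5, 8, TRUE), ncol = 2)
    B <- matrix(sample(-5:5, 8, TRUE), ncol = 2) +
      sample(c(0, 12), 1)
    v0 <- hulls_disjoint(A, B)$status
    w <- runif(4); w <- w / sum(w)
    A2 <- rbind(A, drop(t(A) %*% w))
    expect_equal(hulls_disjoint(A2, B)$status, v0)
  }
})

test_that("diagonal rescaling does not flip verdicts", {
  set.seed(17)
  for (rep in 1:10) {
    A <- matrix(sample(-5:5, 10, TRUE), ncol = 2)
    B <- matrix(sample(-5:5, 10, TRUE), ncol = 2) + sample(c(0, 10), 1)
    s <- 10^runif(2, -3, 3)
    v1 <- hulls_disjoint(A, B)$status
    v2 <- hulls_disjoint(sweep(A, 2, s, "*"), sweep(B, 2, s, "*"))$status
    expect_equal(v2, v1)
  }
})

test_that("LP verdicts agree with the exact 2-D geometry oracle", {
  set.seed(99)
  n_cases <- 120
  for (rep in seq_len(n_cases)) {
    nA <- sample(1:8, 1); nB <- sample(1:8, 1)
    shift <- sample(c(0, 0, 4, 12), 1)
    A <- matrix(sample(-5:5, 2 * nA, TRUE), ncol = 2)
    B <- matrix(sample(-5:5, 2 * nB, TRUE), ncol = 2) + shift
    want <- if (hulls_intersect_oracle(A, B)) "intersecting" else "disjoint"
    expect_equal(hulls_disjoint(A, B)$status, want,
                 label = paste0("case ", rep))
  }
  # touching at a single shared vertex counts as intersecting
  expect_equal(hulls_disjoint(rbind(c(0, 0), c(-2, 0), c(0, -2)),
                              rbind(c(0, 0), c(2, 0), c(0, 2)))$status,
               "intersecting")
  # nested hulls intersect
  expect_equal(hulls_disjoint(rbind(c(-5, -5), c(5, -5), c(0, 5)),
                              rbind(c(-1, -1), c(1, -1), c(0, 1)))$status,
               "intersecting")
})

test_that("pairwise report counts pairs and filters small groups", {
  sets <- list(F1 = tri_A, F2 = tri_B + 20, F3 = tri_A + 40)
  rep3 <- pairwise_hull_report(sets)
  expect_equal(nrow(rep3), 3)  # C(3,2)
  s <- summary(rep3)
  expect_equal(unname(s["total_pairs"]), 3)
  expect_equal(unname(s["disjoint_pairs"] + s["intersecting_pairs"] +
                        s["solver_failures"]), 3)
  expect_equal(unname(s["disjoint_pairs"]), 3)
  sets$tiny <- matrix(c(100, 100), 1)
  expect_message(rep2 <- pairwise_hull_report(sets), "fewer than 3")
  expect_equal(nrow(rep2), 3)
  expect_equal(nrow(pairwise_hull_report(sets[1:2])), 1)  # C(2,2) = 1
  f <- withr::local_tempfile(fileext = ".json")
  write_hull_report(rep3, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$summary$disjoint_pairs, 3)
})

test_that("separating hyperplane strictly separates disjoint hulls", {
  # 1-D: plane sits strictly between the two points, |w| = 1
  hp1 <- separating_hyperplane(matrix(0, 1, 1), matrix(2, 1, 1))
  expect_equal(abs(hp1$w), 1)
  plane_at <- -hp1$b / hp1$w
  expect_gt(plane_at, 0)
  expect_lt(plane_at, 2)
  A <- rbind(c(0, 0), c(1, 0), c(0, 1))
  B <- A + 5
  hp <- separating_hyperplane(A, B)
  expect_equal(sqrt(sum(hp$w^2)), 1, tolerance = 1e-9)
  expect_true(all(A %*% hp$w + hp$b > 0))
  expect_true(all(B %*% hp$w + hp$b < 0))
  expect_gt(hp$margin, 0)
  expect_error(separating_hyperplane(tri_A, tri_B), "disjoint")
})

test_that("hyperplane agrees with LP verdicts on separated Gaussian clouds", {
  set.seed(55)
  for (rep in 1:5) {
    d <- sample(2:6, 1)
    A <- matrix(rnorm(8 * d), ncol = d)
    B <- matrix(rnorm(8 * d), ncol = d) + 8
    expect_equal(hulls_disjoint(A, B)$status, "disjoint")
    hp <- separating_hyperplane(A, B, check = FALSE)
    expect_true(all(sign(A %*% hp$w + hp$b) == 1))
    expect_true(all(sign(B %*% hp$w + hp$b) == -1))
  }
})

test_that("2-D projection uses a deterministic orthonormal pair", {
  set.seed(8)
  for (rep in 1:10) {
    d <- sample(2:18, 1)
    w <- rnorm(d)
    v <- natvec:::orthogonal_unit(w / sqrt(sum(w^2)))
    expect_equal(sum(v * w), 0, tolerance = 1e-9)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
  # w = e1 in 2-D: projection is the identity up to axis order
  pts <- matrix(rnorm(10), ncol = 2)
  pr <- project_2d(pts, c(1, 0))
  expect_equal(unname(pr[, "u"]), pts[, 1])
  expect_equal(abs(unname(pr[, "v"])), abs(pts[, 2]))
  # projected families stay on opposite sides of the separating line
  A <- rbind(c(0, 0, 0), c(1, 0, 0)); B <- A + 4
  hp <- separating_hyperplane(A, B, check = FALSE)
  prA <- project_2d(A, hp$w); prB <- project_2d(B, hp$w)
  expect_true(all(prA[, "u"] + hp$b > 0))
  expect_true(all(prB[, "u"] + hp$b < 0))
  expect_error(project_2d(pts, c(0, 0)), "nonzero")
})

test_that("18-dimensional natural-vector families get correct verdicts", {
  fams <- generate_families(list(
    family_spec("x", 6, c(200, 220), c(0.7, 0.1, 0.1, 0.1), seed = 4),
    family_spec("y", 6, c(200, 220), c(0.1, 0.7, 0.1, 0.1), seed = 5)))
  v <- vectorize(fams$sequences)
  sets <- split_by_group(v, fams$labels)
  expect_equal(hulls_disjoint(sets$x, sets$y)$status, "disjoint")
  # a family is never disjoint from itself
  expect_equal(hulls_disjoint(sets$x, sets$x)$status, "intersecting")
})
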