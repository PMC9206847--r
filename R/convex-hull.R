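#' Convex hull disjointness by LP feasibility
#'
#' Two families of natural vectors have intersecting convex hulls iff some
#' convex combination of the first point set equals a convex combination of
#' the second: the feasibility of the linear program with variables
#' \eqn{\lambda \ge 0, \beta \ge 0}, equality constraints
#' \eqn{\sum_i \lambda_i a_i = \sum_j \beta_j b_j},
#' \eqn{\sum \lambda = 1, \sum \beta = 1}, and zero objective. A feasible
#' solution means intersecting; proven infeasibility means disjoint.
#'
#' Before solving, every coordinate is rescaled by its maximum absolute value
#' over both sets (an invertible diagonal map; hull disjointness is
#' invariant). Natural-vector components span several orders of magnitude
#' (counts vs covariances), so this conditioning step matters. A "feasible"
#' solution whose certificate violates the constraints at `1e-6` is re-solved
#' at tighter tolerance, and reported as `solver_failure` if still
#' inconsistent - solver noise is never silently classified.
#'
#' @param A,B numeric matrices, one point per row, equal column counts.
#' @param group_a,group_b optional group names for the report.
#' @param tol feasibility tolerance on constraint residuals (scaled space).
#' @return object of class `hull_pair`: list with `group_a`, `group_b`,
#'   `status` (`"disjoint"`, `"intersecting"` or `"solver_failure"`), and for
#'   intersecting pairs a `certificate` (`lambda`, `beta`, the common
#'   `point`, and the residual).
#' @examples
#' A <- rbind(c(0, 0), c(2, 0), c(0, 2))
#' B <- rbind(c(1, 1), c(3, 1), c(1, 3))
#' hulls_disjoint(A, B)$status   # "intersecting"
#' hulls_disjoint(A, B + 10)$status  # "disjoint"
#' @export
hulls_disjoint <- function(A, B, group_a = "A", group_b = "B", tol = 1e-8) {
  A <- as_points(A)
  B <- as_points(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty point set", call. = FALSE)
  if (ncol(A) != ncol(B)) stop("dimension mismatch", call. = FALSE)
  sc <- apply(rbind(abs(A), abs(B)), 2, max)
  sc[sc == 0] <- 1
  As <- sweep(A, 2, sc, "/")
  Bs <- sweep(B, 2, sc, "/")
  m <- nrow(A); n <- nrow(B); d <- ncol(A)
  E <- rbind(cbind(t(As), -t(Bs)),
             c(rep(1, m), rep(0, n)),
             c(rep(0, m), rep(1, n)))
  b3 <- c(rep(0, d), 1, 1)
  sol <- lp_feasible(E, b3, feas_tol = tol)

  out <- list(group_a = group_a, group_b = group_b, certificate = NULL,
              dim = d)
  if (is.na(sol$feasible)) {
    out$status <- "solver_failure"
    out$diagnostics <- sol$diagnostics
  } else if (!sol$feasible) {
    out$status <- "disjoint"
  } else {
    x <- sol$x
    resid <- max(abs(E %*% x - b3))
    if (resid <= 1e-6 && all(x >= -1e-6)) {
      lambda <- x[seq_len(m)]
      beta <- x[m + seq_len(n)]
      out$status <- "intersecting"
      out$certificate <- list(lambda = lambda, beta = beta,
                              point = drop(t(A) %*% lambda),
                              residual = resid)
    } else {
      out$status <- "solver_failure"
      out$diagnostics <- paste0("feasible LP solution violates certificate ",
                                "check (residual ", format(resid), ")")
    }
  }
  class(out) <- "hull_pair"
  out
}

# Phase-1 simplex for the feasibility system E x = b, x >= 0, with Bland's
# anti-cycling rule: deterministic and finite. Artificial variables start in
# the basis; the system is feasible iff their summed value can be driven to
# (numerical) zero. Inputs are pre-conditioned to O(1) entries by the caller.
lp_feasible <- function(E, b, feas_tol = 1e-8, pivot_tol = 1e-11,
                        max_iter = 20000L) {
  k <- nrow(E)
  nv <- ncol(E)
  neg <- b < 0
  E[neg, ] <- -E[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  tab <- cbind(E, diag(k), b)
  basis <- nv + seq_len(k)
  # phase-1 reduced-cost row (artificial costs 1): rc_j = -sum_i tab[i, j]
  cost <- c(-colSums(tab[, seq_len(nv), drop = FALSE]), rep(0, k),
            -sum(b))
  for (it in seq_len(max_iter)) {
    enter <- which(cost[seq_len(nv + k)] < -pivot_tol)
    if (length(enter) == 0) {
      obj <- -cost[nv + k + 1]
      x <- numeric(nv + k)
      x[basis] <- tab[, nv + k + 1]
      return(list(feasible = obj <= feas_tol, x = x[seq_len(nv)],
                  objective = obj))
    }
    j <- enter[[1]]  # Bland: smallest eligible index
    col <- tab[, j]
    rows <- which(col > pivot_tol)
    if (length(rows) == 0) {
      return(list(feasible = NA,
                  diagnostics = "phase-1 LP unbounded (numerical failure)"))
    }
    ratios <- tab[rows, nv + k + 1] / col[rows]
    cand <- rows[ratios <= min(ratios) + 0]
    r <- cand[which.min(basis[cand])]  # Bland on ties
    piv <- tab[r, j]
    tab[r, ] <- tab[r, ] / piv
    upd <- setdiff(seq_len(k), r)
    tab[upd, ] <- tab[upd, , drop = FALSE] -
      outer(tab[upd, j], tab[r, ])
    cost <- cost - cost[j] * tab[r, ]
    basis[r] <- j
  }
  list(feasible = NA,
       diagnostics = paste0("phase-1 simplex did not converge in ", max_iter,
                            " iterations"))
}

#' @export
print.hull_pair <- function(x, ...) {
  cat("<hull_pair> ", x$group_a, " vs ", x$group_b, ": ", x$status, "\n",
      sep = "")
  if (!is.null(x$diagnostics)) cat("  ", x$diagnostics, "\n")
  invisible(x)
}

#' Pairwise convex-hull disjointness report
#'
#' Evaluates [hulls_disjoint()] for every unordered pair of groups and
#' summarizes the number of disjoint pairs out of the C(g, 2) total, the
#' statistic used to compare 12- vs 18-dimensional representations on real
#' family collections.
#'
#' @param sets named list of point matrices (see [split_by_group()]).
#' @param min_size minimum members for a group to enter the analysis
#'   (default 3, mirroring the published family filter); smaller groups are
#'   dropped with a message.
#' @inheritParams hulls_disjoint
#' @return data frame of class `hull_report` with columns `group_a`,
#'   `group_b`, `status`; attributes `summary` (named counts: `total_pairs`,
#'   `disjoint_pairs`, `intersecting_pairs`, `solver_failures`) and `pairs`
#'   (the full `hull_pair` objects).
#' @export
pairwise_hull_report <- function(sets, min_size = 3, tol = 1e-8) {
  keep <- vapply(sets, nrow, integer(1)) >= min_size
  if (any(!keep)) {
    message("dropping ", sum(!keep), " group(s) with fewer than ", min_size,
            " members: ", paste(names(sets)[!keep], collapse = ", "))
    sets <- sets[keep]
  }
  g <- length(sets)
  if (g < 2) stop("need at least two groups of size >= min_size", call. = FALSE)
  idx <- utils::combn(g, 2)
  pairs <- lapply(seq_len(ncol(idx)), function(j) {
    i1 <- idx[1, j]; i2 <- idx[2, j]
    hulls_disjoint(sets[[i1]], sets[[i2]],
                   group_a = names(sets)[i1], group_b = names(sets)[i2],
                   tol = tol)
  })
  df <- data.frame(group_a = vapply(pairs, `[[`, "", "group_a"),
                   group_b = vapply(pairs, `[[`, "", "group_b"),
                   status = vapply(pairs, `[[`, "", "status"),
                   stringsAsFactors = FALSE)
  attr(df, "summary") <- c(total_pairs = nrow(df),
                           disjoint_pairs = sum(df$status == "disjoint"),
                           intersecting_pairs = sum(df$status == "intersecting"),
                           solver_failures = sum(df$status == "solver_failure"))
  attr(df, "pairs") <- pairs
  class(df) <- c("hull_report", "data.frame")
  df
}

#' @export
print.hull_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<hull_report> ", s[["disjoint_pairs"]], " of ", s[["total_pairs"]],
      " group pairs disjoint (", s[["intersecting_pairs"]], " intersecting, ",
      s[["solver_failures"]], " solver failures)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.hull_report <- function(object, ...) attr(object, "summary")

#' Maximum-margin separating hyperplane of two disjoint hulls
#'
#' For two point sets with disjoint convex hulls there is a hyperplane
#' \eqn{w^T x + b = 0} strictly separating them. It is computed as the
#' hard-margin linear maximum-margin separator (linear SVM with an
#' effectively infinite cost) on the rescaled coordinates, mapped back and
#' normalized so that `w` has unit norm and points of `A` fall on the
#' positive side.
#'
#' @inheritParams hulls_disjoint
#' @param check verify disjointness first (recommended); if the sets are not
#'   disjoint an error is raised.
#' @return list with unit normal `w`, offset `b`, and the minimum absolute
#'   margin over all points.
#' @export
separating_hyperplane <- function(A, B, check = TRUE) {
  A <- as_points(A)
  B <- as_points(B)
  if (check) {
    hp <- hulls_disjoint(A, B)
    if (hp$status != "disjoint") {
      stop("separating_hyperplane() requires disjoint hulls (status: ",
           hp$status, ")", call. = FALSE)
    }
  }
  sc <- apply(rbind(abs(A), abs(B)), 2, max)
  sc[sc == 0] <- 1
  X <- sweep(rbind(A, B), 2, sc, "/")
  y <- factor(c(rep("A", nrow(A)), rep("B", nrow(B))), levels = c("A", "B"))
  fit <- e1071::svm(X, y, kernel = "linear", cost = 1e8, scale = FALSE)
  ws <- drop(t(fit$coefs) %*% fit$SV)
  w <- ws / sc
  b <- -fit$rho
  # orient so A is on the positive side
  if (mean(A %*% w + b) < 0) { w <- -w; b <- -b }
  nw <- sqrt(sum(w^2))
  w <- w / nw
  b <- b / nw
  margin <- min(abs(c(A %*% w + b, B %*% w + b)))
  if (!(all(A %*% w + b > 0) && all(B %*% w + b < 0))) {
    stop("failed to find a strictly separating hyperplane", call. = FALSE)
  }
  list(w = w, b = b, margin = margin)
}

#' Project points to two dimensions along a hyperplane normal
#'
#' For visualizing a separated family pair: each point x is mapped to
#' `(w . x, v . x)` where `v` is a deterministic unit vector orthogonal to
#' `w` (the first standard basis vector not parallel to `w`, orthogonalized
#' against it and normalized).
#'
#' @param points numeric matrix, one point per row.
#' @param w nonzero normal vector (e.g. from [separating_hyperplane()]).
#' @return two-column matrix of (u, v) coordinates.
#' @export
project_2d <- function(points, w) {
  points <- as_points(points)
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("w must be nonzero", call. = FALSE)
  what <- w / nw
  v <- orthogonal_unit(what)
  out <- cbind(points %*% w, points %*% v)
  colnames(out) <- c("u", "v")
  out
}

orthogonal_unit <- function(what) {
  d <- length(what)
  if (d < 2) stop("need dimension >= 2 to construct an orthogonal vector",
                  call. = FALSE)
  for (i in seq_len(d)) {
    e <- rep(0, d); e[i] <- 1
    v <- e - sum(e * what) * what
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
  stop("could not construct an orthogonal vector", call. = FALSE)
}

#' Write a hull report to disk
#'
#' @param report a `hull_report`.
#' @param path output path; `.json` writes a JSON object with `pairs` and
#'   `summary` blocks, anything else a CSV of the pair table.
#' @return `path`, invisibly.
#' @export
write_hull_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(pairs = as.data.frame(report),
                              summary = as.list(attr(report, "summary"))),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
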