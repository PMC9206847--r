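#' Euclidean distance between two vectors
#'
#' Sequence similarity is measured as the Euclidean (L2) distance between
#' natural vectors. No feature scaling is applied by default, mirroring how
#' raw 18-dimensional vectors are compared (count components dominate for
#' long genomes; see the vignette for the caveat and the `standardize`
#' option of [pairwise_matrix()]).
#'
#' @param u,v numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
euclidean <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  sqrt(sum((u - v)^2))
}

#' All-pairs Euclidean distance matrix
#'
#' @param vectors numeric matrix, one item per row, row names as labels.
#' @param standardize divide each column by its standard deviation over the
#'   items before computing distances (off by default; the raw vectors are
#'   the published convention).
#' @return symmetric matrix with zero diagonal and the row names as labels.
#' @export
pairwise_matrix <- function(vectors, standardize = FALSE) {
  vectors <- as.matrix(vectors)
  if (is.null(rownames(vectors))) {
    rownames(vectors) <- paste0("item", seq_len(nrow(vectors)))
  }
  if (standardize) {
    s <- apply(vectors, 2, stats::sd)
    s[s == 0 | is.na(s)] <- 1
    vectors <- sweep(vectors, 2, s, "/")
  }
  m <- as.matrix(stats::dist(vectors))
  diag(m) <- 0
  m
}

#' Hausdorff distance between two point sets
#'
#' The larger of the two directed worst-case nearest-point distances,
#' \eqn{d(X,Y) = \max\{\sup_{x} \inf_{y} d(x,y), \sup_{y} \inf_{x} d(x,y)\}},
#' under the Euclidean metric. Used as a between-family distance on sets of
#' natural vectors.
#'
#' @param X,Y numeric matrices (points in rows) of equal column count; a
#'   plain vector is taken as a single point.
#' @return nonnegative scalar; 0 iff the two sets are equal as point sets.
#' @export
hausdorff <- function(X, Y) {
  X <- as_points(X)
  Y <- as_points(Y)
  if (nrow(X) == 0 || nrow(Y) == 0) stop("empty point set", call. = FALSE)
  if (ncol(X) != ncol(Y)) stop("dimension mismatch", call. = FALSE)
  D <- cross_dist(X, Y)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

cross_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  sqrt(pmax(d2, 0))
}

as_points <- function(X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  as.matrix(X)
}

#' Hausdorff distance matrix between labeled groups
#'
#' @param sets named list of point matrices (one per group), e.g. from
#'   [split_by_group()].
#' @return symmetric matrix over the group names.
#' @export
hausdorff_matrix <- function(sets) {
  g <- length(sets)
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be a named list", call. = FALSE)
  }
  m <- matrix(0, g, g, dimnames = list(names(sets), names(sets)))
  if (g >= 2) {
    for (i in seq_len(g - 1)) {
      for (j in seq(i + 1, g)) {
        m[i, j] <- m[j, i] <- hausdorff(sets[[i]], sets[[j]])
      }
    }
  }
  m
}

#' Split a vector matrix into labeled groups
#'
#' @param vectors matrix with sequence ids as row names.
#' @param labels data frame with columns `id`, `group` (see [read_labels()]).
#' @param min_size drop groups with fewer members (with a message); the
#'   convex-hull analyses use 3 by default, other callers can pass 1.
#' @return named list of matrices, one per retained group.
#' @export
split_by_group <- function(vectors, labels, min_size = 1) {
  ids <- rownames(vectors)
  if (is.null(ids)) stop("vectors must have row names (sequence ids)", call. = FALSE)
  hit <- match(ids, labels$id)
  if (anyNA(hit)) {
    stop("no group label for id(s): ",
         paste(utils::head(ids[is.na(hit)], 5), collapse = ", "), call. = FALSE)
  }
  groups <- labels$group[hit]
  sets <- lapply(split(seq_along(ids), groups), function(i) {
    vectors[i, , drop = FALSE]
  })
  small <- vapply(sets, nrow, integer(1)) < min_size
  if (any(small)) {
    message("dropping ", sum(small), " group(s) below min_size = ", min_size,
            ": ", paste(names(sets)[small], collapse = ", "))
    sets <- sets[!small]
  }
  sets
}

#' Read and write distance matrices
#'
#' Square CSV with a header row and label column, or the relaxed square
#' PHYLIP distance format.
#'
#' @param m symmetric distance matrix with labels as dimnames.
#' @param path file path.
#' @param format `"csv"` or `"phylip"`.
#' @return `write_distance_matrix()` returns `path` invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  validate_distance_matrix(m)
  if (format == "csv") {
    utils::write.csv(as.data.frame(m), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(format(nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(rownames(m)[i],
                       paste(sprintf("%.10g", m[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                          comment.char = "#")
    m <- as.matrix(df)
    colnames(m) <- rownames(m)
  } else {
    lines <- readLines(path, warn = FALSE)
    n <- as.integer(trimws(lines[[1]]))
    parts <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
    lab <- vapply(parts, `[[`, "", 1)
    m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
    dimnames(m) <- list(lab, lab)
  }
  validate_distance_matrix(m)
  m
}

validate_distance_matrix <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (any(m < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(m)) > tol)) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  invisible(m)
}
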