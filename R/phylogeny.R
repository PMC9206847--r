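#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group method with arithmetic mean: repeatedly
#' merge the closest pair of clusters, with the distance between clusters the
#' size-weighted arithmetic mean of member pairwise distances, and place the
#' merge node at half the merge distance, so every root-to-leaf path has the
#' same length (the tree is ultrametric). When several pairs tie at the
#' minimal distance, the pair whose (smaller index, larger index) is
#' lexicographically least in the current cluster ordering is merged -
#' results are deterministic across runs and platforms. Children are ordered
#' by their lexicographically smallest leaf label in the Newick output.
#'
#' @param dm symmetric nonnegative distance matrix with zero diagonal and
#'   item labels as dimnames (>= 2 items).
#' @return an [ape::read.tree()] `phylo` object with branch lengths; the
#'   canonical Newick string is available via [to_newick()].
#' @examples
#' dm <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' to_newick(upgma_tree(dm))
#' @export
upgma_tree <- function(dm) {
  dm <- as.matrix(dm)
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 items", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))

  D <- dm
  active <- seq_len(n)
  size <- rep(1, n)
  height <- rep(0, n)
  merge_heights <- numeric(0)
  # provisional node ids: leaves 1..n, merge r creates node n + r
  edges <- matrix(0L, 2 * (n - 1), 2)
  elen <- numeric(2 * (n - 1))
  e <- 0L

  while (length(active) > 1) {
    sub <- D[active, active, drop = FALSE]
    dmin <- min(sub[upper.tri(sub)])
    cand <- which(sub == dmin & upper.tri(sub), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- active[cand[1, 1]]
    j <- active[cand[1, 2]]
    h <- dmin / 2
    merge_heights <- c(merge_heights, h)

    # append merged cluster, retire i and j
    D <- rbind(cbind(D, 0), 0)
    new <- nrow(D)
    others <- setdiff(active, c(i, j))
    if (length(others)) {
      dnew <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[new, others] <- dnew
      D[others, new] <- dnew
    }
    for (child in c(i, j)) {
      e <- e + 1L
      edges[e, ] <- c(new, child)
      elen[e] <- h - height[child]
    }
    size <- c(size, size[i] + size[j])
    height <- c(height, h)
    active <- c(others, new)
  }

  # renumber internal nodes: root gets n + 1, then preorder, as ape expects
  root_old <- active
  newid <- integer(2 * n - 1)
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  stack <- root_old
  kids_of <- split(edges[, 2], edges[, 1])
  while (length(stack)) {
    node <- stack[[1]]
    stack <- stack[-1]
    newid[node] <- nxt
    nxt <- nxt + 1L
    ch <- kids_of[[as.character(node)]]
    stack <- c(ch[ch > n], stack)
  }
  tree <- structure(list(edge = cbind(newid[edges[, 1]], newid[edges[, 2]]),
                         edge.length = elen,
                         tip.label = labels,
                         Nnode = n - 1L),
                    class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "merge_heights") <- merge_heights
  tree
}

#' Group-level UPGMA tree from Hausdorff distances
#'
#' Builds the between-group distance matrix with [hausdorff_matrix()] and
#' clusters it with [upgma_tree()]; one leaf per group.
#'
#' @inheritParams hausdorff_matrix
#' @return a `phylo` object, identical to
#'   `upgma_tree(hausdorff_matrix(sets))`.
#' @export
group_tree <- function(sets) {
  upgma_tree(hausdorff_matrix(sets))
}

#' Canonical Newick serialization
#'
#' Serializes a rooted tree with branch lengths to Newick. Children are
#' ordered by their lexicographically smallest descendant leaf label (stable
#' diffs: the same tree always prints the same string), branch lengths carry
#' 10 significant digits, and labels containing spaces or Newick
#' metacharacters are single-quoted.
#'
#' @param tree a `phylo` object.
#' @param path optional output file.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  serialize <- function(node) {
    if (node <= ntip) {
      return(list(str = newick_label(tree$tip.label[node]),
                  minlab = tree$tip.label[node]))
    }
    parts <- lapply(kids[[as.character(node)]], function(e) {
      child <- serialize(tree$edge[e, 2])
      child$str <- paste0(child$str, ":", format_brlen(tree$edge.length[e]))
      child
    })
    parts <- parts[order(vapply(parts, `[[`, "", "minlab"))]
    list(str = paste0("(", paste(vapply(parts, `[[`, "", "str"),
                                 collapse = ","), ")"),
         minlab = min(vapply(parts, `[[`, "", "minlab")))
  }
  s <- paste0(serialize(root)$str, ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

newick_label <- function(lab) {
  if (grepl("[][ \t(),:;']", lab)) {
    paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
  } else {
    lab
  }
}

format_brlen <- function(x) {
  sprintf("%.10g", x)
}
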