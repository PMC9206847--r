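#' Nearest-neighbor typing of query vectors
#'
#' For each query vector, finds the reference vector at minimal Euclidean
#' distance and reports its group ("type"). Distance ties are broken by the
#' lexicographically smallest reference id, so results are deterministic and
#' invariant under permutation of the reference pool. With
#' `exclude_self = TRUE` a reference sharing the query's id is skipped
#' (matching is by id, not by vector equality), which gives leave-one-out
#' behavior when the queries are a subset of the references.
#'
#' @param queries numeric matrix of query vectors, ids as row names.
#' @param references numeric matrix of reference vectors, ids as row names.
#' @param ref_groups data frame with columns `id`, `group` labeling the
#'   references (see [read_labels()]), or `NULL` to report ids only.
#' @param exclude_self skip the reference with the same id as the query.
#' @return data frame with columns `query_id`, `nearest_id`, `nearest_group`,
#'   `distance`.
#' @export
nearest_neighbor <- function(queries, references, ref_groups = NULL,
                             exclude_self = FALSE) {
  queries <- as_points(queries)
  references <- as_points(references)
  if (nrow(references) == 0) stop("empty reference pool", call. = FALSE)
  if (ncol(queries) != ncol(references)) stop("dimension mismatch", call. = FALSE)
  qid <- rownames(queries)
  rid <- rownames(references)
  if (is.null(qid)) qid <- paste0("q", seq_len(nrow(queries)))
  if (is.null(rid)) stop("references must have row names (ids)", call. = FALSE)
  grp <- function(id) {
    if (is.null(ref_groups)) return(NA_character_)
    g <- ref_groups$group[match(id, ref_groups$id)]
    if (is.na(g)) NA_character_ else g
  }
  D <- cross_dist(queries, references)
  res <- lapply(seq_len(nrow(queries)), function(i) {
    d <- D[i, ]
    keep <- rep(TRUE, length(d))
    if (exclude_self) keep <- rid != qid[[i]]
    if (!any(keep)) stop("no eligible reference for query '", qid[[i]],
                         "' after self-exclusion", call. = FALSE)
    ord <- order(d[keep], rid[keep])
    j <- which(keep)[ord[[1]]]
    data.frame(query_id = qid[[i]], nearest_id = rid[[j]],
               nearest_group = grp(rid[[j]]), distance = d[[j]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Tally of nearest-neighbor types per query group
#'
#' Cross-tabulates nearest-reference types by query group, the layout used to
#' summarize which domain of life each virus family's genomes resemble. Row
#' sums equal the query-group sizes. When sequence lengths are supplied,
#' per-group length summaries (max, min, mean, median) are appended.
#'
#' @param results data frame from [nearest_neighbor()].
#' @param query_groups data frame with columns `id`, `group` labeling the
#'   queries.
#' @param seq_lengths optional named numeric vector of sequence lengths
#'   (names are query ids).
#' @return data frame: one row per query group, `n` members, one count
#'   column per nearest type, and optional length summary columns.
#' @export
type_tally <- function(results, query_groups, seq_lengths = NULL) {
  g <- query_groups$group[match(results$query_id, query_groups$id)]
  if (anyNA(g)) stop("query id(s) missing from query_groups", call. = FALSE)
  tab <- table(group = g, nearest = results$nearest_group)
  out <- data.frame(group = rownames(tab), n = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (ty in colnames(tab)) out[[ty]] <- as.integer(tab[, ty])
  if (!is.null(seq_lengths)) {
    len <- seq_lengths[results$query_id]
    agg <- function(f) vapply(split(len, g), f, numeric(1))
    out$len_max <- agg(max)[out$group]
    out$len_min <- agg(min)[out$group]
    out$len_mean <- agg(mean)[out$group]
    out$len_median <- agg(stats::median)[out$group]
  }
  rownames(out) <- NULL
  out
}
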