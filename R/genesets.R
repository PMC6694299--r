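#' Row-scaled expression matrix for a gene set
#'
#' Restricts the normalized matrix to the members of a gene set present on
#' the panel and z-scores each row across samples (mean 0, SD 1). Members
#' absent from the panel are dropped with a warning; constant rows get
#' z-scores of zero.
#'
#' @param nm a `tg_norm` object.
#' @param genes character vector of gene-set members.
#' @return a list of class `tg_heatmap` with `values` (members x samples,
#'   row-scaled), `group` (per-sample factor); row order follows the input
#'   gene order.
#' @export
gene_set_matrix <- function(nm, genes) {
  stopifnot(inherits(nm, "tg_norm"))
  present <- genes[genes %in% rownames(nm$values)]
  dropped <- setdiff(genes, present)
  if (length(dropped) > 0)
    warning("gene-set member(s) not on panel, dropped: ",
            paste(dropped, collapse = ", "))
  if (length(present) == 0) stop("no gene-set member is on the panel")
  v <- nm$values[present, , drop = FALSE]
  mu <- rowMeans(v)
  sd_ <- apply(v, 1, stats::sd)
  z <- (v - mu) / ifelse(sd_ > 0, sd_, 1)
  structure(list(values = z, group = nm$group), class = "tg_heatmap")
}

#' k-means clustering with gap-statistic selection of k
#'
#' Clusters the rows of a heatmap matrix by k-means, choosing the number of
#' clusters with the gap statistic: `B` uniform reference datasets drawn
#' over the per-feature ranges of the data, and k selected as the smallest k
#' whose gap is within one simulation standard error of the next
#' (Tibshirani's criterion).
#'
#' @param hm a `tg_heatmap` from [gene_set_matrix()].
#' @param k_max largest k considered (must be below the number of rows).
#' @param B number of reference datasets.
#' @param seed integer seed (clustering and references are deterministic
#'   given the seed).
#' @return `hm` with added elements `row_cluster` (integer label per row)
#'   and `k_selected`, plus the `gap` table.
#' @export
kmeans_gap <- function(hm, k_max = 8, B = 50, seed = 1L) {
  stopifnot(inherits(hm, "tg_heatmap"))
  n <- nrow(hm$values)
  if (n < 2) stop("need at least 2 rows to cluster")
  if (k_max < 1) stop("k_max must be at least 1")
  if (k_max >= n) stop("k_max must be below the number of rows")
  set.seed(seed)
  km <- function(x, k) stats::kmeans(x, k, nstart = 20, iter.max = 50)
  gap <- cluster::clusGap(hm$values, FUNcluster = km, K.max = max(2, k_max),
                          B = B, spaceH0 = "original", verbose = FALSE)
  tab <- gap$Tab
  k_selected <- cluster::maxSE(tab[seq_len(k_max), "gap"],
                               tab[seq_len(k_max), "SE.sim"],
                               method = "Tibs2001SEmax")
  set.seed(seed)
  hm$row_cluster <- if (k_selected == 1) rep(1L, n) else
    km(hm$values, k_selected)$cluster
  hm$k_selected <- k_selected
  hm$gap <- tab
  hm
}

#' Rank network hubs by summed edge confidence
#'
#' Drops edges with confidence at or below the threshold, then scores every
#' node by the sum of confidences of its retained incident edges (a
#' self-loop counts once). Nodes are ranked by descending score, ties broken
#' by node id.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`
#'   (confidences in \[0,1\]; duplicated unordered pairs are an error).
#' @param threshold retention threshold (strictly greater-than); default 0.4.
#' @return a data.frame of class `tg_hubs` with columns `node`, `score`,
#'   `rank`, ordered by rank.
#' @export
top_regulators <- function(edges, threshold = 0.4) {
  edges <- as.data.frame(edges)
  if (!all(c("node_a", "node_b", "confidence") %in% names(edges)))
    stop("edges must have columns node_a, node_b, confidence")
  conf <- edges$confidence
  if (!is.numeric(conf) || any(!is.finite(conf)) || any(conf < 0 | conf > 1))
    stop("edge confidences must be numbers in [0,1]")
  key <- paste(pmin(edges$node_a, edges$node_b), pmax(edges$node_a, edges$node_b))
  if (anyDuplicated(key))
    stop("duplicated edge(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  keep <- conf > threshold
  score <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in which(keep)) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    score[a] <- score[a] + conf[i]
    if (b != a) score[b] <- score[b] + conf[i]
  }
  ord <- order(-score, names(score))
  out <- data.frame(node = names(score)[ord], score = unname(score)[ord],
                    rank = seq_along(score), stringsAsFactors = FALSE)
  class(out) <- c("tg_hubs", "data.frame")
  out
}
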