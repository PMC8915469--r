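#' Complete-linkage agglomerative clustering
#'
#' Standard agglomeration over a labelled distance matrix: at each of
#' the n-1 steps the pair of clusters at minimum inter-cluster
#' distance merges, where the inter-cluster distance is the maximum
#' pairwise distance between members (complete linkage, so merge
#' heights are non-decreasing). Ties are broken by the
#' lexicographically smallest pair of cluster indices in creation
#' order (leaves first, then merged clusters), which makes runs
#' bit-reproducible.
#'
#' @param d labelled symmetric distance matrix with >= 2 rows.
#' @return object of class `"linkage_tree"`: list with `labels`
#'   (leaf order as given), `merge` (hclust-style (n-1) x 2 integer
#'   matrix, negative entries are leaves), `height` (merge heights).
#' @seealso [subtree_height()], [to_newick()], [as.hclust.linkage_tree()]
#' @export
complete_linkage <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 samples to cluster", call. = FALSE)
  labels <- rownames(d)
  work <- unname(d)
  # cluster bookkeeping: code[i] is the hclust code of active cluster i
  # (negative leaf index or positive merge row); active clusters kept
  # in creation order.
  code <- -seq_len(n)
  created <- seq_len(n)                  # creation rank of slot occupant
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    idx <- idx[order(created[idx])]      # creation order for tie-breaks
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ii in seq_along(idx)[-length(idx)]) {
      i <- idx[ii]
      js <- idx[(ii + 1L):length(idx)]
      dij <- work[i, js]
      k <- which.min(dij)               # first minimum: smallest partner
      if (dij[k] < best_d) {            # strict: earliest pair kept on ties
        best_d <- dij[k]
        best <- c(i, js[k])
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- c(code[i], code[j])
    height[step] <- best_d
    # complete linkage: distance to the merged cluster is the max
    others <- setdiff(idx, c(i, j))
    newd <- pmax(work[i, others], work[j, others])
    work[i, others] <- newd
    work[others, i] <- newd
    code[i] <- step
    created[i] <- n + step
    active[j] <- FALSE
  }
  structure(list(labels = labels, merge = merge, height = height),
            class = "linkage_tree")
}

merge_leafsets <- function(tree) {
  m <- nrow(tree$merge)
  sets <- vector("list", m)
  for (k in seq_len(m)) {
    kids <- tree$merge[k, ]
    sets[[k]] <- c(if (kids[1] < 0) -kids[1] else sets[[kids[1]]],
                   if (kids[2] < 0) -kids[2] else sets[[kids[2]]])
  }
  sets
}

#' Height of the lowest node spanning a set of leaves
#'
#' Returns the cophenetic span of a leaf set: the merge height of the
#' lowest tree node whose leaf set contains all the given labels
#' (0 for a single leaf). Smaller spans mean the samples sit closer in
#' the dendrogram — the quantity behind "T60 samples merge lower than
#' T0 samples".
#'
#' @param tree a `"linkage_tree"`.
#' @param labels non-empty subset of the tree's leaf labels.
#' @return the spanning height (numeric scalar).
#' @export
subtree_height <- function(tree, labels) {
  stopifnot(inherits(tree, "linkage_tree"))
  if (length(labels) == 0L) stop("labels must be non-empty", call. = FALSE)
  leaf <- match(labels, tree$labels)
  if (anyNA(leaf)) {
    stop("unknown label(s): ",
         paste(labels[is.na(leaf)], collapse = ", "), call. = FALSE)
  }
  leaf <- unique(leaf)
  if (length(leaf) == 1L) return(0)
  sets <- merge_leafsets(tree)
  for (k in seq_along(sets)) {
    if (all(leaf %in% sets[[k]])) return(tree$height[k])
  }
  stop("internal error: no spanning node found")     # nocov
}

newick_quote <- function(x) {
  needs <- grepl("[][ ():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a linkage tree as Newick text
#'
#' Branch lengths are assigned so that every leaf-to-root path length
#' equals the root merge height (an ultrametric dendrogram). Labels
#' containing Newick metacharacters are single-quoted.
#'
#' @param tree a `"linkage_tree"`.
#' @param digits significant digits for branch lengths (default 10).
#' @return a Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 10) {
  stopifnot(inherits(tree, "linkage_tree"))
  labs <- newick_quote(tree$labels)
  fmt <- function(x) format(x, digits = digits, trim = TRUE,
                            scientific = FALSE)
  render <- function(code, parent_h) {
    if (code < 0) {
      paste0(labs[-code], ":", fmt(parent_h))
    } else {
      h <- tree$height[code]
      paste0("(", render(tree$merge[code, 1], h), ",",
             render(tree$merge[code, 2], h), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", render(tree$merge[root, 1], h), ",",
         render(tree$merge[root, 2], h), ");")
}

#' Convert a linkage tree to a base-R hclust object
#'
#' Useful for plotting with [stats::plot.hclust()] or cutting with
#' [stats::cutree()].
#'
#' @param x a `"linkage_tree"`.
#' @param ... unused.
#' @return an object of class `"hclust"`.
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  order <- unlist(lapply(nrow(x$merge), function(root) {
    walk <- function(code) {
      if (code < 0) -code else c(walk(x$merge[code, 1]),
                                 walk(x$merge[code, 2]))
    }
    walk(root)
  }))
  structure(list(merge = x$merge, height = x$height, order = order,
                 labels = x$labels, method = "complete",
                 call = match.call(), dist.method = "phi"),
            class = "hclust")
}

#' Cophenetic distance matrix of a linkage tree
#'
#' @param tree a `"linkage_tree"`.
#' @return labelled symmetric matrix of spanning heights per leaf pair.
#' @export
cophenetic_matrix <- function(tree) {
  n <- length(tree$labels)
  out <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  sets <- merge_leafsets(tree)
  for (k in seq_along(sets)) {
    kids <- tree$merge[k, ]
    left <- if (kids[1] < 0) -kids[1] else sets[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else sets[[kids[2]]]
    out[left, right] <- tree$height[k]
    out[right, left] <- tree$height[k]
  }
  out
}
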