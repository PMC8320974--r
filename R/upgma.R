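#' UPGMA hierarchical clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic averaging: the closest pair of
#' clusters is merged iteratively, cluster-to-cluster distance being the
#' arithmetic mean of all member pairwise distances (size-weighted update).
#' Node height is half the merge distance, so the result is ultrametric. Ties
#' are broken deterministically by merging the pair whose (label-sorted)
#' cluster representatives are lexicographically smallest.
#'
#' @param d symmetric distance matrix with labels (n >= 2); `NA`/`NaN`
#'   entries are rejected
#' @return object of class `upgma_tree`: list with `root` (recursive node
#'   structure: leaves are labels, internal nodes have `left`, `right`,
#'   `height`), `labels`, `heights` (merge heights in merge order)
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix contains NA/NaN or infinite values")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  dimnames(d) <- list(labels, labels)
  # active clusters
  nodes <- as.list(labels)              # recursive node structures
  reps <- labels                        # lexicographic representative label
  sizes <- rep(1L, n)
  act <- seq_len(n)
  D <- d
  heights <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(act)
    Dm <- D
    diag(Dm) <- Inf
    best <- which(Dm == min(Dm), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1) {
      key <- apply(best, 1, function(ij) {
        r <- sort(c(reps[ij[1]], reps[ij[2]]))
        paste(r, collapse = "\r")
      })
      best <- best[order(key), , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    h <- D[i, j] / 2
    heights[step] <- h
    new_node <- list(left = nodes[[i]], right = nodes[[j]], height = h)
    new_d <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], new_d[keep]),
               c(new_d[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
    reps <- c(reps[keep], min(reps[c(i, j)]))
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    act <- seq_len(m - 1L)
  }
  structure(list(root = nodes[[1]], labels = labels, heights = heights),
            class = "upgma_tree")
}

is_leaf <- function(node) is.character(node)

node_leaves <- function(node) {
  if (is_leaf(node)) return(node)
  c(node_leaves(node$left), node_leaves(node$right))
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common ancestor (equal to the merge distance at which they joined).
#'
#' @param tree an `upgma_tree`
#' @return symmetric labelled matrix
#' @export
cophenetic_upgma <- function(tree) {
  labs <- tree$labels
  n <- length(labs)
  cm <- matrix(0, n, n, dimnames = list(labs, labs))
  fill <- function(node) {
    if (is_leaf(node)) return(invisible(NULL))
    lv <- node_leaves(node$left); rv <- node_leaves(node$right)
    cm[lv, rv] <<- 2 * node$height
    cm[rv, lv] <<- 2 * node$height
    fill(node$left); fill(node$right)
  }
  fill(tree$root)
  cm
}

#' Check the ultrametric property of a UPGMA tree
#' @param tree an `upgma_tree`
#' @return TRUE if every internal node is at least as high as its children
#' @export
is_ultrametric <- function(tree) {
  ok <- TRUE
  walk <- function(node) {
    if (is_leaf(node)) return(0)
    hl <- walk(node$left); hr <- walk(node$right)
    if (node$height < max(hl, hr) - 1e-12) ok <<- FALSE
    node$height
  }
  walk(tree$root)
  ok
}

#' Serialise a UPGMA tree to Newick
#'
#' Branch lengths are parent height minus child height (leaves sit at height
#' zero), printed with 6 decimal places.
#'
#' @param tree an `upgma_tree`
#' @param path optional file to write; when `NULL` the string is returned
#' @param digits decimal places for branch lengths
#' @return the Newick string (invisibly when written to file)
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  rec <- function(node, parent_h) {
    if (is_leaf(node)) return(paste0(node, ":", fmt(parent_h)))
    paste0("(", rec(node$left, node$height), ",",
           rec(node$right, node$height), "):",
           fmt(parent_h - node$height))
  }
  root <- tree$root
  s <- paste0("(", rec(root$left, root$height), ",",
              rec(root$right, root$height), ");")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
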