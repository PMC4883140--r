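# Segment decomposition and the standard morphology metrics
# (total length, bifurcations, branches, tips).

#' Decompose a reconstruction into segments at critical nodes
#'
#' A segment is a maximal path between two critical nodes — roots, branch
#' nodes (>= 2 children) and tips — whose interior nodes each have exactly
#' one child. Segments partition the tree's edge set. Multifurcations start
#' one segment per child. For forests, every component is decomposed.
#'
#' @param tree a [neuron_tree].
#' @return list of segments; each is a list with `nodes` (ordered node-id
#'   vector from the proximal critical node `i` to the distal one `j`),
#'   `endpoints` `(i, j)` and `parent_segment` (index of the segment ending
#'   at `i`, or `NA` for segments starting at a root).
#' @export
decompose_segments <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0) return(list())
  kids <- tree_children(tree)
  nkids <- lengths(kids)[as.character(nd$id)]
  roots <- nd$id[nd$parent == -1L]
  segments <- list()
  seg_ending_at <- list()  # node id (chr) -> segment index
  # walk from every critical node downwards, in id order for determinism
  queue <- sort(roots)
  while (length(queue)) {
    start <- queue[1]; queue <- queue[-1]
    for (child in kids[[as.character(start)]]) {
      path <- c(start, child)
      cur <- child
      while (nkids[as.character(cur)] == 1L) {
        cur <- kids[[as.character(cur)]][1]
        path <- c(path, cur)
      }
      segments[[length(segments) + 1L]] <- list(
        nodes = path, endpoints = c(start, cur),
        parent_segment = if (as.character(start) %in% names(seg_ending_at))
          seg_ending_at[[as.character(start)]] else NA_integer_)
      seg_ending_at[[as.character(cur)]] <- length(segments)
      if (nkids[as.character(cur)] >= 2L) queue <- c(queue, cur)
    }
  }
  segments
}

#' Morphology metrics of a reconstruction
#'
#' Computes the standard reconstruction summary: total length (sum of
#' Euclidean parent-child edge lengths, in voxels), number of bifurcation
#' nodes (>= 2 children; a multifurcation counts once), number of branches
#' (segments from [decompose_segments()]), and number of tips (childless
#' non-root nodes). Forests are measured per component and summed.
#'
#' @param tree a [neuron_tree].
#' @return a list of class `morphology_report` with fields `total_length`,
#'   `n_bifurcations`, `n_branches`, `n_tips`.
#' @export
measure_morphology <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0) {
    return(structure(list(total_length = 0, n_bifurcations = 0L,
                          n_branches = 0L, n_tips = 0L),
                     class = "morphology_report"))
  }
  prow <- match(nd$parent, nd$id)
  has_parent <- !is.na(prow)
  dx <- nd$x[has_parent] - nd$x[prow[has_parent]]
  dy <- nd$y[has_parent] - nd$y[prow[has_parent]]
  dz <- nd$z[has_parent] - nd$z[prow[has_parent]]
  total <- sum(sqrt(dx^2 + dy^2 + dz^2))
  nchildren <- table(factor(nd$parent[has_parent], levels = nd$id))
  n_bif <- sum(nchildren >= 2)
  n_tip <- sum(nchildren == 0 & nd$parent != -1L)
  structure(list(total_length = total, n_bifurcations = as.integer(n_bif),
                 n_branches = length(decompose_segments(tree)),
                 n_tips = as.integer(n_tip)),
            class = "morphology_report")
}

#' @export
print.morphology_report <- function(x, ...) {
  cat(sprintf(
    "<morphology> length %.1f voxels, %d bifurcation(s), %d branch(es), %d tip(s)\n",
    x$total_length, x$n_bifurcations, x$n_branches, x$n_tips))
  invisible(x)
}

# (z,y,x) 1-based coordinates of a segment's node path
segment_zyx <- function(tree, seg) {
  rows <- tree_node_row(tree, seg$nodes)
  swc_to_zyx(cbind(tree$nodes$x[rows], tree$nodes$y[rows],
                   tree$nodes$z[rows]))
}

# Euclidean length of a segment's node path
segment_length <- function(tree, seg) {
  p <- segment_zyx(tree, seg)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}
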