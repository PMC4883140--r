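#' Neuron reconstruction tree
#'
#' An SWC-backed rooted tree. `nodes` is a data.frame with the standard seven
#' SWC columns: `id` (positive integer, unique), `type` (SWC type code),
#' `x`, `y`, `z` (0-based voxel coordinates, possibly fractional), `radius`
#' (voxels; missing or non-positive values are replaced by 1), and `parent`
#' (id of the parent node, or -1 for a root). Forests (several roots) are
#' permitted; cycles and dangling parents are not.
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent.
#' @param comments character vector of '#' comment lines kept for round-trips.
#' @return an object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, comments = character()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("`nodes` must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$radius[!is.finite(nodes$radius) | nodes$radius <= 0] <- 1
  tree <- structure(list(nodes = nodes, comments = comments),
                    class = "neuron_tree")
  validate_tree(tree)
}

validate_tree <- function(tree) {
  nd <- tree$nodes
  if (nrow(nd) == 0) return(tree)
  if (any(nd$id <= 0)) stop("node ids must be positive")
  if (anyDuplicated(nd$id)) stop("duplicate node ids")
  roots <- nd$parent == -1L
  if (!any(roots)) stop("tree has no root (parent = -1)")
  nonroot <- nd$parent[!roots]
  if (!all(nonroot %in% nd$id)) {
    bad <- setdiff(nonroot, nd$id)
    stop("dangling parent id(s): ", paste(bad, collapse = ", "))
  }
  # cycle check by traversal from roots: every node must be reached
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  reached <- character(0)
  queue <- nd$id[roots]
  seen <- logical(nrow(nd))
  names(seen) <- as.character(nd$id)
  while (length(queue)) {
    cur <- as.character(queue[1]); queue <- queue[-1]
    if (seen[cur]) stop("cycle detected at node ", cur)
    seen[cur] <- TRUE
    queue <- c(queue, kids[[cur]])
  }
  if (!all(seen)) {
    stop("cycle detected: node(s) unreachable from any root: ",
         paste(names(seen)[!seen], collapse = ", "))
  }
  tree
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf("<neuron_tree> %d nodes, %d root(s)\n",
              nrow(x$nodes), sum(x$nodes$parent == -1L)))
  invisible(x)
}

#' Read an SWC reconstruction file
#'
#' Parses the standard 7-column whitespace-separated SWC format. Lines
#' starting with `#` are kept as comments and re-emitted by [write_swc()].
#' Malformed lines and structural faults (dangling parents, cycles) raise
#' errors; records are never silently dropped.
#'
#' @param path path to an SWC file.
#' @return a [neuron_tree].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  stripped <- trimws(raw)
  comments <- raw[startsWith(stripped, "#")]
  data_lines <- which(nzchar(stripped) & !startsWith(stripped, "#"))
  if (length(data_lines) == 0) {
    return(neuron_tree(data.frame(id = integer(), type = integer(),
                                  x = numeric(), y = numeric(), z = numeric(),
                                  radius = numeric(), parent = integer()),
                       comments = comments))
  }
  fields <- strsplit(stripped[data_lines], "[[:space:]]+")
  nfield <- lengths(fields)
  if (any(nfield != 7)) {
    bad <- data_lines[which(nfield != 7)[1]]
    stop("malformed SWC line ", bad, ": expected 7 fields, got ",
         nfield[which(nfield != 7)[1]])
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    bad <- data_lines[which(rowSums(is.na(m)) > 0)[1]]
    stop("malformed SWC line ", bad, ": non-numeric field")
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  neuron_tree(nodes, comments = comments)
}

#' Write a neuron tree to an SWC file
#'
#' Emits standard 7-column SWC ordered by node id, preceded by any stored
#' comment lines. When `color_scores` is given (a per-node scalar, e.g. a
#' segment confidence score), a sidecar file `<path>.scores.tsv` with columns
#' `id` and `score` is written alongside so viewers can color the
#' reconstruction by score.
#'
#' @param tree a [neuron_tree].
#' @param path output file path.
#' @param color_scores optional numeric vector, one value per node (aligned
#'   with `tree$nodes` rows or named by node id).
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path, color_scores = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  nd <- tree$nodes[order(tree$nodes$id), , drop = FALSE]
  fmt <- function(v) {
    out <- formatC(v, format = "fg", digits = 15)
    trimws(out)
  }
  lines <- c(tree$comments,
             sprintf("%d %d %s %s %s %s %d", nd$id, nd$type,
                     fmt(nd$x), fmt(nd$y), fmt(nd$z), fmt(nd$radius),
                     nd$parent))
  writeLines(lines, path)
  if (!is.null(color_scores)) {
    if (!is.null(names(color_scores))) {
      sc <- color_scores[as.character(nd$id)]
    } else {
      if (length(color_scores) != nrow(nd))
        stop("`color_scores` must have one value per node")
      sc <- color_scores[order(tree$nodes$id)]
    }
    writeLines(c("id\tscore", sprintf("%d\t%g", nd$id, sc)),
               paste0(path, ".scores.tsv"))
  }
  invisible(path)
}

# children ids per node id (named list)
tree_children <- function(tree) {
  nd <- tree$nodes
  split(nd$id, factor(nd$parent, levels = nd$id))
}

# node rows by id
tree_node_row <- function(tree, ids) {
  match(ids, tree$nodes$id)
}

#' Accept an externally produced SWC reconstruction
#'
#' Adapter for plugging any third-party tracer into the pipeline by file
#' exchange: reads and validates the SWC and tags it with its provenance.
#'
#' @param path path to the SWC file written by the external tracer.
#' @return a [neuron_tree] with a `provenance` attribute.
#' @export
trace_adapter <- function(path) {
  tree <- read_swc(path)
  attr(tree, "provenance") <- sprintf("external:%s", basename(path))
  tree
}
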