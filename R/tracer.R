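# Minimal shortest-path-tree tracer used for the initial and final tracing
# passes. Deliberately simple and deliberately gap-limited: it only traces
# the thresholded connected component containing the soma seed, so a signal
# gap truncates the reconstruction — closing gaps is the learning stage's
# job, not the tracer's.

#' Baseline tracer configuration
#'
#' @param background_threshold voxels with intensity >= this are foreground.
#' @param soma_seed `"auto"` (the global intensity maximum; ties go to the
#'   lowest linear voxel index) or a 1-based `(z, y, x)` voxel.
#' @param min_branch_length prune traced branches shorter than this (voxels).
#' @param connectivity 26 (default) or 6.
#' @return an object of class `tracer_config`.
#' @export
tracer_config <- function(background_threshold = 30, soma_seed = "auto",
                          min_branch_length = 5, connectivity = 26) {
  if (background_threshold < 0) stop("threshold must be >= 0")
  structure(list(background_threshold = background_threshold,
                 soma_seed = soma_seed,
                 min_branch_length = min_branch_length,
                 connectivity = connectivity),
            class = "tracer_config")
}

#' Trace a neuron with the built-in shortest-path-tree tracer
#'
#' Pipeline: (i) threshold the image to foreground; (ii) keep only the
#' connected component containing the soma seed (this is what makes the
#' tracer stop at signal gaps); (iii) build an intensity-weighted
#' shortest-path tree from the seed over that component (same cost function
#' as the confidence module's path search); (iv) extract a centerline tree
#' by repeatedly walking back from the unclaimed voxel with the largest
#' geodesic cost until reaching the existing tree, accepting the walk as a
#' branch when it adds at least `min_branch_length` voxels of length and
#' claiming a tube around it; (v) estimate per-node radius as the Euclidean
#' distance to the nearest background voxel.
#'
#' @param img an [image3d].
#' @param cfg a [tracer_config()].
#' @return a [neuron_tree]; node coordinates are 0-based SWC `(x, y, z)`.
#' @export
baseline_trace <- function(img, cfg = tracer_config()) {
  stopifnot(inherits(img, "image3d"), inherits(cfg, "tracer_config"))
  dims <- dim(img$data)
  n <- prod(dims)
  fg <- as.vector(img$data >= cfg$background_threshold)
  if (!any(fg)) stop("no voxel reaches the background threshold")

  if (identical(cfg$soma_seed, "auto")) {
    seed_idx <- which.max(img$data)
  } else {
    seed_idx <- vox_index(dims, matrix(round(as.numeric(cfg$soma_seed)), 1))
  }
  if (!fg[seed_idx]) {  # snap the seed to the nearest foreground voxel
    fg_idx <- which(fg)
    co <- vox_coords(dims, fg_idx)
    sc <- vox_coords(dims, seed_idx)
    d2 <- (co[, 1] - sc[1])^2 + (co[, 2] - sc[2])^2 + (co[, 3] - sc[3])^2
    seed_idx <- fg_idx[which.min(d2)]
  }

  radius <- sqrt(cpp_edt_sq(!fg, as.integer(dims)))
  radius <- pmax(radius, 0.5)

  # hill-climb a voxel onto the local ridge of the distance-to-background
  # map (the tube centerline), so node radii span the full cross-section
  snap_to_ridge <- function(idx) {
    for (step in 1:4) {
      co <- vox_coords(dims, idx)
      zr <- max(1, co[1] - 1):min(dims[1], co[1] + 1)
      yr <- max(1, co[2] - 1):min(dims[2], co[2] + 1)
      xr <- max(1, co[3] - 1):min(dims[3], co[3] + 1)
      nb <- as.matrix(expand.grid(zr, yr, xr))
      nb_idx <- vox_index(dims, nb)
      nb_idx <- nb_idx[fg[nb_idx]]
      best <- nb_idx[which.max(radius[nb_idx])]
      if (radius[best] <= radius[idx]) break  # strict ascent only
      idx <- best
    }
    idx
  }

  seed_idx <- snap_to_ridge(seed_idx)
  nodecost <- (1 - as.vector(img$data) / max(img$data))^2 + 1e-6
  sp <- cpp_grid_dijkstra(as.integer(dims), nodecost, seed_idx - 1, -1,
                          fg, as.integer(cfg$connectivity))
  reach <- is.finite(sp$dist)  # the seed's connected component

  covered <- rep(FALSE, n)
  node_of <- integer(n)  # voxel -> node id (0 = none)
  nodes_z <- nodes_y <- nodes_x <- numeric(0)
  nodes_r <- numeric(0)
  nodes_parent <- integer(0)

  add_node <- function(idx, parent_id) {
    co <- vox_coords(dims, idx)
    nodes_z[length(nodes_z) + 1L] <<- co[1]
    nodes_y[length(nodes_y) + 1L] <<- co[2]
    nodes_x[length(nodes_x) + 1L] <<- co[3]
    nodes_r[length(nodes_r) + 1L] <<- radius[idx]
    nodes_parent[length(nodes_parent) + 1L] <<- parent_id
    node_of[idx] <<- length(nodes_z)
    length(nodes_z)
  }
  stamp_cover <- function(idxs) {
    pts <- vox_coords(dims, idxs)
    covered <<- cpp_stamp_spheres(covered, as.integer(dims),
                                  matrix(as.numeric(pts), ncol = 3),
                                  radius[idxs] + 2)
  }

  add_node(seed_idx, -1L)
  covered[seed_idx] <- TRUE
  stamp_cover(seed_idx)

  # candidates ranked by geodesic path length (furthest leaf first)
  pool <- sp$pathlen
  pool[!reach | covered] <- -Inf
  max_branches <- 10000L
  for (iter in seq_len(max_branches)) {
    cand <- which.max(pool)
    if (!is.finite(pool[cand])) break
    # walk back the shortest-path tree until an existing tree node
    path <- cand
    cur <- cand
    while (node_of[cur] == 0L) {
      p <- sp$parent[cur] + 1
      if (p <= 0) break
      cur <- as.integer(p)
      path <- c(cur, path)
    }
    attach_idx <- path[1]
    new_idx <- path[-1]
    co <- vox_coords(dims, path)
    steps <- sqrt(rowSums((co[-1, , drop = FALSE] -
                           co[-nrow(co), , drop = FALSE])^2))
    # only the genuinely new (uncovered) extent counts toward acceptance,
    # otherwise surface bumps re-thread long covered stretches as branches
    new_len <- sum(steps[!covered[new_idx]])
    if (new_len >= cfg$min_branch_length && length(new_idx) > 0 &&
        node_of[attach_idx] > 0L) {
      parent <- node_of[attach_idx]
      snapped_all <- integer(0)
      for (idx in new_idx) {
        snapped <- snap_to_ridge(idx)
        if (node_of[snapped] > 0L) {
          parent <- node_of[snapped]
        } else {
          parent <- add_node(snapped, parent)
          snapped_all <- c(snapped_all, snapped)
        }
        if (node_of[idx] == 0L) node_of[idx] <- parent
      }
      stamp_cover(unique(c(new_idx, snapped_all)))
      covered[new_idx] <- TRUE
      pool[covered] <- -Inf
    } else {
      pool[path] <- -Inf  # pruned: too short to matter
    }
    pool[cand] <- -Inf
  }

  # light Laplacian smoothing of chain nodes: ridge plateaus in thick tubes
  # make consecutive snapped nodes bounce laterally, inflating path length
  nkids <- tabulate(nodes_parent[nodes_parent > 0], nbins = length(nodes_z))
  prow <- ifelse(nodes_parent > 0, nodes_parent, NA_integer_)
  kid <- rep(NA_integer_, length(nodes_z))
  single <- which(nkids == 1)
  for (i in seq_along(nodes_parent)) {
    p <- nodes_parent[i]
    if (p > 0 && nkids[p] == 1) kid[p] <- i
  }
  movable <- which(!is.na(prow) & !is.na(kid))
  for (pass in 1:2) {
    if (!length(movable)) break
    nz2 <- nodes_z; ny2 <- nodes_y; nx2 <- nodes_x
    nz2[movable] <- 0.25 * nodes_z[prow[movable]] + 0.5 * nodes_z[movable] +
      0.25 * nodes_z[kid[movable]]
    ny2[movable] <- 0.25 * nodes_y[prow[movable]] + 0.5 * nodes_y[movable] +
      0.25 * nodes_y[kid[movable]]
    nx2[movable] <- 0.25 * nodes_x[prow[movable]] + 0.5 * nodes_x[movable] +
      0.25 * nodes_x[kid[movable]]
    nodes_z <- nz2; nodes_y <- ny2; nodes_x <- nx2
  }

  ids <- seq_along(nodes_z)
  xyz <- zyx_to_swc(cbind(nodes_z, nodes_y, nodes_x))
  tree <- neuron_tree(data.frame(
    id = ids, type = c(1L, rep(3L, length(ids) - 1L)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = nodes_r, parent = nodes_parent),
    comments = sprintf(
      "# baseline shortest-path-tree trace: threshold %g, min branch %g",
      cfg$background_threshold, cfg$min_branch_length))
  tree <- prune_short_tips(tree, cfg$min_branch_length)
  attr(tree, "provenance") <- "baseline_trace"
  tree
}

# iteratively remove terminal twigs shorter than min_len (walk-back paths
# around branch points occasionally leave 1-2 node stubs behind)
prune_short_tips <- function(tree, min_len) {
  repeat {
    nd <- tree$nodes
    kids <- table(factor(nd$parent, levels = nd$id))
    tips <- nd$id[kids[as.character(nd$id)] == 0 & nd$parent != -1L]
    drop <- integer(0)
    for (tp in tips) {
      path <- tp
      cur <- tp
      repeat {
        p <- nd$parent[match(cur, nd$id)]
        if (p == -1L || kids[as.character(p)] >= 2) break
        path <- c(path, p)
        cur <- p
      }
      rows <- match(path, nd$id)
      if (length(rows) >= 2) {
        len <- sum(sqrt(diff(nd$x[rows])^2 + diff(nd$y[rows])^2 +
                        diff(nd$z[rows])^2))
      } else {
        len <- 0
      }
      if (len < min_len) drop <- c(drop, path)
    }
    drop <- setdiff(drop, nd$id[nd$parent == -1L])
    if (!length(drop)) return(tree)
    if (length(drop) >= nrow(nd) - 1) return(tree)  # keep a 1-node tree max pruned
    tree <- neuron_tree(nd[!nd$id %in% drop, , drop = FALSE],
                        comments = tree$comments)
  }
}
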