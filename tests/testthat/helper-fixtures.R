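# Shared test fixtures, built in code and cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, .fixture_cache)) assign(name, builder(), .fixture_cache)
  get(name, .fixture_cache)
}

# straight noiseless tube: x 8..55 (SWC), centerline (z, y) = (16, 16)
tube_phantom <- function() cached("tube", function() {
  spec <- phantom_spec(c(32, 32, 64),
                       branches = list(rbind(c(8, 16, 16), c(55, 16, 16))),
                       tube_radius = 2)
  c(generate_phantom(spec), list(spec = spec, soma_seed = c(17, 17, 9)))
})

# the same tube with a 4-voxel gap at half length
gap_tube_phantom <- function() cached("gap_tube", function() {
  spec <- phantom_spec(c(32, 32, 64),
                       branches = list(rbind(c(8, 16, 16), c(55, 16, 16))),
                       tube_radius = 2,
                       gaps = list(list(branch = 1, start_frac = 0.5,
                                        length = 4)))
  c(generate_phantom(spec), list(spec = spec, soma_seed = c(17, 17, 9)))
})

# Y-shaped phantom; both arms long enough to survive coverage pruning
y_phantom <- function() cached("y", function() {
  spec <- phantom_spec(c(48, 64, 96),
                       branches = list(rbind(c(10, 32, 24), c(70, 32, 24)),
                                       rbind(c(40, 32, 24), c(70, 55, 24))),
                       tube_radius = 2)
  c(generate_phantom(spec), list(spec = spec, soma_seed = c(25, 33, 11)))
})

# hand-built trees ------------------------------------------------------

chain_tree <- function(coords, radius = 1) {
  n <- nrow(coords)
  neuron_tree(data.frame(id = seq_len(n), type = c(1L, rep(3L, n - 1)),
                         x = coords[, 1], y = coords[, 2], z = coords[, 3],
                         radius = radius,
                         parent = c(-1L, seq_len(n - 1))))
}

# root(1)-stem(2)-fork(3) with arms 4-5 and 6-7
y_tree <- function() {
  neuron_tree(data.frame(
    id = 1:7, type = c(1L, rep(3L, 6)),
    x = c(0, 1, 2, 3, 4, 3, 4), y = c(0, 0, 0, 1, 2, -1, -2),
    z = 0, radius = 1,
    parent = c(-1L, 1L, 2L, 3L, 4L, 3L, 6L)))
}

random_tree <- function(n = 50, seed = 7) {
  set.seed(seed)
  parent <- c(-1L, vapply(2:n, function(i) sample.int(i - 1L, 1), 1L))
  neuron_tree(data.frame(id = seq_len(n), type = 3L,
                         x = runif(n, 0, 30), y = runif(n, 0, 30),
                         z = runif(n, 0, 30), radius = 1, parent = parent))
}

# independent Dijkstra oracle over the full voxel graph (igraph)
dijkstra_oracle_cost <- function(img, from, to, connectivity = 26,
                                 eps = 1e-6, i_max = NULL, blocked = NULL) {
  dims <- dim(img$data)
  mx <- if (is.null(i_max)) max(img$data) else i_max
  nodecost <- (1 - as.vector(img$data) / mx)^2 + eps
  idx <- array(seq_len(prod(dims)), dims)
  edges <- NULL; weights <- NULL
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dz == 0 & offs$dy == 0 & offs$dx == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dz) + abs(offs$dy) + abs(offs$dx) == 1, ]
  ok_vox <- if (is.null(blocked)) rep(TRUE, prod(dims)) else !as.vector(blocked)
  el <- list(); wl <- list()
  for (k in seq_len(nrow(offs))) {
    o <- as.numeric(offs[k, ])
    zr <- seq(max(1, 1 - o[1]), min(dims[1], dims[1] - o[1]))
    yr <- seq(max(1, 1 - o[2]), min(dims[2], dims[2] - o[2]))
    xr <- seq(max(1, 1 - o[3]), min(dims[3], dims[3] - o[3]))
    a <- as.vector(idx[zr, yr, xr])
    b <- as.vector(idx[zr + o[1], yr + o[2], xr + o[3]])
    keep <- ok_vox[a] & ok_vox[b]
    a <- a[keep]; b <- b[keep]
    el[[k]] <- rbind(a, b)
    wl[[k]] <- 0.5 * (nodecost[a] + nodecost[b]) * sqrt(sum(o^2))
  }
  g <- igraph::make_graph(as.vector(do.call(cbind, el)),
                          n = prod(dims), directed = FALSE)
  w <- unlist(wl)
  src <- selftrace:::vox_index(dims, matrix(from, 1))
  dst <- selftrace:::vox_index(dims, matrix(to, 1))
  as.numeric(igraph::distances(g, v = src, to = dst, weights = w,
                               algorithm = "dijkstra"))
}
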