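# segment masking, alternative paths, and confidence scores

test_that("masking zeroes the segment tube but protects the endpoints", {
  ph <- tube_phantom()
  tr <- baseline_trace(ph$image,
                       tracer_config(30, ph$soma_seed))
  seg <- decompose_segments(tr)[[1]]
  masked <- mask_segment(ph$image, seg, tr)
  expect_s3_class(masked, "image3d")
  # original untouched
  expect_equal(max(ph$image$data), 200)
  # centerline interior is zero away from the protected endpoints
  pts <- selftrace:::segment_zyx(tr, seg)
  interior <- pts[8:(nrow(pts) - 8), , drop = FALSE]
  expect_true(all(selftrace:::interp_intensity(masked, interior) == 0))
  # masking twice equals masking once
  expect_identical(mask_segment(masked, seg, tr)$data, masked$data)
})

test_that("masked voxel count matches a brute-force distance check", {
  img <- image3d(array(100, c(24, 24, 24)))
  tr <- chain_tree(cbind(c(6, 17), c(11, 11), c(11, 11)), radius = 1.5)
  seg <- decompose_segments(tr)[[1]]
  masked <- mask_segment(img, seg, tr)
  got <- which(masked$data == 0)
  # brute force: voxels within the tube radius of the segment line,
  # outside protection spheres of radius tube_r + 1 at the endpoints
  tube_r <- max(1.5, 1) + 1
  prot_r <- tube_r + 1
  co <- selftrace:::vox_coords(dim(img$data), seq_along(img$data))
  a <- c(12, 12, 7); b <- c(12, 12, 18)   # (z,y,x), 1-based
  v <- b - a
  w <- sweep(co, 2, a)
  t <- pmin(pmax(w %*% v / sum(v^2), 0), 1)
  d <- sqrt(rowSums((w - outer(as.vector(t), v))^2))
  de1 <- sqrt(rowSums(sweep(co, 2, a)^2))
  de2 <- sqrt(rowSums(sweep(co, 2, b)^2))
  want <- which(d <= tube_r & de1 > prot_r & de2 > prot_r)
  expect_equal(got, want)
})

test_that("uniform-intensity path search finds the straight geodesic", {
  img <- image3d(array(100, c(12, 12, 12)))
  ap <- alternative_path(img, c(2, 2, 2), c(2, 2, 11))
  expect_equal(nrow(ap$path), 10)           # straight 26-connected line
  expect_equal(ap$cost, 9 * 1e-6, tolerance = 1e-9)
  apd <- alternative_path(img, c(2, 2, 2), c(11, 11, 11))
  expect_equal(apd$cost, 9 * sqrt(3) * 1e-6, tolerance = 1e-9)
})

test_that("path cost equals an independent Dijkstra oracle", {
  set.seed(21)
  for (conn in c(26, 6)) {
    img <- image3d(array(sample(0:200, 16^3, TRUE), c(16, 16, 16)))
    from <- c(2, 3, 2); to <- c(14, 12, 15)
    ap <- alternative_path(img, from, to, connectivity = conn)
    oracle <- dijkstra_oracle_cost(img, from, to, connectivity = conn)
    expect_equal(ap$cost, oracle, tolerance = 1e-10)
  }
  # with a blocked corridor
  img <- image3d(array(sample(0:200, 12^3, TRUE), c(12, 12, 12)))
  blocked <- array(FALSE, c(12, 12, 12)); blocked[5:8, 5:8, ] <- TRUE
  blocked[, , 1:2] <- FALSE
  ap <- alternative_path(img, c(2, 2, 2), c(11, 11, 11), blocked = blocked)
  oracle <- dijkstra_oracle_cost(img, c(2, 2, 2), c(11, 11, 11),
                                 blocked = blocked)
  expect_equal(ap$cost, oracle, tolerance = 1e-10)
  expect_false(any(blocked[ap$path]))
})

test_that("the alternative path follows the bright half of a loop", {
  lp <- make_loop_phantom(c(16, 56, 56), loop_radius = 16)
  seg <- decompose_segments(lp$tree)[[1]]
  tube <- selftrace:::segment_mask_voxels(lp$image, seg, lp$tree)
  masked <- lp$image; masked$data[tube] <- 0
  ends <- selftrace:::segment_zyx(lp$tree, seg)
  ap <- alternative_path(masked, ends[1, ], ends[nrow(ends), ],
                         i_max = max(lp$image$data), blocked = tube)
  ival <- lp$image$data[cbind(ap$path)]
  expect_gte(mean(ival > 10 + 3 * 1e-9), 0.9)  # >=90% of voxels on signal
})

test_that("mean path intensity is the arc-length-weighted trapezoid", {
  img <- image3d(array(100, c(8, 8, 8)))
  expect_equal(mean_path_intensity(img, rbind(c(2, 2, 2), c(6, 3, 7))), 100)

  img2 <- image3d(array(0, c(4, 4, 4)))
  img2$data[2, 2, 2] <- 10; img2$data[2, 2, 3] <- 30
  expect_equal(mean_path_intensity(img2, rbind(c(2, 2, 2), c(2, 2, 3))), 20)

  # random path on a random image matches the brute-force computation
  set.seed(5)
  img3 <- image3d(array(sample(0:255, 10^3, TRUE), c(10, 10, 10)))
  path <- cbind(runif(12, 1, 10), runif(12, 1, 10), runif(12, 1, 10))
  manual <- 0; total <- 0
  for (k in 1:(nrow(path) - 1)) {
    ds <- sqrt(sum((path[k + 1, ] - path[k, ])^2))
    iv <- selftrace:::interp_intensity(img3, path[c(k, k + 1), ])
    manual <- manual + mean(iv) * ds
    total <- total + ds
  }
  expect_equal(mean_path_intensity(img3, path), manual / total)
  expect_error(mean_path_intensity(img3, rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
})

test_that("confidence separates isolated tubes, loops, and duplicates", {
  iso <- fixture_isolated_tube()
  tr <- baseline_trace(iso$image, tracer_config(30, iso$soma_seed))
  r_iso <- score_segments(iso$image, tr, threshold = 0.5)
  expect_lte(r_iso$table$score[1], 0.3)
  expect_equal(r_iso$table$label[1], "confident")

  lp <- make_loop_phantom(c(24, 64, 64), loop_radius = 20)
  r_loop <- score_segments(lp$image, lp$tree, threshold = 0.5)
  expect_gte(r_loop$table$score[1], 0.8)
  expect_equal(r_loop$table$label[1], "uncertain")

  par <- fixture_parallel_tubes()
  r_par <- score_segments(par$image, par$tree, threshold = 0.5)
  expect_gte(r_par$table$score[1], 0.9)
  expect_lte(r_par$table$score[1], 1.1)
})

test_that("scores are invariant under global intensity scaling", {
  iso <- fixture_isolated_tube()
  tr <- baseline_trace(iso$image, tracer_config(30, iso$soma_seed))
  s1 <- score_segments(iso$image, tr)$table$score[1]
  half <- iso$image; half$data <- half$data / 2
  s2 <- score_segments(half, tr)$table$score[1]
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("brightening the alternative corridor never lowers the score", {
  scores <- vapply(c(120, 160, 200), function(fg2) {
    spec <- phantom_spec(c(16, 48, 48),
                         branches = list(rbind(c(8, 12, 8), c(40, 12, 8)),
                                         rbind(c(8, 30, 8), c(40, 30, 8))),
                         tube_radius = 2,
                         foreground_intensity = c(200, fg2))
    ph <- generate_phantom(spec)
    spec1 <- spec
    spec1$branches <- spec$branches[1]
    spec1$tube_radius <- spec$tube_radius[1]
    tr <- selftrace:::phantom_ground_truth(spec1)
    score_segments(ph$image, tr)$table$score[1]
  }, 0)
  expect_true(all(diff(scores) >= -1e-9))
})

test_that("short segments inherit their parent's label", {
  ph <- y_phantom()
  # append a tiny 2-node spur to the ground-truth tree
  nd <- ph$tree$nodes
  tipid <- max(nd$id)
  spur <- data.frame(id = tipid + 1L, type = 3L,
                     x = nd$x[1] + 1, y = nd$y[1] + 1, z = nd$z[1],
                     radius = 1, parent = nd$id[1])
  tr2 <- neuron_tree(rbind(nd, spur))
  r <- score_segments(ph$image, tr2, threshold = 0.5)
  short <- which(!r$table$scored)
  expect_true(length(short) >= 1)
  expect_true(all(r$table$label[short] %in% c("confident", "uncertain")))
  # the spur hangs off the confident root segment, so it is confident
  expect_true(all(r$table$label[short] == "confident"))
})

test_that("brightfield scoring works on the inverted convention", {
  spec <- phantom_spec(c(24, 40, 96),
                       branches = list(rbind(c(10, 20, 12), c(85, 20, 12))),
                       tube_radius = 2, foreground_intensity = 20,
                       background_intensity = 200, brightfield = TRUE)
  ph <- generate_phantom(spec)
  r <- score_segments(ph$image, ph$tree, threshold = 0.5, invert = TRUE)
  expect_lte(r$table$score[1], 0.3)
  expect_equal(r$table$label[1], "confident")
  expect_true(r$inverted)
})
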