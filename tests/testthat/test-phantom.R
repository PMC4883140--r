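# synthetic phantom generator

test_that("straight tube renders bright centerline and exact background", {
  ph <- tube_phantom()
  ctr <- selftrace:::swc_to_zyx(as.matrix(ph$tree$nodes[, c("x", "y", "z")]))
  ival <- selftrace:::interp_intensity(ph$image, ctr)
  expect_true(all(ival >= 0.9 * 200))
  # with zero noise, voxels beyond the tube dilation are exactly background
  dims <- dim(ph$image$data)
  dist <- selftrace:::cpp_polyline_dist(rep(Inf, prod(dims)), dims,
                                        ctr, 1e9)
  expect_true(all(ph$image$data[dist > 3.5] == 10))
})

test_that("identical spec and seed give bit-identical noisy volumes", {
  spec <- phantom_spec(c(16, 16, 32),
                       branches = list(rbind(c(4, 8, 8), c(27, 8, 8))),
                       tube_radius = 1.5, noise_sigma = 8, seed = 99)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$image$data, b$image$data)
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(generate_phantom(spec2)$image$data, a$image$data))
})

test_that("Y-phantom ground truth has one bifurcation and two tips", {
  ph <- y_phantom()
  m <- measure_morphology(ph$tree)
  expect_equal(m$n_bifurcations, 1L)
  expect_equal(m$n_tips, 2L)
  expect_equal(m$n_branches, 3L)
})

test_that("ground-truth length matches the analytic polyline length", {
  for (branches in list(
    list(rbind(c(8, 16, 16), c(55, 16, 16))),
    list(rbind(c(10, 32, 24), c(70, 32, 24)),
         rbind(c(40, 32, 24), c(70, 55, 24))),
    list(rbind(c(8, 10, 10), c(30, 24, 20), c(55, 12, 14))))) {
    spec <- phantom_spec(c(48, 64, 96), branches = branches, tube_radius = 2)
    analytic <- sum(vapply(branches, selftrace:::polyline_length, 0))
    got <- measure_morphology(generate_phantom(spec)$tree)$total_length
    expect_lt(abs(got - analytic) / analytic, 0.005)
  }
})

test_that("listed gaps drop the centerline to background level", {
  ph <- gap_tube_phantom()
  # gap: start_frac 0.5 of a 47-long tube from x = 8, so x ~ 31.5..35.5
  expect_true(all(ph$image$data[17, 17, 34:36] == 10))
  # flanks stay bright
  expect_equal(ph$image$data[17, 17, 20], 200)
  expect_equal(ph$image$data[17, 17, 50], 200)
})

test_that("phantom validation rejects bad specs", {
  expect_error(phantom_spec(c(16, 16, 16),
                            branches = list(rbind(c(1, 8, 8), c(14, 8, 8))),
                            tube_radius = 3),
               "out of bounds")
  expect_error(phantom_spec(c(32, 32, 32),
                            branches = list(rbind(c(8, 16, 16), c(24, 16, 16))),
                            foreground_intensity = 5,
                            background_intensity = 10),
               "exceed")
  expect_error(phantom_spec(c(32, 32, 32),
                            branches = list(rbind(c(8, 16, 16), c(24, 16, 16))),
                            gaps = list(list(branch = 1, start_frac = 0.1,
                                             length = 50))),
               "gap length")
  expect_error(make_loop_phantom(c(24, 64, 64), loop_radius = 0), "positive")
})

test_that("brightfield phantoms invert the intensity convention", {
  spec <- phantom_spec(c(24, 24, 48),
                       branches = list(rbind(c(6, 12, 12), c(40, 12, 12))),
                       tube_radius = 2, foreground_intensity = 20,
                       background_intensity = 200, brightfield = TRUE)
  ph <- generate_phantom(spec)
  expect_equal(ph$image$data[13, 13, 20], 20)   # dark tube
  expect_equal(ph$image$data[3, 3, 3], 200)     # bright background
})

test_that("loop phantom halves are equally bright and the tree covers half", {
  lp <- make_loop_phantom(c(16, 64, 64), loop_radius = 18)
  img <- lp$image
  z0 <- (16 - 1) / 2 + 1
  # sample both halves of the circle at matching angles
  ang <- seq(0.2, pi - 0.2, length.out = 25)
  cx <- (64 - 1) / 2 + 1; cy <- (64 - 1) / 2 + 1
  top <- selftrace:::interp_intensity(img, cbind(z0, cy + 18 * sin(ang),
                                                 cx + 18 * cos(ang)))
  bot <- selftrace:::interp_intensity(img, cbind(z0, cy - 18 * sin(ang),
                                                 cx + 18 * cos(ang)))
  expect_gte(mean(bot), 0.9 * mean(top))
  # the tree spans only the traced half
  expect_true(all(lp$tree$nodes$y >= cy - 1.5))
})

test_that("intensity ramps modulate signal but leave background exact", {
  spec <- phantom_spec(c(24, 24, 64),
                       branches = list(rbind(c(8, 12, 12), c(52, 12, 12))),
                       tube_radius = 2, intensity_gradient = c(0, 0, 0.5))
  ph <- generate_phantom(spec)
  lo <- ph$image$data[13, 13, 12]
  hi <- ph$image$data[13, 13, 50]
  expect_gt(hi, lo)
  expect_equal(ph$image$data[3, 3, 3], 10)
})
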