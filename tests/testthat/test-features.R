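# wavelet features, mutual information, and mRMR selection

test_that("one decomposition level yields 8 half-size subbands", {
  set.seed(2)
  for (side in c(8L, 16L)) {
    cube <- array(rnorm(side^3), rep(side, 3))
    sb <- dwt3_level(cube)
    expect_named(sb, c("LLL", "LLH", "LHL", "LHH",
                       "HLL", "HLH", "HHL", "HHH"))
    expect_true(all(vapply(sb, function(b)
      identical(dim(b), rep(side %/% 2L, 3L)), TRUE)))
  }
  expect_error(dwt3_level(array(1, c(3, 4, 4))), "even")
})

test_that("constant cubes have zero detail and scaled LLL", {
  cc <- array(7, c(8, 8, 8))
  sb <- dwt3_level(cc)
  expect_equal(max(abs(unlist(sb[-1]))), 0)
  expect_equal(sb$LLL, array(7 * 2^1.5, c(4, 4, 4)))
})

test_that("the transform reconstructs perfectly and conserves energy", {
  set.seed(3)
  for (wav in c("haar", "d4")) {
    cube <- array(rnorm(16^3), c(16, 16, 16))
    sb <- dwt3_level(cube, wav)
    rec <- idwt3_level(sb, wav)
    expect_lt(max(abs(rec - cube)) / max(abs(cube)), 1e-8)
    f <- mwr_features(cube, levels = 3, wavelet = wav)
    expect_lt(abs(sum(f^2) - sum(cube^2)) / sum(cube^2), 1e-6)
  }
})

test_that("feature count equals the window voxel count at every side", {
  set.seed(4)
  for (side in c(8, 16, 32)) {
    cube <- array(rnorm(side^3), rep(side, 3))
    f <- mwr_features(cube, levels = 3)
    expect_length(f, side^3)
  }
  # 16^3, 3 levels: 7*512 + 7*64 + 7*8 + 8 = 4096 coefficients
  expect_equal(7 * 512 + 7 * 64 + 7 * 8 + 8, 4096)
  cube <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(mwr_features(cube, 3), mwr_features(cube, 3))
  expect_error(mwr_features(cube, levels = 5), "divisible")
})

test_that("window extraction is centered and mirror-padded", {
  img <- image3d(array(seq_len(20^3) %% 251, c(20, 20, 20)))
  w <- extract_window(img, c(10, 10, 10), side = 8)
  expect_equal(dim(w), c(8, 8, 8))
  # center voxel sits at in-window position side/2
  expect_equal(w[4, 4, 4], img$data[10, 10, 10])
  # interior constant image stays constant
  cimg <- image3d(array(42, c(20, 20, 20)))
  expect_true(all(extract_window(cimg, c(10, 10, 10), 16) == 42))
  # corner window equals brute-force symmetric reflection indexing
  reflect <- function(i, n) {
    while (any(i < 0 | i >= n)) {
      i <- ifelse(i < 0, -1 - i, i)
      i <- ifelse(i >= n, 2 * n - 1 - i, i)
    }
    i
  }
  wc <- extract_window(img, c(1, 1, 20), side = 8)
  off <- (1:8) - 4
  manual <- img$data[reflect(0 + off, 20) + 1,
                     reflect(0 + off, 20) + 1,
                     reflect(19 + off, 20) + 1]
  expect_equal(wc, manual)
  expect_error(extract_window(img, c(5, 5, 5), side = 12), "power of two")
})

test_that("batch features agree with per-window extraction", {
  set.seed(6)
  img <- image3d(array(sample(0:255, 24^3, TRUE), c(24, 24, 24)))
  centers <- rbind(c(12, 12, 12), c(2, 23, 5), c(20, 3, 22))
  batch <- selftrace:::mwr_feature_batch(img, centers, side = 16, levels = 3)
  for (i in 1:3) {
    manual <- mwr_features(extract_window(img, centers[i, ], 16), 3)
    expect_equal(as.numeric(batch[i, ]), manual)
  }
  sel <- c(5L, 100L, 4096L)
  sub <- selftrace:::mwr_feature_batch(img, centers, select = sel)
  expect_equal(sub, batch[, sel])
})

test_that("mutual information matches its definition and properties", {
  a <- rep(c(0, 1), 50)
  expect_equal(mutual_information(a, a), 1)
  # full factorial design: independent variables have zero MI
  grid <- expand.grid(x = 0:2, y = 0:3)
  expect_equal(mutual_information(grid$x, grid$y), 0)
  expect_error(mutual_information(1:3, 1:4), "mismatch")

  # random pair matches a brute-force double-loop histogram computation
  set.seed(8)
  x <- sample(0:3, 300, TRUE); y <- sample(0:2, 300, TRUE)
  brute <- 0
  for (vx in unique(x)) for (vy in unique(y)) {
    pxy <- mean(x == vx & y == vy)
    if (pxy > 0)
      brute <- brute + pxy * log2(pxy / (mean(x == vx) * mean(y == vy)))
  }
  expect_equal(mutual_information(x, y), brute)
  # symmetry and non-negativity on random instances
  for (i in 1:5) {
    x <- sample(0:2, 100, TRUE); y <- sample(0:4, 100, TRUE)
    expect_gte(mutual_information(x, y), 0)
    expect_equal(mutual_information(x, y), mutual_information(y, x))
  }
})

test_that("mRMR selects the planted informative feature first", {
  set.seed(9)
  n <- 200
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(rnorm(n * 10), n, 10)
  feats[, 4] <- labels + rnorm(n, sd = 0.01)
  sel <- mrmr_select(feats, labels, k = 3)
  expect_equal(sel$selected[1], 4L)
  expect_length(sel$selected, 3)
  expect_false(anyDuplicated(sel$selected) > 0)
})

test_that("mRMR penalizes a duplicated feature below a weaker one", {
  set.seed(10)
  n <- 400
  labels <- rep(0:1, each = n / 2)
  strong <- labels + rnorm(n, sd = 0.05)
  weak <- labels + rnorm(n, sd = 0.9)   # informative but noisy, independent
  feats <- cbind(strong, strong + rnorm(n, sd = 0.01), weak,
                 matrix(rnorm(n * 3), n, 3))
  sel <- mrmr_select(feats, labels, k = 2)
  expect_true(sel$selected[1] %in% c(1L, 2L))
  # the twin of the leading strong feature is penalized for redundancy;
  # the weaker independent feature (col 3) is picked instead
  expect_equal(sel$selected[2], 3L)
})

test_that("greedy selection matches exhaustive per-step evaluation", {
  set.seed(11)
  n <- 120
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(rnorm(n * 6), n, 6)
  feats[, 2] <- labels + rnorm(n, sd = 0.5)
  feats[, 5] <- labels * 2 + rnorm(n, sd = 0.7)
  sel <- mrmr_select(feats, labels, k = 3)

  # oracle: recompute the incremental criterion by brute force
  disc <- selftrace:::discretize_features(feats)$states
  cl <- as.integer(factor(labels))
  mi <- function(a, b) mutual_information(a, b)
  chosen <- integer(0)
  for (step in 1:3) {
    cand <- setdiff(1:6, chosen)
    score <- vapply(cand, function(j) {
      rel <- mi(cl, disc[, j])
      red <- if (length(chosen)) mean(vapply(chosen, function(s)
        mi(disc[, j], disc[, s]), 0)) else 0
      rel - red
    }, 0)
    chosen <- c(chosen, cand[which.max(score)])
  }
  expect_equal(sel$selected, chosen)
})

test_that("mRMR is permutation-equivariant in the feature columns", {
  set.seed(12)
  n <- 150
  labels <- rep(0:1, each = n / 2)
  feats <- matrix(rnorm(n * 8), n, 8)
  feats[, 3] <- labels + rnorm(n, sd = 0.3)
  feats[, 7] <- labels + rnorm(n, sd = 0.6)
  sel1 <- mrmr_select(feats, labels, k = 3)
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)   # new order of old columns
  sel2 <- mrmr_select(feats[, perm], labels, k = 3)
  expect_equal(perm[sel2$selected], sel1$selected)
  expect_error(mrmr_select(feats, rep(1, n), k = 2), "2 classes")
  expect_error(mrmr_select(feats, labels, k = 99), "dimension")
})
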