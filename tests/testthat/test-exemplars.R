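# exemplar label volumes and balanced sampling

# a confidence report that simply declares every segment's label
fake_report <- function(tree, labels) {
  segs <- decompose_segments(tree)
  structure(list(
    segments = segs,
    table = data.frame(segment = seq_along(segs),
                       label = rep_len(labels, length(segs)),
                       scored = TRUE),
    threshold_used = 0.5, inverted = FALSE),
    class = "confidence_report")
}

test_that("label counts match exhaustive distance classification", {
  img <- image3d(array(100, c(48, 48, 48)))
  tr <- chain_tree(cbind(c(4, 43), c(23, 23), c(23, 23)))
  lv <- build_label_volume(img, fake_report(tr, "confident"), tr,
                           layer_radii = c(1, 3, 6), border_margin = 0)
  # oracle: classify every voxel by its exact distance to the segment
  co <- selftrace:::vox_coords(c(48, 48, 48), 1:48^3)
  a <- c(24, 24, 5); b <- c(24, 24, 44)
  v <- b - a
  w <- sweep(co, 2, a)
  t <- pmin(pmax(w %*% v / sum(v^2), 0), 1)
  d <- sqrt(rowSums((w - outer(as.vector(t), v))^2))
  code <- label_codes()
  want <- ifelse(d <= 1, code[["FOREGROUND_SAMPLE"]],
          ifelse(d <= 3, code[["UNCERTAIN"]],
          ifelse(d <= 6, code[["BACKGROUND_SAMPLE"]],
                 code[["IRRELEVANT"]])))
  expect_equal(as.vector(lv$labels), as.vector(want))
})

test_that("all-uncertain reports raise the insufficient-exemplars error", {
  img <- image3d(array(100, c(32, 32, 32)))
  tr <- chain_tree(cbind(c(8, 24), c(15, 15), c(15, 15)))
  expect_error(build_label_volume(img, fake_report(tr, "uncertain"), tr),
               class = "insufficient_exemplars")
})

test_that("uncertain zones override background but never confident cores", {
  img <- image3d(array(100, c(40, 40, 40)))
  # two crossing chains: one confident (along x), one uncertain (along y)
  nd <- data.frame(id = 1:4, type = 3L,
                   x = c(5, 34, 19, 19), y = c(19, 19, 5, 34),
                   z = c(19, 19, 19, 19), radius = 1,
                   parent = c(-1L, 1L, -1L, 3L))
  tr <- neuron_tree(nd)
  lv <- build_label_volume(img, fake_report(tr, c("confident", "uncertain")),
                           tr, layer_radii = c(1.5, 3, 6), border_margin = 0)
  code <- label_codes()
  dims <- dim(img$data)
  # at the crossing, voxels in the confident core keep their label
  cross <- selftrace:::vox_index(dims, rbind(c(20, 20, 20)))
  expect_equal(as.integer(lv$labels[cross]), code[["FOREGROUND_SAMPLE"]])
  # far along the uncertain chain, near-tube voxels are uncertain not bg
  unc <- selftrace:::vox_index(dims, rbind(c(20, 31, 22)))
  expect_equal(as.integer(lv$labels[unc]), code[["UNCERTAIN"]])
})

test_that("border demotion clears a full window margin", {
  img <- image3d(array(100, c(32, 32, 32)))
  tr <- chain_tree(cbind(c(4, 27), c(15, 15), c(15, 15)))
  lv <- build_label_volume(img, fake_report(tr, "confident"), tr,
                           layer_radii = c(1, 3, 6), border_margin = 8)
  code <- label_codes()
  expect_true(all(lv$labels[1:8, , ] == code[["IRRELEVANT"]]))
  expect_true(all(lv$labels[, , 25:32] == code[["IRRELEVANT"]]))
  expect_gt(sum(lv$labels == code[["FOREGROUND_SAMPLE"]]), 0)
})

test_that("sampling balances classes and respects the cap", {
  img <- image3d(array(100, c(40, 40, 40)))
  tr <- chain_tree(cbind(c(5, 34), c(19, 19), c(19, 19)))
  lv <- build_label_volume(img, fake_report(tr, "confident"), tr,
                           layer_radii = c(1, 2, 8), border_margin = 0)
  code <- label_codes()
  n_fg <- sum(lv$labels == code[["FOREGROUND_SAMPLE"]])
  n_bg <- sum(lv$labels == code[["BACKGROUND_SAMPLE"]])
  expect_gt(n_bg, n_fg)   # thin core, thick outer annulus
  # cap above the smaller class: balanced at the smaller class size
  s <- draw_training_samples(lv, max_per_class = 10 * n_fg, seed = 1)
  expect_equal(nrow(s$foreground), n_fg)
  expect_equal(nrow(s$background), n_fg)
  # cap below both: balanced at the cap
  s2 <- draw_training_samples(lv, max_per_class = 17, seed = 1)
  expect_equal(nrow(s2$foreground), 17)
  expect_equal(nrow(s2$background), 17)
  # drawn voxels carry the claimed label
  expect_true(all(lv$labels[cbind(s$foreground)] ==
                    code[["FOREGROUND_SAMPLE"]]))
  expect_true(all(lv$labels[cbind(s$background)] ==
                    code[["BACKGROUND_SAMPLE"]]))
  # seeded determinism
  s3 <- draw_training_samples(lv, max_per_class = 17, seed = 1)
  expect_identical(s2, s3)
  expect_false(identical(
    draw_training_samples(lv, max_per_class = 17, seed = 2), s2))
})

test_that("no voxel is both a foreground and a background sample", {
  ph <- y_phantom()
  tr <- baseline_trace(ph$image, tracer_config(30, ph$soma_seed))
  rep <- score_segments(ph$image, tr)
  lv <- build_label_volume(ph$image, rep, tr)
  code <- label_codes()
  # single label array makes overlap impossible; check the partition sums
  expect_equal(sum(lv$counts), prod(dim(ph$image$data)))
})

test_that("shrinking the confident set never adds foreground samples", {
  img <- image3d(array(100, c(40, 40, 40)))
  nd <- data.frame(id = 1:4, type = 3L,
                   x = c(5, 34, 19, 19), y = c(19, 19, 5, 34),
                   z = c(19, 19, 19, 19), radius = 1,
                   parent = c(-1L, 1L, -1L, 3L))
  tr <- neuron_tree(nd)
  lv_all <- build_label_volume(img, fake_report(tr, "confident"), tr,
                               layer_radii = c(1.5, 3, 6))
  lv_one <- build_label_volume(img,
                               fake_report(tr, c("confident", "uncertain")),
                               tr, layer_radii = c(1.5, 3, 6))
  code <- label_codes()
  fg_all <- lv_all$labels == code[["FOREGROUND_SAMPLE"]]
  fg_one <- lv_one$labels == code[["FOREGROUND_SAMPLE"]]
  expect_true(all(fg_all[fg_one]))   # fg_one is a subset of fg_all
})
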