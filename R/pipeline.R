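# Full self-learning tracing loop: score -> label -> sample -> features ->
# select -> train -> grow -> adjust -> re-trace, plus the iterative mode.

#' Pipeline configuration
#'
#' Defaults reproduce the reference operating point: 16-voxel cubic feature
#' window, 3 decomposition levels, top-20 selected features, LIBSVM default
#' classifier settings, and a final tracing threshold of 1 (every predicted
#' background voxel is zeroed, so any positive threshold separates the
#' classes; 1 is the smallest).
#'
#' @param confidence_threshold segment score at or below which a segment is
#'   confident (default 0.5).
#' @param layer_radii `(core, middle, outer)` exemplar radii in voxels, or
#'   `NULL` to derive them from the reconstruction's node radii.
#' @param window_side feature window side (16).
#' @param mwr_levels wavelet decomposition levels (3).
#' @param k_features number of mRMR-selected features (20).
#' @param wavelet `"haar"` or `"d4"`.
#' @param max_per_class training-sample cap per class.
#' @param final_trace_threshold tracing threshold on the adjusted image (1).
#' @param initial_trace_threshold background threshold for the built-in
#'   initial tracer (used only when no initial reconstruction is supplied).
#' @param soma_seed seed for the built-in tracer: `"auto"` or `(z, y, x)`.
#' @param min_branch_length tracer pruning length for the initial trace.
#' @param final_min_branch_length pruning length for the final trace; the
#'   default is larger than `min_branch_length` because the predicted
#'   foreground tube is thicker than the neurite it contains, and its
#'   surface irregularities would otherwise be traced as short twigs.
#' @param connectivity 26 or 6, used for path search and growth.
#' @param invert brightfield flag for confidence scoring.
#' @param rounds maximum iterations for [run_iterative()].
#' @param convergence_ratio stop iterating when the relative total-length
#'   change between rounds falls below this (default 0.05).
#' @param seed top-level RNG seed; fans out to sampling and training.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(confidence_threshold = 0.5, layer_radii = NULL,
                            window_side = 16, mwr_levels = 3,
                            k_features = 20, wavelet = "haar",
                            max_per_class = 500,
                            final_trace_threshold = 1,
                            initial_trace_threshold = 30,
                            soma_seed = "auto", min_branch_length = 5,
                            final_min_branch_length = 10,
                            connectivity = 26, invert = FALSE,
                            rounds = 1, convergence_ratio = 0.05,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_time <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  val <- force(expr)
  list(value = val, seconds = proc.time()[["elapsed"]] - t0)
}

#' Run one round of self-learning tracing
#'
#' Executes the full loop on one image: obtain (or accept) an initial
#' reconstruction, score its segments, build the exemplar label volume, draw
#' balanced samples, extract multi-resolution wavelet features, select the
#' top features by mRMR, train the SVM, grow the predicted foreground from
#' the confident skeleton, remap the image, and re-trace at the final
#' threshold. Deterministic for a fixed config (including its seed).
#'
#' @param img an [image3d].
#' @param initial a [neuron_tree] (e.g. from an external tracer via
#'   [trace_adapter()]) or `"auto"` to run [baseline_trace()].
#' @param cfg a [pipeline_config()].
#' @param debug_dir optional directory; when set, intermediates (scored SWC,
#'   label volume, mask, adjusted image) are written there.
#' @return list with `tree` (final [neuron_tree]) and `report` (class
#'   `run_report`: initial/final morphology, per-stage timings named after
#'   the stage — `T_in`, `T_s`, `T_m`, `T_t`, `T_p`, `T_st` — sample counts,
#'   confident-segment fraction, improvement ratio).
#' @export
run_pipeline <- function(img, initial = "auto", cfg = pipeline_config(),
                         debug_dir = NULL) {
  stopifnot(inherits(img, "image3d"), inherits(cfg, "pipeline_config"))
  timings <- list()

  st <- stage_time({
    if (identical(initial, "auto")) {
      baseline_trace(img, tracer_config(
        background_threshold = cfg$initial_trace_threshold,
        soma_seed = cfg$soma_seed,
        min_branch_length = cfg$min_branch_length,
        connectivity = cfg$connectivity))
    } else {
      stopifnot(inherits(initial, "neuron_tree"))
      initial
    }
  })
  init_tree <- st$value; timings$T_in <- st$seconds

  st <- stage_time(score_segments(
    img, init_tree, threshold = cfg$confidence_threshold,
    invert = cfg$invert, connectivity = cfg$connectivity))
  report <- st$value; timings$T_s <- st$seconds

  lv <- build_label_volume(img, report, init_tree,
                           layer_radii = cfg$layer_radii,
                           border_margin = cfg$window_side / 2)
  samples <- draw_training_samples(lv, max_per_class = cfg$max_per_class,
                                   seed = cfg$seed)

  st <- stage_time({
    fg_feat <- mwr_feature_batch(img, samples$foreground,
                                 side = cfg$window_side,
                                 levels = cfg$mwr_levels,
                                 wavelet = cfg$wavelet)
    bg_feat <- mwr_feature_batch(img, samples$background,
                                 side = cfg$window_side,
                                 levels = cfg$mwr_levels,
                                 wavelet = cfg$wavelet)
    labels <- c(rep(1L, nrow(fg_feat)), rep(0L, nrow(bg_feat)))
    mrmr_select(rbind(fg_feat, bg_feat), labels, k = cfg$k_features)
  })
  sel <- st$value; timings$T_m <- st$seconds

  st <- stage_time({
    fg_feat <- mwr_feature_batch(img, samples$foreground,
                                 side = cfg$window_side,
                                 levels = cfg$mwr_levels,
                                 wavelet = cfg$wavelet,
                                 select = sel$selected)
    bg_feat <- mwr_feature_batch(img, samples$background,
                                 side = cfg$window_side,
                                 levels = cfg$mwr_levels,
                                 wavelet = cfg$wavelet,
                                 select = sel$selected)
    train_classifier(fg_feat, bg_feat, seed = cfg$seed)
  })
  clf <- st$value; timings$T_t <- st$seconds

  st <- stage_time({
    code <- label_codes()
    seed_vox <- vox_coords(dim(img$data),
                           which(lv$labels == code[["FOREGROUND_SAMPLE"]]))
    feature_fn <- function(centers) {
      mwr_feature_batch(img, centers, side = cfg$window_side,
                        levels = cfg$mwr_levels, wavelet = cfg$wavelet,
                        select = sel$selected)
    }
    grow_foreground(img, seed_vox, clf, feature_fn,
                    connectivity = cfg$connectivity)
  })
  fmask <- st$value; timings$T_p <- st$seconds

  st <- stage_time({
    adjusted <- adjust_image(img, fmask, cfg$final_trace_threshold)
    root <- init_tree$nodes[init_tree$nodes$parent == -1L, ][1, ]
    baseline_trace(adjusted, tracer_config(
      background_threshold = cfg$final_trace_threshold,
      soma_seed = swc_to_zyx(cbind(root$x, root$y, root$z))[1, ],
      min_branch_length = cfg$final_min_branch_length,
      connectivity = cfg$connectivity))
  })
  final_tree <- st$value; timings$T_st <- st$seconds

  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    write_swc(init_tree, file.path(debug_dir, "initial.swc"),
              color_scores = node_scores(report, init_tree))
    write_raw_dump(lv$labels, file.path(debug_dir, "labels.raw.txt"))
    write_raw_dump(array(as.integer(fmask$mask), dim(img$data)),
                   file.path(debug_dir, "mask.raw.txt"))
    write_swc(final_tree, file.path(debug_dir, "final.swc"))
  }

  m_init <- measure_morphology(init_tree)
  m_final <- measure_morphology(final_tree)
  rep_out <- structure(list(
    initial_morphology = m_init, final_morphology = m_final,
    timings = timings,
    n_samples_per_class = nrow(samples$foreground),
    selected_features = sel$selected,
    training_accuracy = clf$training_accuracy,
    confident_fraction = mean(report$table$label == "confident"),
    grown_voxels = sum(fmask$mask),
    improvement_ratio = m_final$total_length / m_init$total_length,
    seed = cfg$seed),
    class = "run_report")
  list(tree = final_tree, report = rep_out)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    paste0("<run_report> length %.1f -> %.1f voxels (ratio %.2f), ",
           "%d/%d samples, %.0f%% confident segments\n"),
    x$initial_morphology$total_length, x$final_morphology$total_length,
    x$improvement_ratio, x$n_samples_per_class, x$n_samples_per_class,
    100 * x$confident_fraction))
  invisible(x)
}

#' Run the pipeline iteratively
#'
#' The reconstruction from each round becomes the initial reconstruction of
#' the next. A reconstruction that failed to cross a gap in round 1 can
#' provide richer training exemplars (closer to the gap) in round 2, which
#' is often enough to fill it. Iteration stops at `cfg$rounds` or when the
#' relative total-length change between rounds drops below
#' `cfg$convergence_ratio`. Per-round RNG seeds are derived from `cfg$seed`
#' as `seed + round - 1`.
#'
#' @param img an [image3d].
#' @param cfg a [pipeline_config()]; set `cfg$rounds`.
#' @param initial starting reconstruction or `"auto"`.
#' @return list with `tree` (final reconstruction) and `reports` (one
#'   `run_report` per executed round).
#' @export
run_iterative <- function(img, cfg = pipeline_config(), initial = "auto") {
  stopifnot(cfg$rounds >= 1)
  reports <- list()
  current <- initial
  tree <- NULL
  prev_len <- NA_real_
  for (r in seq_len(cfg$rounds)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    res <- run_pipeline(img, initial = current, cfg = cfg_r)
    tree <- res$tree
    reports[[r]] <- res$report
    len <- res$report$final_morphology$total_length
    if (!is.na(prev_len) && prev_len > 0 &&
        abs(len - prev_len) / prev_len < cfg$convergence_ratio) break
    prev_len <- len
    current <- tree
  }
  list(tree = tree, reports = reports)
}
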