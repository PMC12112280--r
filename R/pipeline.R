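# End-to-end pipeline: generate -> patch -> features -> select -> splits ->
# evaluate -> report, driven by a single configuration and seed.

#' Pipeline configuration
#'
#' Collects every tunable stage parameter with the standard defaults: 256-px
#' windows (5 deterministic + 2 random per source), grid scale nu = 10,
#' hypersphere radius r = 4, k = 100 selected samples from 1000 FUS trials,
#' far-apart threshold t = 0.7, loss-gap readout at epoch 150 with EWMA
#' alpha = 0.9.
#'
#' @param window_size Patch side length (px).
#' @param n_random_windows Random windows per source image.
#' @param min_skeleton_length Patch filter threshold (px of skeleton arc
#'   length).
#' @param nu Grid scale (cells per feature range).
#' @param radius Hypersphere radius (grid units).
#' @param k Number of samples to select.
#' @param n_trials FUS-minimization trials.
#' @param far_threshold Far-apart split distance threshold (z-score units).
#' @param far_candidates Candidate splits scored for the far-apart search.
#' @param split_n Samples per side in feature-extreme and far-apart splits.
#' @param eval_epoch Loss-gap readout epoch.
#' @param smoothing_factor EWMA alpha.
#' @param seed Master seed for all stages.
#' @param n_sources Synthetic source images to generate (pipeline input).
#' @param source_size Size of each synthetic source image (pair).
#' @param param_ranges Generator parameter ranges (see
#'   [generate_collection()]).
#' @return A `run_config` list.
#' @export
run_config <- function(window_size = 256L,
                       n_random_windows = 2L,
                       min_skeleton_length = 100,
                       nu = 10,
                       radius = 4L,
                       k = 100L,
                       n_trials = 1000L,
                       far_threshold = 0.7,
                       far_candidates = 10000L,
                       split_n = 20L,
                       eval_epoch = 150L,
                       smoothing_factor = 0.9,
                       seed = 1L,
                       n_sources = 20L,
                       source_size = c(640L, 640L),
                       param_ranges = list()) {
  structure(
    list(
      window_size = as.integer(window_size),
      n_random_windows = as.integer(n_random_windows),
      min_skeleton_length = min_skeleton_length,
      nu = nu,
      radius = as.integer(radius),
      k = as.integer(k),
      n_trials = as.integer(n_trials),
      far_threshold = far_threshold,
      far_candidates = as.integer(far_candidates),
      split_n = as.integer(split_n),
      eval_epoch = as.integer(eval_epoch),
      smoothing_factor = smoothing_factor,
      seed = as.integer(seed),
      n_sources = as.integer(n_sources),
      source_size = as.integer(source_size),
      param_ranges = param_ranges
    ),
    class = "run_config"
  )
}

#' Run the full sampling pipeline on synthetic data
#'
#' Chains every stage from a single configuration and seed: synthetic source
#' generation, window extraction and filtering, feature mapping,
#' normalization, grid discretization, sampling-set construction,
#' FUS-minimized selection, split generation (feature-extreme, far-apart,
#' random few-shot), a mask-agreement evaluation of the selected samples
#' (Dice / clDice of each mask against its skeleton re-dilation, exercising
#' the metric stack), and the histogram/entropy diagnostics. All outputs are
#' plain CSV/JSON without timestamps, so a rerun with the same configuration
#' is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`sources`,
#'   `windows`, `features`, `normalized`, `grid`, `sset`, `selection`,
#'   `splits`, `scores`, `diagnostics`) and `paths` of the files written.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sources <- generate_collection(
    n_samples = config$n_sources,
    param_ranges = config$param_ranges,
    image_size = config$source_size,
    seed = config$seed
  )

  windows <- purrr::map(seq_len(nrow(sources)), function(i) {
    extract_windows(
      sources$image[[i]], sources$mask[[i]],
      patch_spec(
        window_size = config$window_size,
        n_random = config$n_random_windows,
        min_skeleton_length_px = config$min_skeleton_length,
        seed = config$seed + i
      ),
      source_id = sources$source_id[i]
    )
  })
  windows <- dplyr::bind_rows(windows)
  windows$sample_id <- sprintf("patch_%05d", seq_len(nrow(windows)))
  kept <- filter_windows(windows, config$min_skeleton_length)

  features <- compute_collection_features(kept)
  features_path <- file.path(out_dir, "features.csv")
  write_feature_table(features, features_path)

  normalized <- normalize_features(features)
  grid <- discretize_features(normalized, nu = config$nu)
  sset <- build_sampling_set(grid, r = config$radius)
  selection <- select_best_subset(
    sset, grid,
    k = config$k, n_trials = config$n_trials, seed = config$seed
  )
  selection_path <- file.path(out_dir, "selection.json")
  write_selection_json(selection, selection_path, params = list(
    nu = config$nu, radius = config$radius
  ))

  splits <- list()
  for (f in feature_cols(normalized)) {
    for (side in c("low", "high")) {
      splits[[sprintf("extreme_%s_%s", f, side)]] <-
        extreme_feature_split(normalized, f, n = config$split_n, train_side = side)
    }
  }
  far <- far_apart_split(
    normalized,
    n = config$split_n, threshold = config$far_threshold,
    n_candidates = config$far_candidates, seed = config$seed
  )
  splits[["far_apart"]] <- far$split
  random_splits <- random_few_shot_splits(
    normalized, n_train = 4L,
    n_runs = min(20L, nrow(normalized) - 4L), seed = config$seed
  )
  splits_path <- file.path(out_dir, "splits.json")
  write_split_json(c(splits, random_splits), splits_path,
                   sample_ids = normalized$sample_id)

  # Metric stage: score each selected sample's mask against the tube
  # reconstructed by re-dilating its skeleton; imperfect by construction, so
  # Dice/clDice vary across samples.
  sel_rows <- match(selection$sample_ids, kept$sample_id)
  scores <- purrr::map(sel_rows, function(i) {
    msk <- kept$mask[[i]]
    recon <- dilate_mask(skeletonize_mask(msk), 2)
    tibble(
      sample_id = kept$sample_id[i],
      dice = dice(recon, msk),
      cl_dice = cl_dice(recon, msk)
    )
  })
  scores <- dplyr::bind_rows(scores)
  scores_out <- scores
  scores_out$dice <- sprintf("%.17g", scores_out$dice)
  scores_out$cl_dice <- sprintf("%.17g", scores_out$cl_dice)
  scores_path <- file.path(out_dir, "scores.csv")
  write.csv(scores_out, scores_path, row.names = FALSE, quote = FALSE)

  diag <- diagnostics_report(normalized, selection)
  diag_path <- file.path(out_dir, "diagnostics.csv")
  diag_out <- tidy(diag)
  diag_out$mid <- sprintf("%.17g", diag_out$mid)
  diag_out$frequency <- sprintf("%.17g", diag_out$frequency)
  write.csv(diag_out, diag_path, row.names = FALSE, quote = FALSE)

  provenance_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    c(unclass(config), list(
      artifact_version = as.character(utils::packageVersion("vesselect")),
      n_windows = nrow(windows), n_kept = nrow(kept)
    )),
    provenance_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )

  invisible(list(
    sources = sources, windows = windows, kept = kept, features = features,
    normalized = normalized, grid = grid, sset = sset, selection = selection,
    splits = splits, random_splits = random_splits, far = far,
    scores = scores, diagnostics = diag,
    paths = c(
      features = features_path, selection = selection_path,
      splits = splits_path, scores = scores_path, diagnostics = diag_path,
      provenance = provenance_path
    )
  ))
}
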