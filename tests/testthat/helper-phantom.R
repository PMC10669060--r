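# Shared fixtures: phantoms are expensive to rasterize, so each preset is
# generated once per test run and memoised here.

.fixture_env <- new.env(parent = emptyenv())

get_phantom <- function(preset = "tiny", seed = NULL) {
  key <- paste0(preset, "_", seed %||% "default")
  if (is.null(.fixture_env[[key]])) {
    spec <- phantom_preset(preset)
    if (!is.null(seed)) spec$seed <- seed
    .fixture_env[[key]] <- generate_phantom(spec)
  }
  .fixture_env[[key]]
}

get_segmented <- function(preset = "tiny", seed_cfg = 3) {
  key <- paste0("seg_", preset, "_", seed_cfg)
  if (is.null(.fixture_env[[key]])) {
    ph <- get_phantom(preset)
    cfg <- pipeline_config(seed = seed_cfg)
    segfun <- if (preset == "clenched") truth_slice_segmenter(ph) else NULL
    panofun <- if (preset == "clenched") truth_pano_segmenter(ph) else NULL
    .fixture_env[[key]] <- segment_cbct(ph$volume, cfg, segfun, panofun)
  }
  .fixture_env[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force O(nm) nearest-neighbour oracle
brute_nn <- function(query, target) {
  d <- matrix(0, nrow(query), nrow(target))
  for (a in 1:3) d <- d + outer(query[, a], target[, a], "-")^2
  list(dist = sqrt(apply(d, 1, min)), index = apply(d, 1, which.min))
}

# fraction of jaw-split voxels carrying the expected ground-truth label
jaw_split_accuracy <- function(js, phantom) {
  lab <- phantom$truth$tooth_labels
  jaw_of <- phantom$truth$jaw_of_tooth
  acc <- function(vox, want) {
    if (nrow(vox) == 0) return(NA_real_)
    ids <- lab[vox + 1L]
    ids <- ids[ids > 0]
    mean(jaw_of[ids] == want)
  }
  n_up <- nrow(js$upper_voxels); n_lo <- nrow(js$lower_voxels)
  w <- c(n_up, n_lo) / (n_up + n_lo)
  sum(w * c(acc(js$upper_voxels, "upper"), acc(js$lower_voxels, "lower")))
}

pose_error <- function(transform, truth_transform) {
  err <- compose_transform(transform, invert_transform(truth_transform))
  c(rot_deg = rotation_angle(err),
    trans_mm = sqrt(sum(unclass(err)[1:3, 4]^2)))
}
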