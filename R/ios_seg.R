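#' RGB to HSV conversion
#'
#' Standard hexcone conversion: V = max, S = (max - min)/max (0 when
#' max = 0), H by the sector formula, degrees in `[0, 360)`. Achromatic
#' inputs (S = 0) get hue 0.
#'
#' @param rgb Length-3 vector or n x 3 matrix, channels in `[0, 1]`.
#' @return n x 3 matrix with columns `h` (degrees), `s`, `v`.
#' @export
rgb_to_hsv <- function(rgb) {
  rgb <- rbind_vec(rgb)
  if (any(rgb < 0 | rgb > 1) || any(!is.finite(rgb)))
    stop("RGB channels must lie in [0, 1]")
  hsv <- t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
  cbind(h = hsv[, 1] * 360, s = hsv[, 2], v = hsv[, 3])
}

#' HSV to RGB conversion (inverse of [rgb_to_hsv()])
#' @param hsv n x 3 matrix with columns hue (degrees), saturation, value.
#' @return n x 3 RGB matrix in `[0, 1]`.
#' @export
hsv_to_rgb <- function(hsv) {
  hsv <- rbind_vec(hsv)
  h <- (hsv[, 1] %% 360) / 60
  s <- hsv[, 2]
  v <- hsv[, 3]
  c <- v * s
  x <- c * (1 - abs(h %% 2 - 1))
  m <- v - c
  sector <- floor(h) %% 6
  r <- ifelse(sector %in% c(0, 5), c, ifelse(sector %in% c(1, 4), x, 0))
  g <- ifelse(sector %in% c(1, 2), c, ifelse(sector %in% c(0, 3), x, 0))
  b <- ifelse(sector %in% c(3, 4), c, ifelse(sector %in% c(2, 5), x, 0))
  cbind(r + m, g + m, b + m)
}

# Embedding used for color distances: hue on the circle scaled by
# saturation (so achromatic hues are irrelevant), plus value:
# (s cos h, s sin h, v).
hsv_embed <- function(hsv) {
  a <- hsv[, 1] * pi / 180
  cbind(hsv[, 2] * cos(a), hsv[, 2] * sin(a), hsv[, 3])
}

#' HSV color training set for teeth/gingiva classification
#'
#' @param hsv n x 3 matrix (hue degrees, saturation, value).
#' @param label Character vector, values `"teeth"` or `"gum"`.
#' @return A `color_training_set`.
#' @export
color_training_set <- function(hsv, label) {
  hsv <- rbind_vec(hsv)
  label <- as.character(label)
  if (nrow(hsv) != length(label)) stop("one label per HSV row required")
  if (!all(label %in% c("teeth", "gum")))
    stop("labels must be 'teeth' or 'gum'")
  if (!all(c("teeth", "gum") %in% label))
    stop("training set must contain both classes")
  structure(list(hsv = hsv, label = label, embed = hsv_embed(hsv)),
            class = "color_training_set")
}

#' Default color training set
#'
#' A deterministic grid over the phantom color model: whitish low-
#' saturation high-value teeth and reddish-pink saturated gingiva. Useful
#' as a starting reference set for scanner data with similar color
#' rendering; user-supplied seed points (see [read_color_training()]) are
#' preferred for calibrated work.
#'
#' @param spec A [phantom_spec()] providing the color model.
#' @return A `color_training_set`.
#' @export
default_color_training <- function(spec = phantom_spec()) {
  tg <- expand.grid(
    h = seq(spec$teeth_hue - 2 * spec$teeth_hue_sd,
            spec$teeth_hue + 2 * spec$teeth_hue_sd, length.out = 5) %% 360,
    s = seq(0, spec$teeth_sat_max, length.out = 4),
    v = seq(spec$teeth_val_min, 1, length.out = 4))
  gg <- expand.grid(
    h = seq(spec$gum_hue - 2 * spec$gum_hue_sd,
            spec$gum_hue + 2 * spec$gum_hue_sd, length.out = 5) %% 360,
    s = seq(spec$gum_sat[1], spec$gum_sat[2], length.out = 4),
    v = seq(spec$gum_val[1], spec$gum_val[2], length.out = 4))
  color_training_set(rbind(as.matrix(tg), as.matrix(gg)),
                     c(rep("teeth", nrow(tg)), rep("gum", nrow(gg))))
}

#' Read a labeled color training set from CSV
#'
#' Expects columns `h`, `s`, `v`, `label` (or `r`, `g`, `b`, `label`).
#' @param path CSV path.
#' @return A `color_training_set`.
#' @export
read_color_training <- function(path) {
  df <- utils::read.csv(path)
  if (all(c("h", "s", "v") %in% names(df)))
    color_training_set(as.matrix(df[, c("h", "s", "v")]), df$label)
  else if (all(c("r", "g", "b") %in% names(df)))
    color_training_set(rgb_to_hsv(as.matrix(df[, c("r", "g", "b")])), df$label)
  else stop("training CSV needs h/s/v or r/g/b columns plus label")
}

#' KNN teeth/gingiva classification of a colored surface
#'
#' Each point's color is converted to HSV and embedded as
#' `(s cos h, s sin h, v)` — hue treated circularly and scaled by
#' saturation so near-achromatic (tooth-like) hues carry no spurious
#' weight. Among training points within `max_dist` (embedded Euclidean),
#' the `k` nearest vote; exact ties and points with no in-range training
#' neighbour are labeled `"gum"` (conservative: protects the purity of the
#' teeth set; the out-of-range count is recorded in attribute
#' `n_out_of_range`).
#'
#' @param cloud A [colored_surface()] with colors.
#' @param train A [color_training_set()].
#' @param k Number of voting neighbours (>= 1).
#' @param max_dist Neighbourhood radius in the embedded color space.
#' @return `cloud` with `labels` set to `"teeth"`/`"gum"`.
#' @export
knn_classify <- function(cloud, train, k = 15, max_dist = 0.3) {
  stopifnot(inherits(cloud, "colored_surface"), k >= 1)
  if (!inherits(train, "color_training_set") || nrow(train$hsv) == 0)
    stop("empty or invalid training set")
  if (is.null(cloud$colors))
    stop("cloud has no colors; color-based segmentation is impossible")
  q <- hsv_embed(rgb_to_hsv(cloud$colors))
  tr <- train$embed
  is_teeth <- train$label == "teeth"
  n <- nrow(q)
  lab <- character(n)
  oor <- 0L
  chunk <- 4096L
  tr2 <- rowSums(tr^2)
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    D2 <- outer(rowSums(q[lo:hi, , drop = FALSE]^2), tr2, "+") -
      2 * q[lo:hi, , drop = FALSE] %*% t(tr)
    for (i in seq_len(hi - lo + 1)) {
      d2 <- D2[i, ]
      ok <- which(d2 <= max_dist^2)
      if (length(ok) == 0) { lab[lo + i - 1] <- "gum"; oor <- oor + 1L; next }
      sel <- ok[order(d2[ok])][seq_len(min(k, length(ok)))]
      votes_teeth <- sum(is_teeth[sel])
      lab[lo + i - 1] <- if (votes_teeth > length(sel) / 2) "teeth" else "gum"
    }
  }
  cloud$labels <- lab
  attr(cloud, "n_out_of_range") <- oor
  cloud
}

#' Extract the teeth subset of a labeled cloud, with spatial cleanup
#'
#' Keeps `"teeth"`-labeled points, clusters them by Euclidean proximity
#' and drops clusters smaller than `min_cluster` points (stray
#' misclassified specks).
#'
#' @param labeled A [colored_surface()] with `"teeth"`/`"gum"` labels.
#' @param min_cluster Minimum cluster size to keep.
#' @param cluster_radius Euclidean clustering radius, mm.
#' @return A [colored_surface()] of the retained teeth points; attribute
#'   `kept_index` gives their indices in `labeled`.
#' @export
extract_teeth <- function(labeled, min_cluster = 30, cluster_radius = 1.0) {
  stopifnot(inherits(labeled, "colored_surface"))
  if (is.null(labeled$labels)) stop("cloud is unlabeled; run knn_classify first")
  idx <- which(labeled$labels == "teeth")
  if (length(idx) == 0) stop("no teeth-labeled points in the cloud")
  pts <- labeled$points[idx, , drop = FALSE]
  cl <- cpp_euclidean_cluster(pts, cluster_radius)
  sizes <- tabulate(cl)
  keep <- sizes[cl] >= min_cluster
  if (!any(keep)) stop("no teeth cluster reaches min_cluster points")
  kept <- idx[keep]
  out <- colored_surface(labeled$points[kept, , drop = FALSE],
                         if (!is.null(labeled$colors))
                           labeled$colors[kept, , drop = FALSE],
                         if (!is.null(labeled$normals))
                           labeled$normals[kept, , drop = FALSE],
                         labeled$labels[kept])
  attr(out, "kept_index") <- kept
  out
}

#' Segment an intraoral scan: classify colors, keep the teeth
#'
#' @param surface A [colored_surface()] with colors.
#' @param config A [pipeline_config()] (its `ios` section is used).
#' @param train Optional [color_training_set()] (default
#'   [default_color_training()]).
#' @return The teeth [colored_surface()].
#' @export
segment_ios <- function(surface, config = pipeline_config(), train = NULL) {
  if (is.null(train)) train <- default_color_training()
  ic <- config$ios
  labeled <- knn_classify(surface, train, k = ic$k, max_dist = ic$max_dist)
  extract_teeth(labeled, min_cluster = ic$min_cluster,
                cluster_radius = ic$cluster_radius)
}

#' Write point labels as a sidecar CSV
#' @param surface A labeled [colored_surface()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(surface, path) {
  if (is.null(surface$labels)) stop("surface has no labels")
  utils::write.csv(data.frame(index = seq_len(n_points(surface)) - 1L,
                              label = surface$labels),
                   path, row.names = FALSE)
  invisible(path)
}
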