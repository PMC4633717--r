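#' Otsu brightness threshold for a channel raster
#'
#' @param raster Numeric matrix of intensities (counts).
#' @return A single threshold on the raster's intensity scale.
#' @export
otsu_threshold <- function(raster) {
  mx <- max(raster, 1)
  EBImage::otsu(EBImage::Image(raster / mx), range = c(0, 1), levels = 256) * mx
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged through the components of their adjacency graph.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow(mask))
  nlab <- max(lab)
  if (nlab > 1) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
      cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
    )
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(as.character(rbind(cbind(seq_len(nlab), seq_len(nlab)), pairs)),
             ncol = 2), directed = FALSE)
    comp <- igraph::components(g)$membership
    remap <- integer(nlab)
    remap[as.integer(names(comp))] <- comp
    lab[lab > 0] <- remap[lab[lab > 0]]
    # compact label ids
    ids <- sort(unique(lab[lab > 0]))
    lab[lab > 0] <- match(lab[lab > 0], ids)
  }
  lab
}

#' Threshold a channel and count particles
#'
#' Binarises a raster at a brightness threshold (pixels `>=` threshold are
#' foreground), labels 8-connected components, and keeps those whose pixel
#' area lies inside `size_range`. This is the particle analysis used to count
#' cells in a fluorescence channel; it is deterministic for a fixed raster.
#'
#' @param raster Numeric matrix (one channel).
#' @param threshold Brightness threshold; `NULL` uses [otsu_threshold()].
#' @param size_range Length-2 numeric, inclusive pixel-area bounds for a
#'   particle.
#' @return A `qs_particles` tibble: `particle_id`, `area_px`,
#'   `centroid_row_px`, `centroid_col_px` (0-based, origin top-left),
#'   `mean_intensity`. The label matrix, threshold and size range are attached
#'   as attributes for downstream footprint-based analyses.
#' @export
threshold_and_count <- function(raster, threshold = NULL,
                                size_range = c(20, 1e4)) {
  stopifnot(is.matrix(raster), length(size_range) == 2,
            size_range[1] <= size_range[2])
  if (is.null(threshold)) threshold <- otsu_threshold(raster)
  mask <- raster >= threshold
  if (!any(mask)) {
    out <- tibble::tibble(particle_id = integer(), area_px = integer(),
                          centroid_row_px = numeric(),
                          centroid_col_px = numeric(),
                          mean_intensity = numeric())
    return(particles_obj(out, matrix(0L, nrow(raster), ncol(raster)),
                         threshold, size_range))
  }
  lab <- label_components(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area <- tabulate(lv)
  keep <- which(area >= size_range[1] & area <= size_range[2])
  rows <- tapply(idx[, 1], lv, mean)
  cols <- tapply(idx[, 2], lv, mean)
  means <- tapply(raster[lab > 0], lv, mean)
  out <- tibble::tibble(
    particle_id = seq_along(keep),
    area_px = area[keep],
    centroid_row_px = as.numeric(rows[as.character(keep)]) - 1,
    centroid_col_px = as.numeric(cols[as.character(keep)]) - 1,
    mean_intensity = as.numeric(means[as.character(keep)])
  )
  # relabel matrix to the retained particle ids (0 = background / filtered out)
  remap <- integer(max(lv))
  remap[keep] <- seq_along(keep)
  lab[lab > 0] <- remap[lab[lab > 0]]
  particles_obj(out, lab, threshold, size_range)
}

particles_obj <- function(tbl, labels, threshold, size_range) {
  structure(tbl, labels = labels, threshold = threshold,
            size_range = size_range,
            class = c("qs_particles", class(tbl)))
}

#' Classify particles by size and green/red intensity ratio
#'
#' Runs the combined coculture analysis: binarise each channel at its
#' threshold, take the union mask, label 8-connected components, and classify
#' each particle by its mean-intensity ratio
#' `(mean_green + eps) / (mean_red + eps)`: `green` if the ratio is
#' `>= ratio_threshold`, `red` if `<= 1/ratio_threshold`, otherwise
#' `ambiguous`. Components smaller than `size_threshold` pixels are labelled
#' `sub_size` and excluded from colour counts; the epsilon guard means a
#' zero-intensity channel never divides by zero.
#'
#' @param red,green Numeric matrices of identical dimension.
#' @param thresholds Length-2 brightness thresholds (red, green); `NULL` uses
#'   per-channel Otsu.
#' @param size_threshold Minimum particle area (px).
#' @param max_size Maximum particle area (px).
#' @param ratio_threshold Green:red ratio bound (default 2).
#' @param eps Intensity-unit epsilon in the ratio (default 1).
#' @return A `qs_particles` tibble with columns of [threshold_and_count()]
#'   plus `mean_red`, `mean_green`, `ratio` and `class` in
#'   `{"red", "green", "ambiguous", "sub_size"}`.
#' @seealso [particle_counts()]
#' @export
classify_particles <- function(red, green, thresholds = NULL,
                               size_threshold = 20, max_size = 1e4,
                               ratio_threshold = 2, eps = 1) {
  stopifnot(is.matrix(red), is.matrix(green),
            all(dim(red) == dim(green)))
  if (is.null(thresholds)) {
    thresholds <- c(otsu_threshold(red), otsu_threshold(green))
  }
  mask <- (red >= thresholds[1]) | (green >= thresholds[2])
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) {
    out <- tibble::tibble(particle_id = integer(), area_px = integer(),
                          centroid_row_px = numeric(), centroid_col_px = numeric(),
                          mean_red = numeric(), mean_green = numeric(),
                          ratio = numeric(), class = character())
    return(particles_obj(out, lab, thresholds, c(size_threshold, max_size)))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area <- tabulate(lv)
  mr <- as.numeric(tapply(red[lab > 0], lv, mean))
  mg <- as.numeric(tapply(green[lab > 0], lv, mean))
  ratio <- (mg + eps) / (mr + eps)
  cls <- dplyr::case_when(
    area < size_threshold | area > max_size ~ "sub_size",
    ratio >= ratio_threshold ~ "green",
    ratio <= 1 / ratio_threshold ~ "red",
    TRUE ~ "ambiguous"
  )
  out <- tibble::tibble(
    particle_id = seq_len(n),
    area_px = area,
    centroid_row_px = as.numeric(tapply(idx[, 1], lv, mean)) - 1,
    centroid_col_px = as.numeric(tapply(idx[, 2], lv, mean)) - 1,
    mean_red = mr, mean_green = mg, ratio = ratio, class = cls
  )
  particles_obj(out, lab, thresholds, c(size_threshold, max_size))
}

#' Per-class particle counts
#'
#' @param particles Output of [classify_particles()].
#' @return A tibble with one row per class (`red`, `green`, `ambiguous`,
#'   `sub_size`) and column `n`, including zero rows.
#' @export
particle_counts <- function(particles) {
  lv <- c("red", "green", "ambiguous", "sub_size")
  counts <- table(factor(particles$class, levels = lv))
  tibble::tibble(class = lv, n = as.integer(counts))
}

#' Colocalized fraction of a particle set
#'
#' A primary particle counts as colocalized when the mean probe-channel
#' intensity over its footprint is at or above `probe_threshold`. Returns the
#' colocalized fraction `f_c = n_colocalized / n_primary`; with no primary
#' particles `f_c` is `NA` (no data), never 0.
#'
#' @param particles A `qs_particles` object whose label matrix matches the
#'   probe raster's geometry.
#' @param probe Numeric matrix, the probe channel.
#' @param probe_threshold Intensity threshold in the probe channel; `NULL`
#'   uses Otsu.
#' @return A one-row tibble: `n_primary`, `n_colocalized`, `f_c`.
#' @export
colocalization_fraction <- function(particles, probe, probe_threshold = NULL) {
  stopifnot(inherits(particles, "qs_particles"), is.matrix(probe))
  lab <- attr(particles, "labels")
  if (!all(dim(lab) == dim(probe))) {
    rlang::abort("probe raster must match the primary raster's dimensions",
                 class = "qs_error_geometry")
  }
  if (is.null(probe_threshold)) probe_threshold <- otsu_threshold(probe)
  n_primary <- nrow(particles)
  if (n_primary == 0) {
    return(tibble::tibble(n_primary = 0L, n_colocalized = 0L, f_c = NA_real_))
  }
  fg <- lab > 0
  mean_probe <- tapply(probe[fg], lab[fg], mean)
  ids <- as.integer(names(mean_probe))
  hit <- mean_probe[ids %in% particles$particle_id] >= probe_threshold
  tibble::tibble(n_primary = n_primary,
                 n_colocalized = as.integer(sum(hit)),
                 f_c = sum(hit) / n_primary)
}

#' Spatial signal density of a channel
#'
#' The area occupied by supra-threshold signal as a percentage of the total
#' visible area: `100 * (# pixels >= threshold) / (# pixels)`.
#'
#' @param raster Numeric matrix.
#' @param threshold Brightness threshold; `NULL` uses Otsu.
#' @return Percentage in `[0, 100]`.
#' @export
spatial_density <- function(raster, threshold = NULL) {
  stopifnot(is.matrix(raster))
  if (is.null(threshold)) threshold <- otsu_threshold(raster)
  100 * mean(raster >= threshold)
}

#' Mean-grey-value line profile
#'
#' Extracts the ordered intensity sequence along a horizontal slice of a
#' raster (optionally averaging a band of rows). Coincident peaks across the
#' two channels of a field indicate colocalized cells.
#'
#' @param x A numeric matrix or a `qs_image_field`.
#' @param row 0-based row index of the slice.
#' @param halfwidth Rows averaged on either side of `row`.
#' @param ... Unused.
#' @return A tibble with `position_px` (0-based column) and `value`; for a
#'   field, an extra `channel` column covers both channels.
#' @export
line_profile <- function(x, row, halfwidth = 0, ...) UseMethod("line_profile")

#' @export
line_profile.matrix <- function(x, row, halfwidth = 0, ...) {
  r1 <- row + 1
  if (row < 0 || r1 > nrow(x)) {
    rlang::abort("row index out of bounds", class = "qs_error_geometry")
  }
  rows <- max(1, r1 - halfwidth):min(nrow(x), r1 + halfwidth)
  vals <- colMeans(x[rows, , drop = FALSE])
  tibble::tibble(position_px = seq_along(vals) - 1, value = vals)
}

#' @export
line_profile.qs_image_field <- function(x, row, halfwidth = 0, ...) {
  dplyr::bind_rows(
    dplyr::mutate(line_profile(x$red, row, halfwidth), channel = "red"),
    dplyr::mutate(line_profile(x$green, row, halfwidth), channel = "green")
  )
}

#' Score detected particles against rendered ground truth
#'
#' Greedy nearest-centroid matching between detected particles and the
#' ground-truth activated cells of a rendered field, within a capture radius.
#' Reports detection recall and precision, and colour accuracy when the
#' particle table carries a `class` column.
#'
#' @param particles A `qs_particles` tibble.
#' @param field The `qs_image_field` the particles came from (supplies ground
#'   truth and pixel size), or a ground-truth tibble with `centroid_x_px`,
#'   `centroid_y_px` (and optionally `colour`) columns.
#' @param max_dist_um Maximum centroid distance for a match (um).
#' @param pixel_size Pixel size, required when `field` is a plain tibble.
#' @param colour Restrict ground truth to activated cells of this colour
#'   (`NULL` keeps all activated cells).
#' @return A one-row tibble: `n_truth`, `n_detected`, `n_matched`, `recall`,
#'   `precision`, `colour_accuracy` (NA without class information).
#' @export
match_ground_truth <- function(particles, field, max_dist_um = 1,
                               pixel_size = NULL, colour = NULL) {
  if (inherits(field, "qs_image_field")) {
    truth <- field$ground_truth
    pixel_size <- field$pixel_size
  } else {
    truth <- field
    stopifnot(!is.null(pixel_size))
  }
  if ("activated" %in% names(truth)) truth <- truth[truth$activated, ]
  if (!is.null(colour)) truth <- truth[truth$colour == colour, ]
  n_truth <- nrow(truth); n_det <- nrow(particles)
  if (n_truth == 0 || n_det == 0) {
    return(tibble::tibble(n_truth = n_truth, n_detected = n_det,
                          n_matched = 0L,
                          recall = ifelse(n_truth == 0, NA_real_, 0),
                          precision = ifelse(n_det == 0, NA_real_, 0),
                          colour_accuracy = NA_real_))
  }
  d <- outer(particles$centroid_row_px, truth$centroid_y_px, "-")^2 +
       outer(particles$centroid_col_px, truth$centroid_x_px, "-")^2
  d <- sqrt(d) * pixel_size
  ord <- order(d)
  used_p <- logical(n_det); used_t <- logical(n_truth)
  matches <- list()
  for (k in ord) {
    if (d[k] > max_dist_um) break
    i <- (k - 1) %% n_det + 1
    j <- (k - 1) %/% n_det + 1
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE
      matches[[length(matches) + 1]] <- c(i, j)
    }
  }
  n_matched <- length(matches)
  col_acc <- NA_real_
  if (n_matched > 0 && "class" %in% names(particles) &&
      "colour" %in% names(truth)) {
    mm <- do.call(rbind, matches)
    col_acc <- mean(particles$class[mm[, 1]] == truth$colour[mm[, 2]])
  }
  tibble::tibble(n_truth = n_truth, n_detected = n_det,
                 n_matched = n_matched,
                 recall = n_matched / n_truth,
                 precision = n_matched / n_det,
                 colour_accuracy = col_acc)
}
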