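#' Place rod-shaped cells in a field of view
#'
#' Samples positions, sizes and orientations for a mixed population of
#' rod-shaped bacteria (modelled as rotated ellipses, length uniform in
#' 1.5-2 um, 3:1 aspect ratio). Placement rejects centroids closer than
#' `min_separation_um` to an already-placed cell for a bounded number of
#' retries; if a spot cannot be found the cell is placed anyway and a warning
#' summarises how many placements overlapped (dense fields never hang).
#'
#' @param n_red,n_green Number of cells of each reporter colour.
#' @param frac_activated_red,frac_activated_green Activation probability per
#'   colour (per-cell Bernoulli draws).
#' @param field_um Side length of the square field (um).
#' @param seed Integer seed.
#' @param length_range_um Cell length range (um).
#' @param aspect_ratio Length:width ratio.
#' @param min_separation_um Minimum centre-to-centre distance attempted.
#' @param max_retries Placement retries per cell before accepting overlap.
#' @return A tibble of cells: `cell_id`, `x_um`, `y_um` (centroid, x = column
#'   direction, y = row direction, origin top-left), `length_um`, `width_um`,
#'   `theta` (orientation, radians), `colour`, `activated`, `bound`.
#' @export
place_cells <- function(n_red, n_green, frac_activated_red = 1,
                        frac_activated_green = 1, field_um = 51.2, seed,
                        length_range_um = c(1.5, 2), aspect_ratio = 3,
                        min_separation_um = 1.8, max_retries = 40) {
  check_seed(seed)
  n <- n_red + n_green
  withr::with_seed(seed, {
    colour <- sample(rep(c("red", "green"), c(n_red, n_green)))
    p_act <- ifelse(colour == "red", frac_activated_red, frac_activated_green)
    activated <- stats::runif(n) < p_act
    xs <- ys <- numeric(n)
    overlaps <- 0L
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        x <- stats::runif(1, 0, field_um); y <- stats::runif(1, 0, field_um)
        if (i == 1L ||
            min((xs[seq_len(i - 1)] - x)^2 + (ys[seq_len(i - 1)] - y)^2) >=
              min_separation_um^2) {
          placed <- TRUE
          break
        }
      }
      if (!placed) overlaps <- overlaps + 1L
      xs[i] <- x; ys[i] <- y
    }
    if (overlaps > 0) {
      rlang::warn(sprintf("%d cells placed with overlap after %d retries",
                          overlaps, max_retries),
                  class = "qs_warning_placement")
    }
    len <- stats::runif(n, length_range_um[1], length_range_um[2])
    tibble::tibble(
      cell_id = seq_len(n), x_um = xs, y_um = ys,
      length_um = len, width_um = len / aspect_ratio,
      theta = stats::runif(n, 0, pi),
      colour = colour, activated = activated, bound = FALSE
    )
  })
}

#' Default optics configuration for field rendering
#'
#' @param amplitude Peak signal added per activated cell (counts).
#' @param background Mean background level (counts).
#' @param psf_sigma_um Gaussian point-spread sigma (um).
#' @param read_noise_sd Additive Gaussian read-noise standard deviation.
#' @return A named list.
#' @export
optics_config <- function(amplitude = 3000, background = 100,
                          psf_sigma_um = 0.15, read_noise_sd = 20) {
  list(amplitude = amplitude, background = background,
       psf_sigma_um = psf_sigma_um, read_noise_sd = read_noise_sd)
}

#' Render a two-channel fluorescence field
#'
#' Rasterises activated cells into their colour channel as filled rotated
#' ellipses, convolves with a Gaussian point-spread function, and adds
#' Poisson shot noise plus Gaussian read noise on top of a uniform background.
#' Non-activated cells contribute nothing beyond background (they carry no
#' fluorophore load). The ground-truth cell table travels with the rasters so
#' downstream quantification can be scored exactly.
#'
#' @param cells A cell tibble from [place_cells()] (or the captured output of
#'   [magnetic_sweep()]).
#' @param field_um Side length of the square field (um).
#' @param pixel_size Pixel size (um/px), default 0.1.
#' @param optics An [optics_config()] list.
#' @param seed Integer seed (noise only; geometry comes from `cells`).
#' @return An object of class `qs_image_field`: numeric matrices `red` and
#'   `green` (counts, rows = y), `pixel_size`, and `ground_truth` (the cell
#'   tibble with 0-based `centroid_x_px`, `centroid_y_px` appended).
#' @examples
#' cells <- place_cells(3, 3, field_um = 12.8, seed = 1)
#' fld <- render_field(cells, field_um = 12.8, seed = 2)
#' dim(fld$red)
#' @export
render_field <- function(cells, field_um = 51.2, pixel_size = 0.1,
                         optics = optics_config(), seed) {
  check_seed(seed)
  stopifnot(field_um > 0, pixel_size > 0)
  npx <- round(field_um / pixel_size)
  red <- matrix(0, npx, npx)
  green <- matrix(0, npx, npx)
  act <- cells[cells$activated, , drop = FALSE]
  for (i in seq_len(nrow(act))) {
    m <- rasterise_ellipse(npx, pixel_size,
                           act$x_um[i], act$y_um[i],
                           act$length_um[i] / 2, act$width_um[i] / 2,
                           act$theta[i])
    if (identical(act$colour[i], "red")) {
      red[m] <- red[m] + optics$amplitude
    } else {
      green[m] <- green[m] + optics$amplitude
    }
  }
  sig <- max(1, round(3 * optics$psf_sigma_um / pixel_size) * 2 + 1)
  brush <- EBImage::makeBrush(sig, shape = "gaussian",
                              sigma = optics$psf_sigma_um / pixel_size)
  # zero-padded boundaries: no wrap-around bleed from edge-touching cells
  red <- EBImage::filter2(red, brush, boundary = 0)
  green <- EBImage::filter2(green, brush, boundary = 0)
  out <- withr::with_seed(seed, {
    noisify <- function(ch) {
      lam <- pmax(ch + optics$background, 0)
      n <- matrix(stats::rpois(length(lam), lam), nrow(lam)) +
        matrix(stats::rnorm(length(lam), 0, optics$read_noise_sd), nrow(lam))
      pmin(pmax(n, 0), 65535)
    }
    list(red = noisify(red), green = noisify(green))
  })
  gt <- dplyr::mutate(cells,
                      centroid_x_px = .data$x_um / pixel_size - 0.5,
                      centroid_y_px = .data$y_um / pixel_size - 0.5)
  structure(list(red = out$red, green = out$green, pixel_size = pixel_size,
                 field_um = field_um, optics = optics, ground_truth = gt),
            class = "qs_image_field")
}

# Logical mask of pixels whose centres fall inside a rotated ellipse.
# Pixel (r, c) (1-based matrix indices) has centre ((c-0.5)*ps, (r-0.5)*ps).
rasterise_ellipse <- function(npx, ps, x0, y0, a, b, theta) {
  cmin <- max(1, floor((x0 - a) / ps)); cmax <- min(npx, ceiling((x0 + a) / ps))
  rmin <- max(1, floor((y0 - a) / ps)); rmax <- min(npx, ceiling((y0 + a) / ps))
  m <- matrix(FALSE, npx, npx)
  if (cmin > cmax || rmin > rmax) return(m)
  cc <- ((cmin:cmax) - 0.5) * ps - x0
  rr <- ((rmin:rmax) - 0.5) * ps - y0
  dx <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dy <- matrix(rr, length(rr), length(cc))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m[rmin:rmax, cmin:cmax] <- inside
  m
}

#' @export
print.qs_image_field <- function(x, ...) {
  cat(sprintf(
    "<qs_image_field %dx%d px at %.2g um/px, %d cells (%d activated)>\n",
    nrow(x$red), ncol(x$red), x$pixel_size, nrow(x$ground_truth),
    sum(x$ground_truth$activated)))
  invisible(x)
}

#' @method autoplot qs_image_field
#' @export
autoplot.qs_image_field <- function(object, downsample = 1, ...) {
  idx <- seq(1, nrow(object$red), by = downsample)
  df <- tidyr::expand_grid(row = idx, col = idx)
  df$red <- object$red[cbind(df$row, df$col)]
  df$green <- object$green[cbind(df$row, df$col)]
  mx <- max(df$red, df$green, 1)
  df$fill <- grDevices::rgb(pmin(df$red / mx * 2, 1),
                            pmin(df$green / mx * 2, 1), 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Write / read an image field as 16-bit TIFF plus ground-truth CSV
#'
#' The two channels are stored in the red and green planes of an RGB TIFF
#' (blue is zero); intensities are stored as counts / 65535. Ground truth goes
#' to `<prefix>_truth.csv` with 0-based pixel centroids.
#'
#' @param field A `qs_image_field`.
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>_truth.csv`.
#' @return `write_image_field()` returns the TIFF path invisibly;
#'   `read_image_field()` returns a `qs_image_field` (ground truth may be
#'   `NULL` if the CSV is absent).
#' @export
write_image_field <- function(field, prefix) {
  stopifnot(inherits(field, "qs_image_field"))
  arr <- array(0, c(nrow(field$red), ncol(field$red), 3))
  arr[, , 1] <- field$red / 65535
  arr[, , 2] <- field$green / 65535
  tif <- paste0(prefix, ".tif")
  tiff::writeTIFF(arr, tif, bits.per.sample = 16)
  utils::write.csv(
    dplyr::select(field$ground_truth, "centroid_x_px", "centroid_y_px",
                  "length_um", "colour", "activated", "bound"),
    paste0(prefix, "_truth.csv"), row.names = FALSE)
  invisible(tif)
}

#' @rdname write_image_field
#' @param pixel_size Pixel size (um/px) to attach on read.
#' @export
read_image_field <- function(prefix, pixel_size = 0.1) {
  arr <- tiff::readTIFF(paste0(prefix, ".tif"))
  truth_path <- paste0(prefix, "_truth.csv")
  gt <- if (file.exists(truth_path)) {
    tibble::as_tibble(utils::read.csv(truth_path))
  } else NULL
  structure(list(red = arr[, , 1] * 65535, green = arr[, , 2] * 65535,
                 pixel_size = pixel_size,
                 field_um = nrow(arr) * pixel_size,
                 optics = NULL, ground_truth = gt),
            class = "qs_image_field")
}
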