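#' Quadrant rule for phase-plane binning
#'
#' Thresholds that partition the (red, green) output plane into four
#' quadrants, mapped to fixed colour categories:
#' Q1 (both below) -> `none`; Q2 (red at/above, green below) -> `red`;
#' Q3 (green at/above, red below) -> `green`; Q4 (both at/above) ->
#' `red+green`. Comparisons use `>=` so boundary points classify
#' deterministically upward.
#'
#' @param t_r Red-axis threshold (`>= 0`).
#' @param t_g Green-axis threshold (`>= 0`).
#' @param unit Unit tag of the outputs being classified (e.g. `"fraction"`,
#'   `"count"`, `"percent_area"`); points must carry the same unit.
#' @return An object of class `qs_rule`.
#' @export
quadrant_rule <- function(t_r, t_g = t_r, unit = "fraction") {
  if (t_r < 0 || t_g < 0) {
    rlang::abort("thresholds must be >= 0", class = "qs_error_rule")
  }
  structure(list(t_r = t_r, t_g = t_g, unit = unit), class = "qs_rule")
}

quadrant_categories <- c(Q1 = "none", Q2 = "red", Q3 = "green",
                         Q4 = "red+green")

#' Classify phase points into quadrants and colour categories
#'
#' @param points A data frame with red output `x` and green output `y`
#'   columns (non-negative, same unit as the rule); an optional `unit` column
#'   or attribute is checked against the rule's unit.
#' @param rule A [quadrant_rule()].
#' @return `points` with `quadrant` (`"Q1"`..`"Q4"`) and `category`
#'   (`"none"`, `"red"`, `"green"`, `"red+green"`) columns appended.
#' @examples
#' classify_point(tibble::tibble(x = c(0, 1), y = c(0, 1)),
#'                quadrant_rule(0.05))
#' @export
classify_point <- function(points, rule) {
  stopifnot(is.data.frame(points), inherits(rule, "qs_rule"),
            all(c("x", "y") %in% names(points)))
  unit <- if ("unit" %in% names(points)) unique(points$unit)
          else attr(points, "unit")
  if (!is.null(unit) && !identical(unit, rule$unit)) {
    rlang::abort(sprintf("unit mismatch: points in '%s', rule in '%s'",
                         paste(unit, collapse = ","), rule$unit),
                 class = "qs_error_unit")
  }
  if (any(points$x < 0) || any(points$y < 0)) {
    rlang::abort("phase points must be non-negative", class = "qs_error_rule")
  }
  q <- dplyr::case_when(
    points$x >= rule$t_r & points$y >= rule$t_g ~ "Q4",
    points$x >= rule$t_r ~ "Q2",
    points$y >= rule$t_g ~ "Q3",
    TRUE ~ "Q1"
  )
  dplyr::mutate(tibble::as_tibble(points), quadrant = q,
                category = unname(quadrant_categories[q]))
}

# Largest value a curve attains over S >= 0 (for default threshold placement).
curve_max <- function(curve) {
  switch(curve$shape,
    monotone_up = curve$fmax,
    monotone_down = curve$fmax,
    constant = curve$f0,
    band_pass = {
      Sg <- exp(seq(log(curve$K) - 6, log(curve$K2) + 6, length.out = 400))
      max(activation_fraction(curve, c(0, Sg)))
    })
}

#' Default quadrant rule for a response pair
#'
#' Places each threshold at 5% of the maximum attainable output of its axis
#' (scaled by the population shares), the package's configurable convention
#' for "negligible colour".
#'
#' @param pair A `red`/`green` curve pair (e.g. from [case_library()]).
#' @param shares Population shares scaling the two axes.
#' @param frac Threshold as a fraction of maximum attainable output.
#' @param unit Unit tag for the rule.
#' @return A [quadrant_rule()].
#' @export
default_rule <- function(pair, shares = c(0.5, 0.5), frac = 0.05,
                         unit = "fraction") {
  quadrant_rule(frac * shares[1] * max(curve_max(pair$red), 1e-12),
                frac * shares[2] * max(curve_max(pair$green), 1e-12),
                unit = unit)
}

#' Sweep a response pair across a dose grid on the phase plane
#'
#' Evaluates the red and green outputs (population-share scaled activation
#' fractions) along a grid of signal concentrations, classifies each point,
#' and summarises the visual pattern: the set of occupied quadrants and the
#' ordered first-visit signature (e.g. `"Q1>Q2>Q4"`).
#'
#' @param pair A `red`/`green` curve pair.
#' @param S_grid Non-empty numeric vector of doses (uM, `>= 0`), ordered as
#'   the sweep should run.
#' @param rule A [quadrant_rule()]; `NULL` uses [default_rule()].
#' @param shares Population shares of the red and green members.
#' @return An object of class `qs_trajectory`: tibble `S_uM`, `x`, `y`,
#'   `quadrant`, `category`, with attributes `occupied` (character vector) and
#'   `signature`.
#' @examples
#' tr <- sweep_trajectory(case_library(7), S_grid = c(0, 0.5, 2, 10, 100))
#' occupied_quadrants(tr)
#' @export
sweep_trajectory <- function(pair, S_grid, rule = NULL,
                             shares = c(0.5, 0.5)) {
  if (length(S_grid) == 0 || any(S_grid < 0)) {
    rlang::abort("S_grid must be non-empty and non-negative",
                 class = "qs_error_rule")
  }
  if (is.null(rule)) rule <- default_rule(pair, shares)
  pts <- tibble::tibble(
    S_uM = S_grid,
    x = shares[1] * activation_fraction(pair$red, S_grid),
    y = shares[2] * activation_fraction(pair$green, S_grid)
  )
  out <- classify_point(pts, rule)
  first <- out$quadrant[!duplicated(out$quadrant)]
  structure(out,
            occupied = sort(unique(out$quadrant)),
            signature = paste(first, collapse = ">"),
            rule = rule,
            class = c("qs_trajectory", class(out)))
}

#' @rdname sweep_trajectory
#' @param trajectory A `qs_trajectory`.
#' @export
occupied_quadrants <- function(trajectory) attr(trajectory, "occupied")

#' @rdname sweep_trajectory
#' @export
trajectory_signature <- function(trajectory) attr(trajectory, "signature")

#' Robustness of a binning pattern under parameter perturbation
#'
#' Scores how stable a pair's occupied-quadrant set is when the curve
#' parameters are perturbed: over `n_draws` seeded draws, each curve's `K`
#' (and optionally `fmax`) is multiplied by a log-uniform factor in
#' `[1/(1+rel), 1+rel]`, the sweep is re-run, and the score is the fraction
#' of draws whose occupied set equals the unperturbed one. A zero-width
#' perturbation scores 1 by definition.
#'
#' @param pair A `red`/`green` curve pair.
#' @param S_grid Dose grid for the sweeps.
#' @param rule A [quadrant_rule()]; `NULL` uses [default_rule()].
#' @param rel_K Relative perturbation range for `K`.
#' @param rel_fmax Relative perturbation range for `fmax` (clamped to
#'   `[f0, 1]`).
#' @param n_draws Number of perturbation draws.
#' @param seed Integer seed.
#' @param shares Population shares.
#' @return A scalar in `[0, 1]`.
#' @export
robustness_score <- function(pair, S_grid, rule = NULL, rel_K = 0.1,
                             rel_fmax = 0, n_draws = 500, seed = 1,
                             shares = c(0.5, 0.5)) {
  check_seed(seed)
  if (is.null(rule)) rule <- default_rule(pair, shares)
  base <- occupied_quadrants(sweep_trajectory(pair, S_grid, rule, shares))
  if ((rel_K <= 0 && rel_fmax <= 0) || n_draws < 1) return(1)
  perturb <- function(curve, uK, uF) {
    K <- curve$K * (1 + rel_K)^uK
    fmax <- curve$fmax
    if (rel_fmax > 0) {
      fmax <- min(1, max(curve$f0, fmax * (1 + rel_fmax)^uF))
    }
    dose_response(curve$f0, fmax, K = K, n = curve$n, shape = curve$shape,
                  K2 = if (identical(curve$shape, "band_pass"))
                         curve$K2 * (1 + rel_K)^uK else NULL)
  }
  withr::with_seed(seed, {
    hits <- vapply(seq_len(n_draws), function(i) {
      u <- stats::runif(4, -1, 1)
      p2 <- list(red = perturb(pair$red, u[1], u[2]),
                 green = perturb(pair$green, u[3], u[4]))
      identical(occupied_quadrants(sweep_trajectory(p2, S_grid, rule, shares)),
                base)
    }, logical(1))
    mean(hits)
  })
}

#' Phase-plane pattern data for a set of library cases
#'
#' Produces plot-ready structured data for the per-case phase-plane patterns:
#' swept trajectories, threshold lines, and dot markers wherever two distinct
#' cases produce coincident phase points (within a tolerance), which makes
#' shared endpoints and crossings visually explicit.
#'
#' @param case_ids Integer vector of [case_library()] ids.
#' @param S_grid Dose grid (uM).
#' @param rule A shared [quadrant_rule()]; `NULL` derives a per-case default.
#' @param shares Population shares.
#' @param coincidence_tol Euclidean distance below which two cases' points at
#'   the same grid dose count as coincident.
#' @return An object of class `qs_pattern`: list of tibbles `points`,
#'   `thresholds`, `coincidences`.
#' @export
render_pattern <- function(case_ids, S_grid = c(0, 10^seq(-2, 3, length.out = 40)),
                           rule = NULL, shares = c(0.5, 0.5),
                           coincidence_tol = 1e-3) {
  stopifnot(all(case_ids %in% 1:10))
  points <- purrr::map_dfr(case_ids, function(id) {
    pair <- case_library(id)
    r <- rule %||% default_rule(pair, shares)
    tr <- sweep_trajectory(pair, S_grid, r, shares)
    dplyr::mutate(tibble::as_tibble(tr), case_id = id, .before = 1)
  })
  thresholds <- purrr::map_dfr(case_ids, function(id) {
    r <- rule %||% default_rule(case_library(id), shares)
    tibble::tibble(case_id = id, t_r = r$t_r, t_g = r$t_g)
  })
  coincidences <- tibble::tibble(case_a = integer(), case_b = integer(),
                                 S_uM = numeric(), x = numeric(), y = numeric())
  if (length(case_ids) > 1) {
    combos <- utils::combn(sort(unique(case_ids)), 2)
    for (k in seq_len(ncol(combos))) {
      a <- points[points$case_id == combos[1, k], ]
      b <- points[points$case_id == combos[2, k], ]
      hit <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2) < coincidence_tol
      if (any(hit)) {
        coincidences <- dplyr::bind_rows(coincidences, tibble::tibble(
          case_a = combos[1, k], case_b = combos[2, k],
          S_uM = a$S_uM[hit], x = a$x[hit], y = a$y[hit]))
      }
    }
  }
  structure(list(points = points, thresholds = thresholds,
                 coincidences = coincidences),
            class = "qs_pattern")
}

#' @export
print.qs_pattern <- function(x, ...) {
  cat(sprintf("<qs_pattern: %d cases, %d points, %d coincidences>\n",
              length(unique(x$points$case_id)), nrow(x$points),
              nrow(x$coincidences)))
  invisible(x)
}

#' @method autoplot qs_pattern
#' @export
autoplot.qs_pattern <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$quadrant), size = 1.5) +
    ggplot2::geom_vline(data = object$thresholds,
                        ggplot2::aes(xintercept = .data$t_r), linetype = 3) +
    ggplot2::geom_hline(data = object$thresholds,
                        ggplot2::aes(yintercept = .data$t_g), linetype = 3) +
    ggplot2::geom_point(data = object$coincidences, shape = 21, size = 3,
                        stroke = 0.8, fill = NA) +
    ggplot2::facet_wrap(~case_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "red output", y = "green output") +
    ggplot2::theme_minimal()
}
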