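#' Configuration of the nanoparticle capture-and-focus model
#'
#' Activated cells display the surface affinity peptide and so bind
#' streptavidin-conjugated magnetic nanoparticles with probability `beta`;
#' non-activated cells bind only non-specifically (`beta_ns`). A magnetic
#' sweep then captures each bound cell with efficiency `eta` and repositions
#' captured cells uniformly within a focal area `a_f` much smaller than the
#' distributed culture area `a0` — the source of the fold-amplification in
#' per-area fluorescent density, whose expectation is
#' `eta * beta * (a0 / a_f)`.
#'
#' @param bind_prob_activated Binding probability `beta` for activated cells.
#' @param bind_prob_nonspecific Non-specific binding probability `beta_ns`
#'   (must not exceed `beta`).
#' @param capture_efficiency Capture probability `eta` per bound cell.
#' @param distributed_area_um2 Distributed culture area `a0` (um^2).
#' @param focal_area_um2 Focal area `a_f` (um^2), `< a0`.
#' @return An object of class `qs_focus_config`.
#' @export
focus_config <- function(bind_prob_activated = 0.9,
                         bind_prob_nonspecific = 0.01,
                         capture_efficiency = 0.9,
                         distributed_area_um2 = 2.6e5,
                         focal_area_um2 = 2.6e3) {
  p <- c(bind_prob_activated, bind_prob_nonspecific, capture_efficiency)
  if (any(p < 0) || any(p > 1)) {
    rlang::abort("probabilities must lie in [0, 1]", class = "qs_error_focus")
  }
  if (bind_prob_nonspecific > bind_prob_activated) {
    rlang::abort("non-specific binding cannot exceed specific binding",
                 class = "qs_error_focus")
  }
  if (focal_area_um2 >= distributed_area_um2 || focal_area_um2 <= 0) {
    rlang::abort("need 0 < focal_area_um2 < distributed_area_um2",
                 class = "qs_error_focus")
  }
  structure(list(bind_prob_activated = bind_prob_activated,
                 bind_prob_nonspecific = bind_prob_nonspecific,
                 capture_efficiency = capture_efficiency,
                 distributed_area_um2 = distributed_area_um2,
                 focal_area_um2 = focal_area_um2),
            class = "qs_focus_config")
}

#' Bind magnetic nanoparticles to a cell population
#'
#' @param cells A cell tibble with a logical `activated` column (e.g. from
#'   [place_cells()]).
#' @param config A [focus_config()].
#' @param seed Integer seed.
#' @return `cells` with the logical `bound` column set per the binding model.
#' @export
bind_nanoparticles <- function(cells, config = focus_config(), seed) {
  stopifnot(is.data.frame(cells), "activated" %in% names(cells),
            inherits(config, "qs_focus_config"))
  check_seed(seed)
  p <- ifelse(cells$activated, config$bind_prob_activated,
              config$bind_prob_nonspecific)
  bound <- withr::with_seed(seed, stats::runif(nrow(cells)) < p)
  cells$bound <- bound
  attr(cells, "mNP_bound") <- TRUE
  cells
}

#' Apply a magnetic sweep to a nanoparticle-bound population
#'
#' Each bound cell is captured with probability `eta`; captured cells are
#' repositioned uniformly within a focal disc of area `a_f` centred on the
#' magnet, all other cells go to the supernatant. Capture is colour- and
#' size-blind given the bound flag, so the expected green:red composition of
#' the capture equals the pre-sweep activated composition. Cell bookkeeping is
#' exact: every input cell appears in exactly one output partition.
#'
#' @param cells Output of [bind_nanoparticles()] (must carry a `bound`
#'   column).
#' @param config A [focus_config()].
#' @param seed Integer seed.
#' @param centre_um Focal disc centre `(x, y)` in um.
#' @return An object of class `qs_sweep`: list with tibbles `captured`
#'   (repositioned) and `supernatant`, plus the config.
#' @export
magnetic_sweep <- function(cells, config = focus_config(), seed,
                           centre_um = c(0, 0)) {
  stopifnot(is.data.frame(cells), inherits(config, "qs_focus_config"))
  if (!"bound" %in% names(cells) || is.null(attr(cells, "mNP_bound"))) {
    rlang::abort("unbound population: run bind_nanoparticles() before sweeping",
                 class = "qs_error_unbound")
  }
  check_seed(seed)
  res <- withr::with_seed(seed, {
    captured <- cells$bound & stats::runif(nrow(cells)) < config$capture_efficiency
    cap <- cells[captured, , drop = FALSE]
    if (nrow(cap) > 0 && all(c("x_um", "y_um") %in% names(cap))) {
      r_f <- sqrt(config$focal_area_um2 / pi)
      rad <- r_f * sqrt(stats::runif(nrow(cap)))
      ang <- stats::runif(nrow(cap), 0, 2 * pi)
      cap$x_um <- centre_um[1] + rad * cos(ang)
      cap$y_um <- centre_um[2] + rad * sin(ang)
    }
    list(captured = cap, supernatant = cells[!captured, , drop = FALSE])
  })
  structure(list(captured = tibble::as_tibble(res$captured),
                 supernatant = tibble::as_tibble(res$supernatant),
                 config = config, seed = seed),
            class = "qs_sweep")
}

#' @export
print.qs_sweep <- function(x, ...) {
  cat(sprintf("<qs_sweep: %d captured, %d in supernatant (eta = %g)>\n",
              nrow(x$captured), nrow(x$supernatant),
              x$config$capture_efficiency))
  invisible(x)
}

#' @method glance qs_sweep
#' @export
glance.qs_sweep <- function(x, ...) {
  comp <- function(df) {
    c(red = sum(df$colour == "red" & df$activated),
      green = sum(df$colour == "green" & df$activated))
  }
  pre <- comp(dplyr::bind_rows(x$captured, x$supernatant))
  post <- comp(x$captured)
  tibble::tibble(n_captured = nrow(x$captured),
                 n_supernatant = nrow(x$supernatant),
                 pre_green_red_ratio = unname(pre["green"] / pre["red"]),
                 captured_green_red_ratio = unname(post["green"] / post["red"]))
}

#' Fold amplification of per-area fluorescent density
#'
#' Ratio of post-sweep to pre-sweep per-area density (counts per area or
#' spatial percent density, any consistent unit). With full capture into the
#' focal area the expectation is `eta * beta * (a0 / a_f)`.
#'
#' @param pre_density Pre-sweep density (`> 0` for a defined factor).
#' @param post_density Post-sweep density.
#' @return The fold change, or `NA` when `pre_density` is zero (no data).
#' @seealso [expected_amplification()]
#' @export
amplification_factor <- function(pre_density, post_density) {
  stopifnot(is.numeric(pre_density), is.numeric(post_density))
  ifelse(pre_density > 0, post_density / pre_density, NA_real_)
}

#' Closed-form expected amplification of a focus configuration
#'
#' @param config A [focus_config()].
#' @return `eta * beta * (a0 / a_f)`.
#' @export
expected_amplification <- function(config) {
  stopifnot(inherits(config, "qs_focus_config"))
  config$capture_efficiency * config$bind_prob_activated *
    config$distributed_area_um2 / config$focal_area_um2
}
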