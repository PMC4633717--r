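#' Describe a molecular environment scenario
#'
#' An environment is either an AI-2 producer culture whose signal accumulates
#' with cell density (`low_density` / `high_density`), or an explicit
#' `titration` of synthesized AI-2 doses. The producer (a non-fluorescent
#' AI-2 source, standing in for a quorum-signalling culture) grows
#' logistically; signal accumulates as `dS/dt = k * X(t)` where `X` is the
#' producer count, so sparse-nutrient cultures accumulate little AI-2 while
#' dense cultures cross the high-threshold responder's detection limit.
#'
#' Defaults encode producer-to-responder inoculation ratios of 20:1
#' (`low_density`, dilute medium, reduced carrying capacity) and 200:1
#' (`high_density`, rich medium) against a responder inoculum of 1e6 cells/mL.
#'
#' @param label `"low_density"`, `"high_density"` or `"titration"`.
#' @param producer_growth_rate Producer specific growth rate, per hour.
#' @param producer_inoculum Initial producer count (cells/mL).
#' @param carrying_capacity Producer carrying capacity (cells/mL).
#' @param signal_yield AI-2 yield `k` in uM per (cell/mL x hour) of integrated
#'   producer density.
#' @param duration Incubation time (h).
#' @param doses Explicit dose list (uM) for `titration` scenarios.
#' @return An object of class `qs_scenario`.
#' @examples
#' environment_scenario("titration")$doses
#' @export
environment_scenario <- function(label = c("low_density", "high_density",
                                           "titration"),
                                 producer_growth_rate = NULL,
                                 producer_inoculum = NULL,
                                 carrying_capacity = NULL,
                                 signal_yield = 2e-9,
                                 duration = 12,
                                 doses = c(0, 2, 10, 28, 75)) {
  label <- match.arg(label)
  defaults <- switch(label,
    low_density  = list(rate = 0.4, x0 = 2e7, cap = 2e8),
    high_density = list(rate = 0.6, x0 = 2e8, cap = 2e9),
    titration    = list(rate = 0, x0 = 0, cap = 1)
  )
  rate <- producer_growth_rate %||% defaults$rate
  x0 <- producer_inoculum %||% defaults$x0
  cap <- carrying_capacity %||% defaults$cap
  if (rate < 0 || x0 < 0 || cap <= 0 || signal_yield < 0 || duration <= 0) {
    rlang::abort("scenario rates, counts and duration must be non-negative",
                 class = "qs_error_scenario")
  }
  if (label == "titration" && any(doses < 0)) {
    rlang::abort("titration doses must be >= 0", class = "qs_error_scenario")
  }
  structure(list(label = label, producer_growth_rate = rate,
                 producer_inoculum = x0, carrying_capacity = cap,
                 signal_yield = signal_yield, duration = duration,
                 doses = if (label == "titration") doses else NULL),
            class = "qs_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate coculture growth
#'
#' Deterministic logistic growth of the responder populations sharing one
#' carrying capacity: `dN_i/dt = r_i N_i (1 - sum(N)/C)`. With equal growth
#' rates the population shares are invariant along the whole trajectory, so an
#' equal-inoculum pair stays a 1:1 mix.
#'
#' @param spec A [coculture()] specification (growth rates are taken from its
#'   responders).
#' @param initial_counts Initial counts per responder (cells/mL).
#' @param duration Simulated time (h).
#' @param dt Output time step (h).
#' @param carrying_capacity Shared carrying capacity (cells/mL).
#' @return A tibble with columns `time_h`, `name`, `colour`, `count`, `share`.
#' @examples
#' ab <- coculture_ab()
#' g <- simulate_growth(ab, c(1e6, 1e6), duration = 12, dt = 0.1)
#' tail(g, 2)
#' @export
simulate_growth <- function(spec, initial_counts, duration = 12, dt = 0.01,
                            carrying_capacity = 1e9) {
  stopifnot(inherits(spec, "qs_coculture"), dt > 0, duration > 0)
  k <- length(spec$responders)
  if (length(initial_counts) != k || any(initial_counts < 0)) {
    rlang::abort("initial_counts must be non-negative, one per responder",
                 class = "qs_error_growth")
  }
  if (sum(initial_counts) <= 0) {
    rlang::abort("total inoculum must be positive", class = "qs_error_growth")
  }
  rates <- vapply(spec$responders, function(r) r$growth_rate, numeric(1))
  deriv <- function(t, N, p) {
    list(p$rates * N * (1 - sum(N) / p$cap))
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(y = initial_counts, times = times, func = deriv,
                      parms = list(rates = rates, cap = carrying_capacity),
                      method = "lsoda", rtol = 1e-10, atol = 1e-4)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out) <- c("time_h", vapply(spec$responders, `[[`, character(1), "name"))
  long <- tidyr::pivot_longer(out, -"time_h", names_to = "name",
                              values_to = "count")
  cols <- vapply(spec$responders, `[[`, character(1), "colour")
  names(cols) <- vapply(spec$responders, `[[`, character(1), "name")
  long$colour <- unname(cols[long$name])
  dplyr::mutate(dplyr::group_by(long, .data$time_h),
                share = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("time_h", "name", "colour", "count", "share")
}

#' AI-2 accumulation in a producer environment
#'
#' Integrates producer logistic growth together with signal accumulation
#' `dS/dt = k * X(t)`. The mapping from culture density to AI-2 is a synthetic
#' monotone-linear calibration (yield `k` per integrated density), not a
#' measured conversion.
#'
#' @param scenario An [environment_scenario()] with a density label;
#'   `titration` scenarios carry explicit doses and are rejected here.
#' @param dt Output time step (h).
#' @return A tibble with columns `time_h`, `producer_count`, `S_uM`.
#' @export
producer_signal <- function(scenario, dt = 0.05) {
  stopifnot(inherits(scenario, "qs_scenario"))
  if (identical(scenario$label, "titration")) {
    rlang::abort("titration scenarios specify doses directly; no producer trajectory",
                 class = "qs_error_scenario")
  }
  deriv <- function(t, y, p) {
    X <- y[1]
    list(c(p$r * X * (1 - X / p$cap), p$k * X))
  }
  times <- seq(0, scenario$duration, by = dt)
  sol <- deSolve::ode(y = c(X = scenario$producer_inoculum, S = 0),
                      times = times, func = deriv,
                      parms = list(r = scenario$producer_growth_rate,
                                   cap = scenario$carrying_capacity,
                                   k = scenario$signal_yield),
                      method = "lsoda", rtol = 1e-9, atol = 1e-6)
  tibble::tibble(time_h = sol[, 1], producer_count = sol[, 2], S_uM = sol[, 3])
}

#' Terminal doses presented to the responders by a scenario
#'
#' Titration scenarios return their dose list; density scenarios return the
#' terminal accumulated AI-2 concentration.
#'
#' @param scenario An [environment_scenario()].
#' @return A tibble with columns `condition` and `dose_uM`.
#' @export
scenario_doses <- function(scenario) {
  stopifnot(inherits(scenario, "qs_scenario"))
  if (identical(scenario$label, "titration")) {
    tibble::tibble(condition = sprintf("%g uM", scenario$doses),
                   dose_uM = scenario$doses)
  } else {
    traj <- producer_signal(scenario)
    tibble::tibble(condition = scenario$label,
                   dose_uM = traj$S_uM[nrow(traj)])
  }
}
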