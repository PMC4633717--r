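#' Configure an end-to-end consortium run
#'
#' Bundles the environment scenario, the responder coculture, the read-out
#' mode, the optional magnetic sweep, the binning rule and the master seed
#' into a validated configuration. Every stochastic stage derives its own seed
#' deterministically from the master seed via a documented counter scheme
#' (see [stage_seed()]), so stages are independently reproducible.
#'
#' @param scenario An [environment_scenario()].
#' @param responders A [coculture()]; defaults to [coculture_ab()].
#' @param readout `"facs"`, `"imaging"` or `"both"`.
#' @param sweep Logical: run nanoparticle binding plus magnetic sweep.
#' @param focus A [focus_config()] used when `sweep` is `TRUE`.
#' @param rule A [quadrant_rule()]; `NULL` uses the default 5%-of-maximum
#'   rule for the responder pair.
#' @param seed Master integer seed.
#' @param n_events FACS events per condition.
#' @param n_cells Cells rendered per imaging condition.
#' @param field_um Imaging field side (um).
#' @return An object of class `qs_run_config`.
#' @export
run_config <- function(scenario = environment_scenario("titration"),
                       responders = coculture_ab(),
                       readout = c("facs", "imaging", "both"),
                       sweep = FALSE, focus = focus_config(), rule = NULL,
                       seed = 1, n_events = 50000, n_cells = 200,
                       field_um = 51.2) {
  readout <- match.arg(readout)
  stopifnot(inherits(scenario, "qs_scenario"),
            inherits(responders, "qs_coculture"),
            inherits(focus, "qs_focus_config"))
  check_seed(seed)
  if (length(responders$responders) != 2) {
    rlang::abort("the pipeline expects exactly two responders (red and green)",
                 class = "qs_error_config")
  }
  cols <- vapply(responders$responders, `[[`, character(1), "colour")
  if (!setequal(cols, c("red", "green"))) {
    rlang::abort("responders must cover both colour channels",
                 class = "qs_error_config")
  }
  structure(list(scenario = scenario, responders = responders,
                 readout = readout, sweep = sweep, focus = focus,
                 rule = rule, seed = as.integer(seed),
                 n_events = n_events, n_cells = n_cells, field_um = field_um),
            class = "qs_run_config")
}

#' Deterministic per-stage seed fan-out
#'
#' Stage seeds are `(master + 1009 * stage + 9173 * index) mod (2^31 - 1)`,
#' where `stage` indexes the pipeline stage (1 FACS, 2 placement, 3 render,
#' 4 binding, 5 sweep, 6 post-render) and `index` the condition. Identical
#' `(config, seed)` pairs therefore reproduce every stage bit-for-bit, and a
#' single stage can be re-run in isolation.
#'
#' @param master Master seed.
#' @param stage Stage counter.
#' @param index Condition counter.
#' @return An integer seed below `2^31`.
#' @export
stage_seed <- function(master, stage, index = 0) {
  as.integer((as.numeric(master) + 1009 * stage + 9173 * index) %% 2147483647)
}

#' Run the full interrogation pipeline
#'
#' Executes the stages in order: scenario doses -> coculture growth ->
#' per-condition activation -> FACS and/or imaging read-out -> optional
#' nanoparticle binding and magnetic sweep -> phase-plane binning. Red and
#' green outputs are kept as fractions internally; the report renders
#' percentages only in its print method.
#'
#' @param config A [run_config()].
#' @return An object of class `qs_run_report`: `conditions` tibble (one row
#'   per condition with red/green outputs, gated fractions, densities,
#'   amplification and bin label), `growth` trajectory, and a provenance list
#'   (seeds, config hash).
#' @examples
#' \donttest{
#' rep <- run_pipeline(run_config(seed = 7, n_events = 2000))
#' glance(rep)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qs_run_config"))
  doses <- scenario_doses(config$scenario)
  spec <- config$responders
  growth <- simulate_growth(spec, rep(1e6, length(spec$responders)),
                            duration = config$scenario$duration, dt = 0.1)
  final_shares <- growth$share[growth$time_h == max(growth$time_h)]
  names(final_shares) <- growth$name[growth$time_h == max(growth$time_h)]
  red_i <- which(vapply(spec$responders, `[[`, character(1), "colour") == "red")
  green_i <- setdiff(1:2, red_i)
  pair <- list(red = spec$responders[[red_i]]$curve,
               green = spec$responders[[green_i]]$curve)
  shares <- c(spec$shares[red_i], spec$shares[green_i])
  rule <- config$rule %||% default_rule(pair, shares)

  rows <- purrr::map_dfr(seq_len(nrow(doses)), function(i) {
    S <- doses$dose_uM[i]
    fr <- coculture_fractions(spec, S)
    row <- tibble::tibble(
      condition = doses$condition[i], dose_uM = S,
      red_activation = fr$activation[fr$colour == "red"],
      green_activation = fr$activation[fr$colour == "green"],
      x = fr$activated_share[fr$colour == "red"],
      y = fr$activated_share[fr$colour == "green"]
    )
    if (config$readout %in% c("facs", "both")) {
      gf <- vapply(spec$responders, function(r) {
        simulate_facs(r, S, config$n_events,
                      seed = stage_seed(config$seed, 1,
                                        i * 10 + match(r$colour, c("red", "green")))
        )$gated_fraction
      }, numeric(1))
      row$red_gated <- gf[red_i]; row$green_gated <- gf[green_i]
    }
    if (config$readout %in% c("imaging", "both")) {
      n_red <- round(config$n_cells * shares[1])
      cells <- place_cells(n_red, config$n_cells - n_red,
                           frac_activated_red = row$red_activation,
                           frac_activated_green = row$green_activation,
                           field_um = config$field_um,
                           seed = stage_seed(config$seed, 2, i))
      fld <- render_field(cells, field_um = config$field_um,
                          seed = stage_seed(config$seed, 3, i))
      row$red_density <- spatial_density(fld$red)
      row$green_density <- spatial_density(fld$green)
      cls <- classify_particles(fld$red, fld$green)
      cnt <- particle_counts(cls)
      row$red_count <- cnt$n[cnt$class == "red"]
      row$green_count <- cnt$n[cnt$class == "green"]
      if (config$sweep) {
        bound <- bind_nanoparticles(cells, config$focus,
                                    seed = stage_seed(config$seed, 4, i))
        sw <- magnetic_sweep(bound, config$focus,
                             seed = stage_seed(config$seed, 5, i))
        a0 <- config$focus$distributed_area_um2
        af <- config$focus$focal_area_um2
        act_pre <- sum(cells$activated)
        act_post <- sum(sw$captured$activated)
        row$pre_sweep_density <- act_pre / a0
        row$post_sweep_density <- act_post / af
        row$amplification <- amplification_factor(act_pre / a0, act_post / af)
        cap <- glance(sw)
        row$captured_green_red_ratio <- cap$captured_green_red_ratio
      }
    }
    row
  })
  binned <- classify_point(dplyr::select(rows, "x", "y"), rule)
  rows$quadrant <- binned$quadrant
  rows$category <- binned$category

  structure(list(
    conditions = rows, growth = growth, rule = rule,
    provenance = list(
      master_seed = config$seed,
      readout = config$readout,
      sweep = config$sweep,
      scenario = config$scenario$label,
      config_hash = rlang::hash(config),
      package_version = as.character(utils::packageVersion("qsconsort"))
    )),
    class = "qs_run_report")
}

#' @export
print.qs_run_report <- function(x, ...) {
  cat(sprintf("<qs_run_report: scenario '%s', %d conditions, seed %d>\n",
              x$provenance$scenario, nrow(x$conditions),
              x$provenance$master_seed))
  show <- dplyr::transmute(
    x$conditions,
    condition = .data$condition,
    dose_uM = round(.data$dose_uM, 3),
    red_pct = round(100 * .data$x, 1),
    green_pct = round(100 * .data$y, 1),
    category = .data$category)
  print(show, n = Inf)
  invisible(x)
}

#' @method glance qs_run_report
#' @export
glance.qs_run_report <- function(x, ...) x$conditions

#' @method tidy qs_run_report
#' @export
tidy.qs_run_report <- function(x, ...) {
  tidyr::pivot_longer(x$conditions, -c("condition", "dose_uM",
                                       "quadrant", "category"),
                      names_to = "metric", values_to = "value")
}

#' Read a run configuration from YAML or JSON
#'
#' The schema mirrors [run_config()]: top-level keys `scenario` (fields of
#' [environment_scenario()]), `responders` (list with `name`, `colour`,
#' `growth_rate` and `curve` fields of [dose_response()], plus optional
#' `shares`), `readout`, `sweep`, `focus` (fields of [focus_config()]),
#' `rule` (`t_r`, `t_g`, `unit`), `seed`, `n_events`, `n_cells`, `field_um`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `qs_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  sc <- do.call(environment_scenario, raw$scenario %||% list())
  resp <- if (is.null(raw$responders)) {
    coculture_ab()
  } else {
    members <- purrr::map(raw$responders$members, function(m) {
      responder(m$name, m$colour,
                do.call(dose_response, m$curve),
                m$growth_rate %||% 0.8)
    })
    coculture(members, raw$responders$shares %||% NULL)
  }
  run_config(
    scenario = sc, responders = resp,
    readout = raw$readout %||% "facs",
    sweep = isTRUE(raw$sweep),
    focus = do.call(focus_config, raw$focus %||% list()),
    rule = if (!is.null(raw$rule)) do.call(quadrant_rule, raw$rule),
    seed = raw$seed %||% 1,
    n_events = raw$n_events %||% 50000,
    n_cells = raw$n_cells %||% 200,
    field_um = raw$field_um %||% 51.2
  )
}

#' Write a curve or responder definition to JSON/YAML
#'
#' @param x A `qs_curve` or `qs_responder`.
#' @param path Output path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_curve_spec <- function(x, path) {
  as_list <- function(cv) {
    l <- list(f0 = cv$f0, fmax = cv$fmax, K = cv$K, n = cv$n, shape = cv$shape)
    if (!is.null(cv$K2)) l$K2 <- cv$K2
    l
  }
  payload <- if (inherits(x, "qs_responder")) {
    list(name = x$name, colour = x$colour, growth_rate = x$growth_rate,
         curve = as_list(x$curve))
  } else if (inherits(x, "qs_curve")) {
    as_list(x)
  } else {
    rlang::abort("x must be a qs_curve or qs_responder", class = "qs_error_io")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}

#' @rdname write_curve_spec
#' @export
read_curve_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$curve)) {
    responder(raw$name, raw$colour, do.call(dose_response, raw$curve),
              raw$growth_rate %||% 0.8)
  } else {
    do.call(dose_response, raw)
  }
}

#' Calibrate against the published dose-response table
#'
#' Loads the packaged CSV of published responding-fraction measurements for
#' responders A (red, low threshold) and B (green, high threshold), fits a
#' Monod curve to each series, re-runs the titration pipeline with the fitted
#' responders, and returns the side-by-side table of published versus fitted
#' fractions with residuals. This is a calibration aid, not a validation: the
#' fitted curves are compared against the very points they were fitted to.
#'
#' @param path CSV with columns `dose_uM`, `fraction`, `responder`, `source`;
#'   defaults to the packaged fixture.
#' @param seed Master seed for the pipeline stage.
#' @return A list with elements `fits` (named list of `qs_fit`),
#'   `comparison` (tibble of published vs fitted fractions) and `report`
#'   (the titration `qs_run_report` at the fitted parameters).
#' @export
reproduce_reference_fixtures <- function(path = NULL, seed = 1) {
  path <- path %||% system.file("extdata", "dose_response_printed.csv",
                                package = "qsconsort")
  if (is.null(path) || !nzchar(path) || !file.exists(path)) {
    rlang::abort("printed dose-response fixture not found",
                 class = "qs_error_missing_fixture")
  }
  tab <- tibble::as_tibble(utils::read.csv(path))
  if (nrow(tab) == 0 ||
      !all(c("dose_uM", "fraction", "responder") %in% names(tab))) {
    rlang::abort("fixture is empty or malformed",
                 class = "qs_error_missing_fixture")
  }
  fits <- purrr::map(split(tab, tab$responder),
                     ~fit_dose_response(.x, dose_uM, fraction))
  comparison <- dplyr::mutate(
    tab,
    fitted = purrr::map2_dbl(.data$responder, .data$dose_uM,
                             ~activation_fraction(fits[[.x]]$curve, .y)),
    residual = .data$fraction - .data$fitted)
  resp <- coculture(list(
    responder("A", "red", fits[["A"]]$curve, 0.8),
    responder("B", "green", fits[["B"]]$curve, 0.8)
  ))
  doses <- sort(unique(tab$dose_uM))
  report <- run_pipeline(run_config(
    scenario = environment_scenario("titration", doses = doses),
    responders = resp, readout = "facs", seed = seed, n_events = 50000))
  list(fits = fits, comparison = tibble::as_tibble(comparison),
       report = report)
}
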