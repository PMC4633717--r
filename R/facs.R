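#' Simulate a flow-cytometry sample
#'
#' Draws per-event activation as Bernoulli trials at the responder's
#' curve-given probability `f(S)`, then assigns each event a fluorescence
#' intensity (arbitrary units) from log-normal "on" or "off" (background)
#' distributions. Events at or above the gate threshold are counted as
#' positive; the gated fraction is an unbiased estimator of the gate-exceedance
#' probability. The default intensity scale places the conventional gate of
#' 2e3 between the off and on modes.
#'
#' @param responder A [responder()].
#' @param S AI-2 concentration (uM), scalar.
#' @param n_events Number of events, `>= 1` (default 50000).
#' @param seed Integer seed; identical `(arguments, seed)` give identical
#'   samples.
#' @param gate_threshold Intensity gate (arbitrary units).
#' @param off_meanlog,off_sdlog Log-normal parameters of the background
#'   ("off") intensity distribution.
#' @param on_meanlog,on_sdlog Log-normal parameters of the activated ("on")
#'   intensity distribution.
#' @return An object of class `qs_facs`: event table plus gate metadata.
#'   `glance()` returns the summary row; `tidy()` the event table.
#' @examples
#' a <- responder("A", "red", dose_response(0, 0.9, K = 10))
#' fs <- simulate_facs(a, S = 10, n_events = 1000, seed = 1)
#' glance(fs)$gated_fraction
#' @export
simulate_facs <- function(responder, S, n_events = 50000, seed,
                          gate_threshold = 2e3,
                          off_meanlog = log(150), off_sdlog = 0.8,
                          on_meanlog = log(2e4), on_sdlog = 0.5) {
  stopifnot(inherits(responder, "qs_responder"), length(S) == 1,
            n_events >= 1)
  check_seed(seed)
  p <- activation_fraction(responder$curve, S)
  events <- withr::with_seed(seed, {
    act <- stats::rbinom(n_events, 1L, p) == 1L
    intensity <- numeric(n_events)
    intensity[act] <- stats::rlnorm(sum(act), on_meanlog, on_sdlog)
    intensity[!act] <- stats::rlnorm(sum(!act), off_meanlog, off_sdlog)
    tibble::tibble(event_id = seq_len(n_events), intensity = intensity,
                   activated_truth = act)
  })
  structure(
    list(events = events,
         gate_threshold = gate_threshold,
         n_events = as.integer(n_events),
         gated_fraction = mean(events$intensity >= gate_threshold),
         S_uM = S, responder = responder$name, colour = responder$colour,
         activation_probability = p, seed = seed),
    class = "qs_facs"
  )
}

check_seed <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed) ||
      seed != round(seed)) {
    rlang::abort("seed must be a single integer", class = "qs_error_seed")
  }
  invisible(as.integer(seed))
}

#' @export
print.qs_facs <- function(x, ...) {
  cat(sprintf(
    "<qs_facs %s at %g uM: %d events, gate %g, gated fraction %.4f>\n",
    x$responder, x$S_uM, x$n_events, x$gate_threshold, x$gated_fraction))
  invisible(x)
}

#' @method tidy qs_facs
#' @export
tidy.qs_facs <- function(x, ...) x$events

#' @method glance qs_facs
#' @export
glance.qs_facs <- function(x, ...) {
  tibble::tibble(responder = x$responder, S_uM = x$S_uM,
                 n_events = x$n_events, gate_threshold = x$gate_threshold,
                 gated_fraction = x$gated_fraction,
                 activation_probability = x$activation_probability)
}

#' @method autoplot qs_facs
#' @export
autoplot.qs_facs <- function(object, bins = 80, ...) {
  ggplot2::ggplot(object$events, ggplot2::aes(x = .data$intensity)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$gate_threshold,
                        linetype = 2, colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "intensity (a.u.)", y = "events",
                  title = sprintf("%s at %g uM (gated %.1f%%)", object$responder,
                                  object$S_uM, 100 * object$gated_fraction)) +
    ggplot2::theme_minimal()
}

#' Write / read a FACS event table as CSV
#'
#' Columns: `event_id`, `intensity`, `activated_truth`. Gate metadata is
#' stored in `#`-prefixed header comments.
#'
#' @param x A `qs_facs` object.
#' @param path Output CSV path.
#' @return `write_facs_csv()` returns `path` invisibly; `read_facs_csv()`
#'   returns the event tibble with gate metadata in attributes.
#' @export
write_facs_csv <- function(x, path) {
  stopifnot(inherits(x, "qs_facs"))
  hdr <- sprintf("# gate_threshold=%g n_events=%d responder=%s S_uM=%g",
                 x$gate_threshold, x$n_events, x$responder, x$S_uM)
  writeLines(hdr, path)
  suppressWarnings(utils::write.table(x$events, path, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      quote = FALSE))
  invisible(path)
}

#' @rdname write_facs_csv
#' @export
read_facs_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  df <- tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
  meta <- strsplit(sub("^# *", "", hdr), " ")[[1]]
  kv <- strsplit(meta, "=")
  for (p in kv) attr(df, p[1]) <- utils::type.convert(p[2], as.is = TRUE)
  df
}
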