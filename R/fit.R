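#' Fit a saturation-constant dose-response model
#'
#' Estimates the saturation constant `K` and the baseline/saturating responding
#' fractions `f0`/`fmax` of a Monod/Hill dose-response curve from observed
#' (dose, fraction) pairs by least squares. The fit is fully deterministic and
#' proceeds in two stages:
#'
#' 1. a log-spaced grid over candidate `K` values; at each `K` the model is
#'    linear in `(f0, fmax)` and is solved exactly subject to
#'    `0 <= f0 <= fmax <= 1` (unconstrained 2x2 solve, projected onto the
#'    active constraint faces when needed);
#' 2. golden-section refinement of `log10(K)` between the grid neighbours of
#'    the grid minimiser.
#'
#' The Hill exponent `n` is held fixed (default 1, the Monod case), mirroring
#' how saturation constants are compared across mono- and coculture
#' measurements without confounding from shape changes.
#'
#' @param data A data frame of observations.
#' @param dose,fraction Column names (unquoted) holding doses (uM, `>= 0`) and
#'   responding fractions (`[0, 1]`).
#' @param shape Curve shape; only `"monotone_up"` fits are supported.
#' @param n Fixed Hill exponent (`1` = Monod).
#' @param K_grid Number of log-spaced grid points in stage one.
#' @param degenerate_tol Minimum spread of the fractions below which the data
#'   cannot identify `K` and the fit aborts with a `"degenerate response"`
#'   error.
#' @return An object of class `qs_fit` supporting [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(dose_uM = c(1, 3, 10, 30, 100),
#'                     fraction = activation_fraction(dose_response(0, 0.9, 10),
#'                                                    c(1, 3, 10, 30, 100)))
#' fit <- fit_dose_response(d, dose_uM, fraction)
#' tidy(fit)
#' @export
fit_dose_response <- function(data, dose = dose_uM, fraction = fraction,
                              shape = "monotone_up", n = 1, K_grid = 120,
                              degenerate_tol = 1e-3) {
  stopifnot(is.data.frame(data))
  S <- dplyr::pull(data, {{ dose }})
  f <- dplyr::pull(data, {{ fraction }})
  if (!identical(shape, "monotone_up")) {
    rlang::abort("only monotone_up fits are supported", class = "qs_error_fit")
  }
  if (any(S < 0) || any(f < 0) || any(f > 1)) {
    rlang::abort("doses must be >= 0 and fractions in [0, 1]",
                 class = "qs_error_fit")
  }
  keep <- !is.na(S) & !is.na(f)
  S <- S[keep]; f <- f[keep]
  if (length(unique(S)) < 3) {
    rlang::abort("need at least 3 distinct doses to fit K",
                 class = "qs_error_fit_underdetermined")
  }
  if (diff(range(f)) < degenerate_tol) {
    rlang::abort("degenerate response: fractions are constant, K unidentifiable",
                 class = "qs_error_fit_degenerate")
  }

  Spos <- S[S > 0]
  grid <- 10^seq(log10(min(Spos)) - 2, log10(max(Spos)) + 2,
                 length.out = K_grid)
  rss_at <- function(K) solve_levels(S, f, K, n)$rss
  rss_grid <- vapply(grid, rss_at, numeric(1))
  i <- which.min(rss_grid)
  lo <- log10(grid[max(1, i - 1)])
  hi <- log10(grid[min(length(grid), i + 1)])
  opt <- stats::optimize(function(lk) rss_at(10^lk), c(lo, hi),
                         tol = 1e-7)  # golden-section + parabolic refinement
  K_hat <- 10^opt$minimum
  sol <- solve_levels(S, f, K_hat, n)

  structure(
    list(
      curve = dose_response(sol$f0, sol$fmax, K = K_hat, n = n,
                            shape = "monotone_up"),
      rss = sol$rss,
      n_obs = length(S),
      data = tibble::tibble(dose_uM = S, fraction = f,
                            fitted = sol$f0 + (sol$fmax - sol$f0) *
                              hill_term(S, K_hat, n)),
      K_grid = grid
    ),
    class = "qs_fit"
  )
}

# Constrained least squares for (f0, fmax) at fixed K and n.
# Model: f = f0 (1 - h) + fmax h with h = S^n/(K^n + S^n); feasible region
# 0 <= f0 <= fmax <= 1. The QP solution is either the unconstrained solve or
# its projection onto a face/corner of the triangle-shaped feasible set.
solve_levels <- function(S, f, K, n) {
  h <- hill_term(S, K, n)
  u <- 1 - h
  rss_of <- function(a, b) sum((f - (a * u + b * h))^2)
  cand <- list()
  # unconstrained normal equations
  M <- matrix(c(sum(u * u), sum(u * h), sum(u * h), sum(h * h)), 2, 2)
  v <- c(sum(f * u), sum(f * h))
  det <- M[1, 1] * M[2, 2] - M[1, 2]^2
  if (det > 1e-12 * M[1, 1] * M[2, 2]) {
    ab <- solve(M, v)
    if (ab[1] >= 0 && ab[2] <= 1 && ab[1] <= ab[2]) {
      cand <- c(cand, list(ab))
    }
  }
  clamp01 <- function(x) min(1, max(0, x))
  # faces: f0 = 0; fmax = 1; f0 = fmax
  if (sum(h * h) > 0) cand <- c(cand, list(c(0, clamp01(sum(f * h) / sum(h * h)))))
  if (sum(u * u) > 0) {
    a <- clamp01(sum((f - h) * u) / sum(u * u))
    cand <- c(cand, list(c(min(a, 1), 1)))
  }
  cand <- c(cand, list(rep(clamp01(mean(f)), 2)),
            list(c(0, 0)), list(c(0, 1)), list(c(1, 1)))
  cand <- Filter(function(ab) ab[1] >= 0 && ab[2] <= 1 && ab[1] <= ab[2], cand)
  rss <- vapply(cand, function(ab) rss_of(ab[1], ab[2]), numeric(1))
  best <- cand[[which.min(rss)]]
  list(f0 = best[1], fmax = best[2], rss = min(rss))
}

#' @export
print.qs_fit <- function(x, ...) {
  cat("<qs_fit>\n")
  print(x$curve)
  cat(sprintf("  RSS = %.4g on %d observations\n", x$rss, x$n_obs))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @method tidy qs_fit
#' @export
tidy.qs_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f0", "fmax", "K", "n"),
    estimate = c(x$curve$f0, x$curve$fmax, x$curve$K, x$curve$n),
    unit = c("fraction", "fraction", "uM", "")
  )
}

#' @method glance qs_fit
#' @export
glance.qs_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n_obs = x$n_obs,
                 df_residual = x$n_obs - 3L,
                 rmse = sqrt(x$rss / x$n_obs))
}

#' @method augment qs_fit
#' @export
augment.qs_fit <- function(x, ...) {
  dplyr::mutate(x$data, .resid = .data$fraction - .data$fitted)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot qs_fit
#' @export
autoplot.qs_fit <- function(object, ...) {
  rng <- range(object$data$dose_uM[object$data$dose_uM > 0])
  Sg <- c(0, 10^seq(log10(rng[1]) - 1, log10(rng[2]) + 1, length.out = 200))
  pred <- tibble::tibble(dose_uM = Sg,
                         fraction = activation_fraction(object$curve, Sg))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose_uM, y = .data$fraction)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = scales_pseudo_log()) +
    ggplot2::labs(x = "AI-2 (uM)", y = "responding fraction",
                  title = sprintf("Fitted curve: K = %.3g uM", object$curve$K)) +
    ggplot2::theme_minimal()
}

# pseudo-log axis that tolerates dose 0 without importing scales directly
scales_pseudo_log <- function() {
  if (requireNamespace("scales", quietly = TRUE)) {
    scales::pseudo_log_trans(base = 10)
  } else {
    "identity"
  }
}
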