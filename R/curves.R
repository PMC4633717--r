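#' Parametric AI-2 dose-response curve
#'
#' Constructs a phenomenological dose-response curve giving the fraction of an
#' engineered responder population that activates (expresses its fluorescent
#' surface fusion) at a signal concentration `S` (micromolar AI-2). The default
#' Monod form (`n = 1`) models saturable uptake-driven induction; a Hill
#' exponent `n > 1` gives steeper switch-like responses used by the
#' hypothetical case library.
#'
#' Supported shapes:
#' * `"monotone_up"`: `f(S) = f0 + (fmax - f0) * S^n / (K^n + S^n)`
#' * `"monotone_down"`: `f(S) = fmax - (fmax - f0) * S^n / (K^n + S^n)`
#' * `"band_pass"`: rises with half-saturation `K`, falls with half-saturation
#'   `K2 > K`: `f(S) = f0 + (fmax - f0) * [S^n/(K^n + S^n)] * [K2^n/(K2^n + S^n)]`
#' * `"constant"`: `f(S) = f0 = fmax` for all `S`
#'
#' @param f0 Baseline responding fraction at zero signal, in `[0, 1]`.
#' @param fmax Saturating responding fraction, in `[f0, 1]`.
#' @param K Saturation constant in uM: the signal level of half-maximal
#'   activation for monotone shapes.
#' @param n Cooperativity (Hill) exponent, `> 0`; `n = 1` is the Monod case.
#' @param shape One of `"monotone_up"`, `"monotone_down"`, `"band_pass"`,
#'   `"constant"`.
#' @param K2 Second half-saturation constant (uM) for the descending limb of a
#'   band-pass curve; must exceed `K`.
#'
#' @return An object of class `qs_curve`.
#' @examples
#' crv <- dose_response(f0 = 0, fmax = 0.9, K = 10)
#' activation_fraction(crv, c(0, 10, 28))
#' @export
dose_response <- function(f0 = 0, fmax = 1, K = 10, n = 1,
                          shape = c("monotone_up", "monotone_down",
                                    "band_pass", "constant"),
                          K2 = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(f0), is.numeric(fmax), is.numeric(K), is.numeric(n),
            length(f0) == 1, length(fmax) == 1, length(K) == 1, length(n) == 1)
  if (f0 < 0 || fmax > 1 || f0 > fmax) {
    rlang::abort("must have 0 <= f0 <= fmax <= 1", class = "qs_error_curve")
  }
  if (K <= 0) rlang::abort("K must be > 0", class = "qs_error_curve")
  if (n < 0) rlang::abort("n must be >= 0", class = "qs_error_curve")
  if (shape == "band_pass") {
    if (is.null(K2) || K2 <= K) {
      rlang::abort("band_pass curves need K2 > K", class = "qs_error_curve")
    }
  } else {
    K2 <- NULL
  }
  if (shape == "constant" && abs(f0 - fmax) > .Machine$double.eps^0.5) {
    rlang::abort("constant curves need f0 == fmax", class = "qs_error_curve")
  }
  structure(list(f0 = f0, fmax = fmax, K = K, n = n, shape = shape, K2 = K2),
            class = "qs_curve")
}

#' @export
print.qs_curve <- function(x, ...) {
  extra <- if (identical(x$shape, "band_pass")) sprintf(", K2 = %g uM", x$K2) else ""
  cat(sprintf("<qs_curve %s: f0 = %g, fmax = %g, K = %g uM, n = %g%s>\n",
              x$shape, x$f0, x$fmax, x$K, x$n, extra))
  invisible(x)
}

# Saturating Hill term S^n/(K^n + S^n); exact 0 at S = 0, stable for large S.
hill_term <- function(S, K, n) {
  out <- numeric(length(S))
  pos <- S > 0
  out[pos] <- 1 / (1 + (K / S[pos])^n)
  if (n == 0) out[!pos] <- 0.5  # degenerate exponent: flat at 1/2
  out
}

#' Evaluate a dose-response curve
#'
#' Returns the activation probability (responding fraction) at one or more
#' signal concentrations.
#'
#' @param curve A [dose_response()] curve.
#' @param S Numeric vector of AI-2 concentrations in uM; all `>= 0`.
#' @return Numeric vector of fractions in `[0, 1]`, same length as `S`.
#' @examples
#' activation_fraction(dose_response(0, 0.9, K = 10), 10)  # 0.45
#' @export
activation_fraction <- function(curve, S) {
  stopifnot(inherits(curve, "qs_curve"), is.numeric(S))
  if (any(!is.finite(S)) || any(S < 0)) {
    rlang::abort("S must be finite and >= 0", class = "qs_error_domain")
  }
  h <- hill_term(S, curve$K, curve$n)
  switch(curve$shape,
    monotone_up   = curve$f0 + (curve$fmax - curve$f0) * h,
    monotone_down = curve$fmax - (curve$fmax - curve$f0) * h,
    band_pass     = curve$f0 + (curve$fmax - curve$f0) * h *
                      (1 - hill_term(S, curve$K2, curve$n)),
    constant      = rep(curve$f0, length(S))
  )
}

#' Define a responder population
#'
#' A named engineered sensor population: its reporter colour channel, its
#' dose-response curve and its exponential growth rate.
#'
#' @param name Population label, e.g. `"A"`.
#' @param colour `"red"` or `"green"` reporter channel.
#' @param curve A [dose_response()] curve.
#' @param growth_rate Specific growth rate, per hour, `>= 0`.
#' @return An object of class `qs_responder`.
#' @export
responder <- function(name, colour = c("red", "green"), curve,
                      growth_rate = 0.8) {
  colour <- match.arg(colour)
  stopifnot(is.character(name), length(name) == 1, inherits(curve, "qs_curve"),
            is.numeric(growth_rate), length(growth_rate) == 1)
  if (growth_rate < 0) rlang::abort("growth_rate must be >= 0",
                                    class = "qs_error_curve")
  structure(list(name = name, colour = colour, curve = curve,
                 growth_rate = growth_rate),
            class = "qs_responder")
}

#' Define a coculture of responder populations
#'
#' @param responders List of [responder()] objects.
#' @param shares Initial population fractions; must sum to 1.
#' @return An object of class `qs_coculture`.
#' @examples
#' ab <- coculture_ab()
#' coculture_fractions(ab, S = 28)
#' @export
coculture <- function(responders, shares = NULL) {
  stopifnot(is.list(responders), length(responders) >= 1,
            all(vapply(responders, inherits, logical(1), "qs_responder")))
  if (is.null(shares)) shares <- rep(1 / length(responders), length(responders))
  if (length(shares) != length(responders)) {
    rlang::abort("shares must match responders in length", class = "qs_error_curve")
  }
  if (abs(sum(shares) - 1) > 1e-9 || any(shares < 0)) {
    rlang::abort("shares must be non-negative and sum to 1 (tol 1e-9)",
                 class = "qs_error_curve")
  }
  structure(list(responders = responders, shares = shares),
            class = "qs_coculture")
}

#' The package's default A/B consortium
#'
#' Responder A reports red (mCherry-type channel) with a low saturation
#' constant; responder B reports green (eGFP-type channel) with a much higher
#' saturation constant, so A activates at AI-2 levels below B's detection
#' limit and B keeps resolving doses after A saturates. The default constants
#' are the ones [fit_dose_response()] recovers from the packaged published
#' dose-response table (see [reproduce_reference_fixtures()]): `K_A` of about
#' 1.3 uM and `K_B` of about 43 uM.
#'
#' @param K_red,K_green Saturation constants (uM) for A and B.
#' @param growth_rate Common growth rate (per hour) for both populations.
#' @param shares Initial shares, default 1:1.
#' @return A `qs_coculture` with responders named `"A"` and `"B"`.
#' @export
coculture_ab <- function(K_red = 1.3, K_green = 43, growth_rate = 0.8,
                         shares = c(0.5, 0.5)) {
  coculture(
    list(
      responder("A", "red",
                dose_response(0, 1, K = K_red, n = 1), growth_rate),
      responder("B", "green",
                dose_response(0, 1, K = K_green, n = 1), growth_rate)
    ),
    shares = shares
  )
}

#' Activated share of the total coculture per responder
#'
#' In a mixed culture each responder can contribute at most its population
#' share: a 1:1 two-member mix with fully saturating signal activates 50% of
#' the total per member rather than 100%. Returns `share_i * f_i(S)` per
#' responder and dose.
#'
#' @param spec A [coculture()] specification.
#' @param S Numeric vector of AI-2 concentrations (uM).
#' @return A tibble with columns `name`, `colour`, `dose_uM`, `share`,
#'   `activation` (within-population fraction) and `activated_share`
#'   (share of the total population).
#' @export
coculture_fractions <- function(spec, S) {
  stopifnot(inherits(spec, "qs_coculture"))
  purrr::map2_dfr(spec$responders, spec$shares, function(r, w) {
    tibble::tibble(
      name = r$name, colour = r$colour, dose_uM = S,
      share = w,
      activation = activation_fraction(r$curve, S),
      activated_share = w * activation_fraction(r$curve, S)
    )
  })
}

#' Effective sensing range of a curve pair
#'
#' The interval(s) of signal concentration over which at least one curve sits
#' between 10% and 90% of its dynamic range. Pairing populations with shifted
#' saturation constants widens this range relative to either member alone.
#' Only monotone increasing curves are supported.
#'
#' @param pair A list with elements `red` and `green`, each a `qs_curve`
#'   (e.g. from [case_library()]).
#' @return A tibble of disjoint segments with columns `S_lo`, `S_hi` (uM).
#' @export
effective_range <- function(pair) {
  curves <- list(pair$red, pair$green)
  if (!all(vapply(curves, function(cv) identical(cv$shape, "monotone_up"),
                  logical(1)))) {
    rlang::abort("effective_range supports monotone_up curves only",
                 class = "qs_error_shape")
  }
  # quantile of the Hill term: S_q = K * (q/(1-q))^(1/n)
  bounds <- purrr::map_dfr(curves, function(cv) {
    tibble::tibble(S_lo = cv$K * (0.1 / 0.9)^(1 / cv$n),
                   S_hi = cv$K * (0.9 / 0.1)^(1 / cv$n))
  })
  bounds <- dplyr::arrange(bounds, .data$S_lo)
  merged <- bounds[1, ]
  for (i in seq_len(nrow(bounds))[-1]) {
    last <- nrow(merged)
    if (bounds$S_lo[i] <= merged$S_hi[last]) {
      merged$S_hi[last] <- max(merged$S_hi[last], bounds$S_hi[i])
    } else {
      merged <- dplyr::bind_rows(merged, bounds[i, ])
    }
  }
  merged
}
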