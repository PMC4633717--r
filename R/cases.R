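#' Library of hypothetical red/green response-pair cases
#'
#' Ten fixed, documented pairings of red and green dose-response curves that
#' span the qualitative design space of two-population reporters. Sweeping a
#' pair across signal concentrations and plotting red output against green
#' output yields a distinct phase-plane pattern per case, which is the basis of
#' colour-binned classification.
#'
#' The taxonomy (all `K` in uM; `f0 = 0` and `n = 1` unless stated):
#'
#' 1. identical monotone pair (`K = 5`, `fmax = 1` both)
#' 2. shifted amplitude (red `fmax = 1`, green `fmax = 0.5`, same `K = 5`)
#' 3. red up / green off (green constant 0)
#' 4. red up / green down (green starts fully on, decays with `K = 5`)
#' 5. red up / green band-pass (`K = 5`, `K2 = 50`)
#' 6. both band-pass, shifted (red `K = 2, K2 = 20`; green `K = 20, K2 = 200`)
#' 7. shifted-threshold monotone pair: `K_green = 10 * K_red` (`K_red = 2`),
#'    `fmax = 1` both — the configuration matching the package's A/B consortium,
#'    whose sweep occupies quadrants Q1, Q2 and Q4 only
#' 8. red constant-on / green up (`K = 5`)
#' 9. steep vs shallow at the same threshold (red `n = 4`, green `n = 1`,
#'    `K = 5`)
#' 10. shifted-threshold pair with unequal amplitude (red `K = 2, fmax = 1`;
#'     green `K = 20, fmax = 0.6`)
#'
#' @param case_id Integer in `1..10`.
#' @return A list with elements `red` and `green` (each a `qs_curve`) and
#'   attribute `case_id`.
#' @examples
#' pair <- case_library(7)
#' activation_fraction(pair$red, 2)    # half-saturated
#' activation_fraction(pair$green, 2)  # still near baseline
#' @export
case_library <- function(case_id) {
  if (!is.numeric(case_id) || length(case_id) != 1 || is.na(case_id) ||
      case_id != round(case_id) || case_id < 1 || case_id > 10) {
    rlang::abort("case_id must be an integer in 1..10",
                 class = "qs_error_case_id")
  }
  up <- function(K, fmax = 1, n = 1) dose_response(0, fmax, K, n, "monotone_up")
  pair <- switch(as.integer(case_id),
    list(red = up(5), green = up(5)),
    list(red = up(5), green = up(5, fmax = 0.5)),
    list(red = up(5),
         green = dose_response(0, 0, K = 1, shape = "constant")),
    list(red = up(5),
         green = dose_response(0, 1, K = 5, shape = "monotone_down")),
    list(red = up(5),
         green = dose_response(0, 1, K = 5, shape = "band_pass", K2 = 50)),
    list(red = dose_response(0, 1, K = 2, shape = "band_pass", K2 = 20),
         green = dose_response(0, 1, K = 20, shape = "band_pass", K2 = 200)),
    list(red = up(2), green = up(20)),
    list(red = dose_response(1, 1, K = 1, shape = "constant"), green = up(5)),
    list(red = up(5, n = 4), green = up(5)),
    list(red = up(2), green = up(20, fmax = 0.6))
  )
  attr(pair, "case_id") <- as.integer(case_id)
  pair
}
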