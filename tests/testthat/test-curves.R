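test_that("activation_fraction matches the closed Monod/Hill form", {
  crv <- dose_response(0, 0.9, K = 10, n = 1)
  expect_identical(activation_fraction(crv, 0), 0)
  expect_equal(activation_fraction(crv, 10), 0.45)
  expect_equal(activation_fraction(crv, 28), 0.9 * 28 / 38, tolerance = 1e-12)
  # saturates at fmax
  expect_equal(activation_fraction(crv, 1e9), 0.9, tolerance = 1e-6)
  # baseline shifts with f0
  crv2 <- dose_response(0.1, 0.8, K = 5)
  expect_equal(activation_fraction(crv2, 0), 0.1)
})

test_that("curves respect shape monotonicity and bounds over sampled grids", {
  S <- c(0, 10^seq(-3, 4, length.out = 200))
  shapes <- list(
    up = dose_response(0.05, 0.95, K = 7, n = 2),
    down = dose_response(0.1, 0.9, K = 3, shape = "monotone_down"),
    band = dose_response(0, 1, K = 2, shape = "band_pass", K2 = 40),
    const = dose_response(0.3, 0.3, K = 1, shape = "constant")
  )
  for (nm in names(shapes)) {
    f <- activation_fraction(shapes[[nm]], S)
    expect_true(all(f >= shapes[[nm]]$f0 - 1e-12), info = nm)
    expect_true(all(f <= shapes[[nm]]$fmax + 1e-12), info = nm)
  }
  expect_true(all(diff(activation_fraction(shapes$up, S)) >= -1e-12))
  expect_true(all(diff(activation_fraction(shapes$down, S)) <= 1e-12))
})

test_that("invalid curve parameters and negative doses are rejected", {
  expect_error(dose_response(0.5, 0.4), class = "qs_error_curve")
  expect_error(dose_response(0, 1, K = -1), class = "qs_error_curve")
  expect_error(dose_response(0, 1, K = 5, shape = "band_pass", K2 = 2),
               class = "qs_error_curve")
  expect_error(activation_fraction(dose_response(), -1),
               class = "qs_error_domain")
})

test_that("coculture activated shares are share-weighted activations", {
  # 1:1 mix of saturating responders splits the output 50/50
  mix <- coculture(list(
    responder("A", "red", monod_up(2)),
    responder("B", "green", monod_up(20))
  ))
  sat <- coculture_fractions(mix, 2e7)
  expect_equal(sat$activated_share, c(0.5, 0.5), tolerance = 1e-6)
  # zero signal with zero baseline gives all zeros
  z <- coculture_fractions(mix, 0)
  expect_identical(z$activated_share, c(0, 0))
  # arithmetic of the definition at uneven shares
  c2 <- coculture(list(
    responder("A", "red", dose_response(0.8, 0.8, shape = "constant")),
    responder("B", "green", dose_response(0.2, 0.2, shape = "constant"))
  ), shares = c(0.25, 0.75))
  got <- coculture_fractions(c2, 1)
  expect_equal(got$activated_share, c(0.25 * 0.8, 0.75 * 0.2))
  # each responder is capped by its share
  expect_true(all(got$activated_share <= got$share + 1e-12))
})

test_that("coculture shares must be a valid composition", {
  r <- list(responder("A", "red", monod_up(2)),
            responder("B", "green", monod_up(20)))
  expect_error(coculture(r, shares = c(0.6, 0.6)), class = "qs_error_curve")
  expect_error(coculture(r, shares = c(1)), class = "qs_error_curve")
})

test_that("effective range follows the Monod closed form and unions intervals", {
  # S10 = K/9, S90 = 9K for n = 1
  pair_same <- list(red = monod_up(10), green = monod_up(10))
  r1 <- effective_range(pair_same)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$S_lo, 10 / 9, tolerance = 1e-12)
  expect_equal(r1$S_hi, 90, tolerance = 1e-12)
  # shifted pair K_green = 10 K_red: overlapping union spans S10(red)..S90(green)
  pair7 <- list(red = monod_up(2), green = monod_up(20))
  r2 <- effective_range(pair7)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$S_lo, 2 / 9, tolerance = 1e-12)
  expect_equal(r2$S_hi, 180, tolerance = 1e-12)
  # the union is wider than either member alone
  expect_gt(r2$S_hi - r2$S_lo, 9 * 2 - 2 / 9)
  # far-apart thresholds yield two disjoint segments
  pair_far <- list(red = monod_up(0.01), green = monod_up(1000))
  r3 <- effective_range(pair_far)
  expect_equal(nrow(r3), 2)
  expect_lt(r3$S_hi[1], r3$S_lo[2])
  # non-monotone members are unsupported
  expect_error(
    effective_range(list(red = monod_up(1),
                         green = dose_response(0, 1, 2, shape = "band_pass",
                                               K2 = 20))),
    class = "qs_error_shape")
})
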