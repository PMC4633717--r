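test_that("deterministic binding limits behave exactly", {
  pop <- make_population(50, 50, n_off = 100)
  all_bind <- focus_config(bind_prob_activated = 1, bind_prob_nonspecific = 0)
  b <- bind_nanoparticles(pop, all_bind, seed = 1)
  expect_identical(b$bound, b$activated)
  none <- focus_config(bind_prob_activated = 0, bind_prob_nonspecific = 0)
  expect_false(any(bind_nanoparticles(pop, none, seed = 1)$bound))
})

test_that("binding counts follow the binomial model", {
  pop <- make_population(10000, 0)
  cfg <- focus_config(bind_prob_activated = 0.8, bind_prob_nonspecific = 0)
  b <- bind_nanoparticles(pop, cfg, seed = 2)
  expect_lt(abs(sum(b$bound) - 8000), 3 * sqrt(10000 * 0.8 * 0.2))
})

test_that("invalid focus configurations are rejected", {
  expect_error(focus_config(bind_prob_activated = 0.1,
                            bind_prob_nonspecific = 0.5),
               class = "qs_error_focus")
  expect_error(focus_config(capture_efficiency = 1.2), class = "qs_error_focus")
  expect_error(focus_config(distributed_area_um2 = 10, focal_area_um2 = 10),
               class = "qs_error_focus")
})

test_that("the sweep partitions the population exactly", {
  pop <- make_population(300, 200, n_off = 500)
  cfg <- focus_config(capture_efficiency = 0.7)
  b <- bind_nanoparticles(pop, cfg, seed = 3)
  sw <- magnetic_sweep(b, cfg, seed = 4)
  expect_equal(nrow(sw$captured) + nrow(sw$supernatant), nrow(pop))
  expect_setequal(c(sw$captured$cell_id, sw$supernatant$cell_id), pop$cell_id)
  # eta = 1 captures exactly the bound set; eta = 0 captures nothing
  one <- focus_config(capture_efficiency = 1)
  sw1 <- magnetic_sweep(b, one, seed = 5)
  expect_setequal(sw1$captured$cell_id, b$cell_id[b$bound])
  zero <- focus_config(capture_efficiency = 0)
  expect_equal(nrow(magnetic_sweep(b, zero, seed = 6)$captured), 0)
})

test_that("sweeping an unbound population is an error", {
  pop <- make_population(10, 10)
  pop$bound <- NULL
  expect_error(magnetic_sweep(pop, focus_config(), seed = 1),
               class = "qs_error_unbound")
})

test_that("captured cells are repositioned inside the focal disc", {
  pop <- make_population(500, 500)
  cfg <- focus_config(bind_prob_activated = 1, capture_efficiency = 1,
                      distributed_area_um2 = 1e4, focal_area_um2 = 100)
  sw <- magnetic_sweep(bind_nanoparticles(pop, cfg, seed = 7), cfg, seed = 8)
  r <- sqrt(sw$captured$x_um^2 + sw$captured$y_um^2)
  expect_true(all(r <= sqrt(100 / pi) + 1e-9))
})

test_that("capture is colour-blind: composition preserved in expectation", {
  cfg <- focus_config(bind_prob_nonspecific = 0)
  ratios <- vapply(1:60, function(s) {
    pop <- make_population(400, 200)
    b <- bind_nanoparticles(pop, cfg, seed = 100 + s)
    glance(magnetic_sweep(b, cfg, seed = 500 + s))$captured_green_red_ratio
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 0.5), 2 * se + 1e-12)
})

test_that("amplification follows the closed-form expectation", {
  expect_equal(expected_amplification(
    focus_config(bind_prob_activated = 1, capture_efficiency = 1,
                 distributed_area_um2 = 1e4, focal_area_um2 = 100)), 100)
  expect_equal(expected_amplification(
    focus_config(bind_prob_activated = 0.8, capture_efficiency = 0.5,
                 distributed_area_um2 = 1e4, focal_area_um2 = 100)), 40)
  expect_equal(amplification_factor(2, 50), 25)
  expect_true(is.na(amplification_factor(0, 5)))
})

test_that("amplification expectation is monotone in eta and area ratio", {
  base <- focus_config(capture_efficiency = 0.5, distributed_area_um2 = 1e4,
                       focal_area_um2 = 200)
  more_eta <- focus_config(capture_efficiency = 0.9,
                           distributed_area_um2 = 1e4, focal_area_um2 = 200)
  tighter <- focus_config(capture_efficiency = 0.5,
                          distributed_area_um2 = 1e4, focal_area_um2 = 50)
  expect_gt(expected_amplification(more_eta), expected_amplification(base))
  expect_gt(expected_amplification(tighter), expected_amplification(base))
})
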