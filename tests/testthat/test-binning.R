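test_that("quadrant classification follows the closed-upper tie rule", {
  rule <- quadrant_rule(1, 2)
  pts <- tibble::tibble(
    x = c(0, 2, 0.5, 1, 0.2, 3),
    y = c(0, 1, 4, 2, 0.1, 5)
  )
  got <- classify_point(pts, rule)
  expect_equal(got$quadrant, c("Q1", "Q2", "Q3", "Q4", "Q1", "Q4"))
  expect_equal(got$category,
               c("none", "red", "green", "red+green", "none", "red+green"))
  # boundary point lands in Q4 under >=
  expect_equal(classify_point(tibble::tibble(x = 1, y = 2), rule)$quadrant, "Q4")
})

test_that("every non-negative point receives exactly one quadrant", {
  rule <- quadrant_rule(0.3, 0.7)
  pts <- withr::with_seed(99, tibble::tibble(x = stats::rexp(2000),
                                             y = stats::rexp(2000)))
  got <- classify_point(pts, rule)
  expect_true(all(got$quadrant %in% c("Q1", "Q2", "Q3", "Q4")))
  expect_false(any(is.na(got$category)))
  # the four regions are mutually exclusive by re-derivation
  manual <- ifelse(pts$x >= 0.3,
                   ifelse(pts$y >= 0.7, "Q4", "Q2"),
                   ifelse(pts$y >= 0.7, "Q3", "Q1"))
  expect_identical(got$quadrant, manual)
})

test_that("unit mismatches between points and rule are rejected", {
  rule <- quadrant_rule(5, 5, unit = "count")
  pts <- tibble::tibble(x = 1, y = 1, unit = "fraction")
  expect_error(classify_point(pts, rule), class = "qs_error_unit")
  expect_error(classify_point(tibble::tibble(x = -1, y = 0), quadrant_rule(1)),
               class = "qs_error_rule")
})

test_that("the consortium-like shifted pair occupies exactly Q1, Q2 and Q4", {
  pair <- case_library(7)
  grid <- c(0, 10^seq(log10(0.01 * pair$red$K), log10(100 * pair$green$K),
                      length.out = 120))
  tr <- sweep_trajectory(pair, grid)
  expect_identical(occupied_quadrants(tr), c("Q1", "Q2", "Q4"))
  expect_identical(trajectory_signature(tr), "Q1>Q2>Q4")
})

test_that("identical curves sweep along the diagonal, never into Q3 or Q2", {
  tr <- sweep_trajectory(case_library(1), c(0, 10^seq(-2, 3, length.out = 60)))
  expect_equal(tr$x, tr$y, tolerance = 1e-12)
  expect_false(any(tr$quadrant %in% c("Q2", "Q3")))
})

test_that("a red-up/green-down pair starts in Q3", {
  tr <- sweep_trajectory(case_library(4), c(0, 0.1, 1, 5, 50, 500))
  expect_equal(tr$quadrant[1], "Q3")
  expect_match(trajectory_signature(tr), "^Q3")
})

test_that("the occupied set is invariant under grid permutation", {
  pair <- case_library(10)
  grid <- c(0, 10^seq(-2, 3, length.out = 50))
  occ1 <- occupied_quadrants(sweep_trajectory(pair, grid))
  occ2 <- occupied_quadrants(
    sweep_trajectory(pair, withr::with_seed(3, sample(grid))))
  expect_identical(occ1, occ2)
})

test_that("robustness scoring is 1 at zero width and degrades with range", {
  pair <- case_library(7)
  grid <- c(0, 10^seq(-2, 3, length.out = 40))
  expect_identical(robustness_score(pair, grid, rel_K = 0), 1)
  s10 <- robustness_score(pair, grid, rel_K = 0.1, n_draws = 200, seed = 5)
  s50 <- robustness_score(pair, grid, rel_K = 0.5, n_draws = 200, seed = 5)
  expect_gte(s10, s50)
  # a green threshold at the green asymptote (case 10: 0.5 * fmax = 0.3) is
  # fragile under fmax perturbation, unlike the default 5%-of-maximum rule
  pair10 <- case_library(10)
  asym <- quadrant_rule(0.025, 0.5 * pair10$green$fmax)
  s_asym <- robustness_score(pair10, grid, rule = asym, rel_K = 0.3,
                             rel_fmax = 0.3, n_draws = 200, seed = 6)
  s_def <- robustness_score(pair10, grid, rel_K = 0.3, rel_fmax = 0.3,
                            n_draws = 200, seed = 6)
  expect_lt(s_asym, s_def)
})

test_that("pattern rendering marks coincident points across cases", {
  # cases 1 and 9 share their saturated endpoint
  grid <- c(0, 1, 10, 1e5)
  pat <- render_pattern(c(1, 9), S_grid = grid, coincidence_tol = 1e-3)
  expect_gt(nrow(pat$coincidences), 0)
  expect_true(any(abs(pat$coincidences$x - 0.5) < 1e-3))
  # a single case never coincides with itself; empty input gives empty pattern
  expect_equal(nrow(render_pattern(7, S_grid = grid)$coincidences), 0)
  empty <- render_pattern(integer(0), S_grid = grid)
  expect_equal(nrow(empty$points), 0)
  expect_s3_class(autoplot(pat), "ggplot")
})
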