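blob <- function(nr, nc, at, value = 100) {
  m <- matrix(0, nr, nc)
  for (p in at) m[p[1], p[2]] <- value
  m
}

test_that("thresholded particle counting handles degenerate rasters", {
  expect_equal(nrow(threshold_and_count(matrix(0, 10, 10), threshold = 1)), 0)
  # two disjoint supra-threshold blobs within the size range
  m <- matrix(0, 20, 20)
  m[2:4, 2:4] <- 50
  m[12:15, 12:15] <- 80
  p <- threshold_and_count(m, threshold = 50, size_range = c(4, 100))
  expect_equal(nrow(p), 2)
  expect_setequal(p$area_px, c(9, 16))
  # pixels equal to the threshold are supra-threshold
  expect_equal(nrow(threshold_and_count(matrix(50, 3, 3), threshold = 50,
                                        size_range = c(1, 100))), 1)
})

test_that("connected components use 8-connectivity", {
  # two pixels touching only at a corner form one particle
  m <- blob(6, 6, list(c(2, 2), c(3, 3), c(4, 4)))
  p <- threshold_and_count(m, threshold = 50, size_range = c(1, 100))
  expect_equal(nrow(p), 1)
  expect_equal(p$area_px, 3)
})

test_that("size filtering excludes particles outside the range", {
  m <- matrix(0, 30, 30)
  m[2, 2] <- 99                 # single pixel, below min size
  m[10:20, 10:20] <- 99         # 121 px, above max size
  m[25:26, 25:27] <- 99         # 6 px, in range
  p <- threshold_and_count(m, threshold = 50, size_range = c(2, 50))
  expect_equal(nrow(p), 1)
  expect_equal(p$area_px, 6)
})

test_that("colour-ratio classification follows the epsilon-guarded rule", {
  r <- matrix(0, 12, 12); g <- matrix(0, 12, 12)
  g[2:4, 2:4] <- 200                   # pure green particle: red mean 0
  cls <- classify_particles(r, g, thresholds = c(50, 50), size_threshold = 4)
  expect_equal(nrow(cls), 1)
  expect_equal(cls$class, "green")
  # equal channel means are ambiguous at ratio threshold 2
  r2 <- g; cls2 <- classify_particles(r2, g, thresholds = c(50, 50),
                                      size_threshold = 4)
  expect_equal(cls2$class, "ambiguous")
  # sub-size components are labelled, not counted as colours
  r3 <- blob(12, 12, list(c(8, 8)), 200)
  cls3 <- classify_particles(r3, matrix(0, 12, 12), thresholds = c(50, 50),
                             size_threshold = 4)
  expect_equal(cls3$class, "sub_size")
  cnt <- particle_counts(cls3)
  expect_equal(cnt$n[cnt$class == "red"], 0)
  expect_equal(cnt$n[cnt$class == "sub_size"], 1)
})

test_that("class counts are invariant under raster translation", {
  # cells confined to a sub-region so the shift never clips content; the
  # crowded sub-field legitimately warns about overlapping placements
  cells <- suppressWarnings(place_cells(20, 20, field_um = 12.8, seed = 21))
  fld <- render_field(cells, field_um = 25.6, seed = 22)
  shift <- function(m, by) {
    out <- matrix(fld$optics$background, nrow(m), ncol(m))
    out[(1 + by):nrow(m), (1 + by):ncol(m)] <-
      m[1:(nrow(m) - by), 1:(ncol(m) - by)]
    out
  }
  thr <- c(1000, 1000)
  c0 <- particle_counts(classify_particles(fld$red, fld$green, thr))
  c1 <- particle_counts(classify_particles(shift(fld$red, 7),
                                           shift(fld$green, 7), thr))
  expect_equal(c0, c1)
})

test_that("colocalization fraction matches footprint overlap", {
  m <- matrix(0, 20, 20)
  m[3:6, 3:6] <- 100
  m[12:15, 12:15] <- 100
  p <- threshold_and_count(m, threshold = 50, size_range = c(4, 100))
  # identical channels: every particle colocalized
  expect_equal(colocalization_fraction(p, m, probe_threshold = 50)$f_c, 1)
  # disjoint probe: none
  probe <- matrix(0, 20, 20); probe[18:19, 1:2] <- 100
  expect_equal(colocalization_fraction(p, probe, probe_threshold = 50)$f_c, 0)
  # probe over one of two particles: 0.5
  half <- matrix(0, 20, 20); half[3:6, 3:6] <- 100
  expect_equal(colocalization_fraction(p, half, probe_threshold = 50)$f_c, 0.5)
  # empty primary set: no-data marker, not zero
  p0 <- threshold_and_count(matrix(0, 20, 20), threshold = 50)
  res <- colocalization_fraction(p0, m, probe_threshold = 50)
  expect_true(is.na(res$f_c))
  expect_error(colocalization_fraction(p, matrix(0, 5, 5), 50),
               class = "qs_error_geometry")
})

test_that("labelled ground truth recovers the expected colocalized fraction", {
  # 70% of red cells also probe-labelled: f_c near 0.7
  set.seed(31)
  cells <- place_cells(100, 0, field_um = 51.2, seed = 31)
  fld <- render_field(cells, field_um = 51.2, seed = 32)
  labelled <- withr::with_seed(33, stats::runif(100) < 0.7)
  probe_cells <- cells[labelled, , drop = FALSE]
  probe_fld <- render_field(probe_cells, field_um = 51.2, seed = 34)
  prim <- threshold_and_count(fld$red, threshold = 1000)
  res <- colocalization_fraction(prim, probe_fld$red, probe_threshold = 1000)
  expect_equal(res$f_c, mean(labelled), tolerance = 3 * sqrt(0.7 * 0.3 / 100) / 0.7)
})

test_that("spatial density is the supra-threshold area percentage", {
  expect_equal(spatial_density(matrix(0, 10, 10), threshold = 1), 0)
  half <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  expect_equal(spatial_density(half, threshold = 10), 50)
  # rendered field: density within 10% relative of rasterised ground truth
  cells <- place_cells(50, 0, field_um = 51.2, seed = 41)
  fld <- render_field(cells, field_um = 51.2, seed = 42)
  truth_px <- sum(vapply(seq_len(nrow(cells)), function(i) {
    sum(qsconsort:::rasterise_ellipse(512, 0.1, cells$x_um[i], cells$y_um[i],
                                      cells$length_um[i] / 2,
                                      cells$width_um[i] / 2, cells$theta[i]))
  }, numeric(1)))
  truth_density <- 100 * truth_px / 512^2
  # half-amplitude threshold: a blurred step edge crosses amplitude/2 at the
  # true object boundary, so the supra-threshold area tracks the raster truth
  half_amp <- fld$optics$amplitude / 2
  expect_equal(spatial_density(fld$red, threshold = half_amp), truth_density,
               tolerance = 0.1)
})

test_that("line profiles report ordered mean grey values", {
  m <- matrix(7, 5, 9)
  prof <- line_profile(m, row = 2)
  expect_equal(prof$value, rep(7, 9))
  expect_equal(prof$position_px, 0:8)
  expect_error(line_profile(m, row = 5), class = "qs_error_geometry")
  # single bright cell: profile peak at the centroid column in both channels
  cells <- place_cells(1, 0, field_um = 12.8, seed = 51)
  cells$colour <- "red"
  fld <- render_field(cells, field_um = 12.8, seed = 52)
  rowpx <- round(cells$y_um / 0.1 - 0.5)
  prof2 <- line_profile(fld$red, row = rowpx, halfwidth = 2)
  expect_lt(abs(prof2$position_px[which.max(prof2$value)] -
                  fld$ground_truth$centroid_x_px), 2)
})

test_that("counting and classification recover rendered ground truth", {
  cells <- place_cells(50, 50, field_um = 51.2, seed = 61)
  fld <- render_field(cells, field_um = 51.2, seed = 62)
  m <- match_ground_truth(threshold_and_count(fld$red), fld, colour = "red")
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  cls <- classify_particles(fld$red, fld$green)
  keep <- dplyr::filter(cls, class != "sub_size")
  mm <- match_ground_truth(keep, fld)
  expect_gte(mm$recall, 0.95)
  expect_gte(mm$colour_accuracy, 0.95)
})
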