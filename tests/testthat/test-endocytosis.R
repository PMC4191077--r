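small_pair <- function(seed, n_cells = 10, intensity = 50, ...) {
  generate_image_pair(n_cells = n_cells, width = 192, height = 192,
                      green_intensity_mean = intensity, seed = seed, ...)
}

test_that("the generator is deterministic and honors edge cases", {
  p1 <- small_pair(3)
  p2 <- small_pair(3)
  expect_identical(p1, p2)
  blank <- generate_image_pair(n_cells = 0, width = 64, height = 64,
                               noise_sd = 0, seed = 1)
  expect_equal(max(blank$nuclear), min(blank$nuclear))
  expect_error(generate_image_pair(n_cells = 500, width = 96, height = 96,
                                   seed = 1, max_tries = 50),
               "non-overlapping")
})

test_that("segmentation counts match generator truth over many seeds", {
  for (seed in 1:100) {
    p <- small_pair(seed)
    expect_equal(segment_nuclei(p$nuclear)$count, 10)
  }
})

test_that("segmentation is invariant to intensity scaling and handles flat images", {
  p <- small_pair(5)
  s1 <- segment_nuclei(p$nuclear)
  s2 <- segment_nuclei(p$nuclear * 2)
  expect_identical(s1$labels, s2$labels)
  flat <- segment_nuclei(matrix(0, 32, 32))
  expect_equal(flat$count, 0)
  expect_true(all(flat$labels == 0))
  const <- segment_nuclei(matrix(7, 32, 32))
  expect_equal(const$count, 0)
})

test_that("per-cell measurement recovers known intensities and floors at zero", {
  p <- small_pair(8, intensity = 50, noise_sd = 2) # SNR 25
  seg <- segment_nuclei(p$nuclear)
  m <- measure_cells(p, seg$labels, dilation_radius_px = 8,
                     background_AU = 5)
  expect_equal(m$cell_count, 10)
  expect_lt(abs(m$mean_corrected_AU - 50) / 50, 0.05)

  uniform <- p
  uniform$green <- matrix(5, 192, 192)
  mu <- measure_cells(uniform, seg$labels, 8, background_AU = 5)
  expect_true(all(mu$per_cell$corrected_AU == 0))

  m2 <- measure_cells(p, seg$labels, 8, background_AU = 15)
  expect_equal(m$per_cell$mean_AU - 5, m$per_cell$corrected_AU,
               tolerance = 1e-12)
  expect_equal(m$per_cell$mean_AU - m2$per_cell$mean_AU,
               rep(0, 10)) # raw means unchanged by background choice
  expect_equal(pmax(m$per_cell$mean_AU - 15, 0), m2$per_cell$corrected_AU)

  bad <- matrix(0L, 10, 10)
  expect_error(measure_cells(p, bad, 8, 0), "shape")
})

test_that("background estimation averages cell-region green signal of controls", {
  mk_ctrl <- function(level, seed) {
    p <- small_pair(seed, intensity = 0, noise_sd = 0, background_AU = level)
    p
  }
  expect_equal(estimate_background(list(mk_ctrl(7, 1))), 7, tolerance = 1e-9)
  expect_equal(estimate_background(list(mk_ctrl(5, 1), mk_ctrl(9, 2))), 7,
               tolerance = 1e-9)
  expect_equal(estimate_background(list(mk_ctrl(0, 3))), 0, tolerance = 1e-9)
  empty <- list(nuclear = matrix(0, 48, 48), green = matrix(4, 48, 48))
  expect_warning(bg <- estimate_background(list(empty)), "whole-image")
  expect_equal(as.numeric(bg), 4)
})

test_that("sample summaries pool cells and are order invariant", {
  pairs <- lapply(1:20, function(i) small_pair(100))
  one <- summarize_sample(pairs[1], background_AU = 5)
  many <- summarize_sample(pairs, background_AU = 5)
  expect_equal(many$mean_corrected_AU, one$mean_corrected_AU)
  expect_equal(many$n_cells, 20 * one$n_cells)

  mixed <- lapply(c(101, 102, 103), small_pair)
  s1 <- summarize_sample(mixed, background_AU = 5)
  s2 <- summarize_sample(rev(mixed), background_AU = 5)
  expect_equal(s1$mean_corrected_AU, s2$mean_corrected_AU)
  expect_equal(s1$n_cells, s2$n_cells)
})

test_that("stimulated and control conditions separate as expected", {
  # no-probe controls carry faint cell-associated autofluorescence (5 AU over
  # a 5 AU background); the stimulated sample carries strong probe signal.
  controls <- lapply(1:3, function(i) small_pair(200 + i, intensity = 5,
                                                noise_sd = 1))
  stim <- lapply(1:5, function(i) small_pair(300 + i, intensity = 55,
                                             noise_sd = 1))
  bg <- estimate_background(controls)
  expect_equal(bg, 10, tolerance = 0.05)
  s_stim <- summarize_sample(stim, background_AU = bg)
  s_ctrl <- summarize_sample(controls, background_AU = bg)
  expect_equal(s_stim$mean_corrected_AU, 50, tolerance = 0.05 * 50)
  expect_lt(s_ctrl$mean_corrected_AU, 1)
})

test_that("zero-probe samples summarize to zero corrected intensity", {
  pairs <- lapply(1:3, function(i) small_pair(400 + i, intensity = 0,
                                              noise_sd = 0))
  bg <- estimate_background(pairs)
  s <- summarize_sample(pairs, background_AU = bg)
  expect_equal(s$mean_corrected_AU, 0, tolerance = 1e-9)
})
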