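# Rendering, segmentation and spot counting.

test_that("rendered images are deterministic with truth independent of noise", {
  i1 <- render_foci_image(c(4, 6), image_params(snr = 8), seed = 9)
  i2 <- render_foci_image(c(4, 6), image_params(snr = 8), seed = 9)
  expect_identical(i1$red, i2$red)
  clean <- render_foci_image(c(4, 6), image_params(snr = Inf), seed = 9)
  expect_identical(clean$truth, i1$truth)
  expect_equal(nrow(clean$truth), 10L)
})

test_that("every rendered focus lies inside its parent nucleus", {
  img <- render_foci_image(c(5, 8, 3, 7), image_params(), seed = 10)
  for (r in seq_len(nrow(img$truth))) {
    e <- img$nuclei[img$nuclei$id == img$truth$nucleus_id[r], ]
    dx <- img$truth$x_px[r] - e$cx; dy <- img$truth$y_px[r] - e$cy
    xr <- dx * cos(e$phi) + dy * sin(e$phi)
    yr <- -dx * sin(e$phi) + dy * cos(e$phi)
    expect_lte((xr / e$a)^2 + (yr / e$b)^2, 0.8^2 + 1e-9)
  }
})

test_that("overcrowded nuclei and canvases fail with actionable errors", {
  expect_error(render_foci_image(rep(3, 60),
                                 image_params(width_px = 96, height_px = 96),
                                 seed = 1), "non-overlapping")
  expect_error(render_foci_image(200, image_params(), seed = 1),
               "minimum")
})

test_that("segmentation finds exactly the rendered nuclei and is
           deterministic; blank images yield zero nuclei", {
  img <- render_foci_image(rep(3, 8), image_params(width_px = 384,
                                                   height_px = 384), seed = 12)
  s1 <- segment_nuclei(img$dapi)
  expect_equal(nrow(s1$table), 8L)
  expect_equal(sort(unique(as.vector(s1$label_mask))), 0:8)
  s2 <- segment_nuclei(img$dapi)
  expect_identical(s1$label_mask, s2$label_mask)
  blank <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(nrow(blank$table), 0L)
  expect_warning(segment_nuclei(matrix(1, 64, 64)), "saturated")
})

test_that("noise-free end-to-end counting is exact for every nucleus", {
  counts <- c(5, 7, 0, 3, 9, 6)
  img <- render_foci_image(counts, image_params(), seed = 2)
  seg <- segment_nuclei(img$dapi)
  expect_equal(nrow(seg$table), length(counts))
  calls <- count_foci(img$red, seg)
  map <- match_nuclei(seg, img)   # segmented label -> generator nucleus id
  expect_equal(calls$table$n_foci, counts[map])
  # intensity-scale invariance
  half <- count_foci(img$red * 0.5, seg)
  dbl <- count_foci(img$red * 2, seg)
  expect_identical(calls$table$n_foci, half$table$n_foci)
  expect_identical(calls$table$n_foci, dbl$table$n_foci)
  expect_error(count_foci(img$red[1:50, 1:50], seg), "shapes differ")
})

test_that("two foci closer than the merge distance count as one", {
  # build a synthetic red channel directly: two Gaussians 2 px apart inside
  # one rendered nucleus
  img <- render_foci_image(0, image_params(), seed = 3)
  seg <- segment_nuclei(img$dapi)
  cx <- seg$table$cx[1]; cy <- seg$table$cy[1]
  xg <- matrix(rep(seq_len(nrow(img$red)), ncol(img$red)), nrow(img$red))
  yg <- matrix(rep(seq_len(ncol(img$red)), each = nrow(img$red)), nrow(img$red))
  spot <- function(x0, y0) exp(-((xg - x0)^2 + (yg - y0)^2) / (2 * 1.5^2))
  near <- spot(cx - 1, cy) + spot(cx + 1, cy)
  expect_equal(sum(count_foci(near, seg)$table$n_foci), 1L)
  farr <- spot(cx - 4, cy) + spot(cx + 4, cy)
  expect_equal(sum(count_foci(farr, seg)$table$n_foci), 2L)
})

test_that("detection benchmark reports ideal and degenerate cases correctly", {
  truth <- data.frame(nucleus_id = 1, x_px = c(10, 30, 50), y_px = c(10, 30, 50))
  perfect <- data.frame(nucleus_id = 1, x_px = c(10, 30, 50),
                        y_px = c(10, 30, 50))
  bm <- detection_benchmark(truth, perfect)
  expect_equal(bm$precision, 1); expect_equal(bm$recall, 1)
  none <- detection_benchmark(truth, truth[0, ])
  expect_equal(none$recall, 0)
  shifted <- perfect; shifted$x_px <- shifted$x_px + 30
  bm2 <- detection_benchmark(truth, shifted, match_radius_px = 3)
  expect_lt(bm2$precision, 0.5)
})

test_that("precision and recall stay above 0.9 at SNR >= 5 on a seeded set", {
  P <- c(); R <- c()
  for (s in 1:6) {
    set.seed(s)
    img <- render_foci_image(pmin(rpois(8, 5) + 1, 8),
                             image_params(width_px = 384, height_px = 384,
                                          snr = 5), seed = 20 + s)
    seg <- segment_nuclei(img$dapi)
    calls <- count_foci(img$red, seg)
    bm <- detection_benchmark(img$truth, calls, match_radius_px = 3)
    P <- c(P, bm$precision); R <- c(R, bm$recall)
  }
  expect_gte(mean(P), 0.9)
  expect_gte(mean(R), 0.9)
})
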