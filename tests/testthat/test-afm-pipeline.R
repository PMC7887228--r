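test_that("flattening removes row offsets, tilt and mean", {
  set.seed(2)
  n <- 64
  base <- matrix(0, n, n)
  base[30:34, 10:50] <- 1.5                       # a molecule-like stripe
  offsets <- rnorm(n, sd = 0.5)
  tilt <- outer(rep(1, n), seq(0, 3, length.out = n))
  img <- topograph(base + offsets + tilt, 1)
  fl <- flatten_topograph(img)
  ## residual row-median spread vanishes
  expect_lt(diff(range(apply(fl$heights, 1, median))), 1e-6)
  expect_lt(abs(mean(fl$heights)), 1e-9)

  ## a pure tilted plane flattens to zero everywhere
  plane <- topograph(outer(seq(0, 2, length.out = n),
                           seq(0, 5, length.out = n), "+"), 1)
  expect_lt(max(abs(flatten_topograph(plane)$heights)), 1e-6)

  ## idempotence
  fl2 <- flatten_topograph(fl)
  expect_equal(fl2$heights, fl$heights, tolerance = 1e-9)

  expect_error(flatten_topograph(topograph(matrix(0, 4, 4), 1)), "8 x 8")
})

test_that("Gaussian smoothing has the right impulse response and mean", {
  n <- 65
  spike <- matrix(0, n, n); spike[33, 33] <- 1
  sm <- smooth_topograph(topograph(spike, 1), sigma_px = 1.5,
                         truncate_px = 3.5)
  h <- sm$heights
  ## fitted sigma from the second moment of the response
  ## neighbour-ratio estimate of sigma: exact for a sampled Gaussian and
  ## insensitive to the kernel truncation
  sigma_est <- sqrt(-0.5 / log(h[33, 34] / h[33, 33]))
  expect_equal(sigma_est, 1.5, tolerance = 0.02 * 1.5)
  expect_equal(mean(h) * n * n, 1, tolerance = 1e-6)   # mass preserved

  const <- topograph(matrix(3.3, 32, 32), 1)
  expect_equal(smooth_topograph(const)$heights, const$heights,
               tolerance = 1e-12)

  ## equality with the dense direct-convolution oracle on a noise field
  set.seed(9)
  m <- matrix(rnorm(24 * 20), 24, 20)
  got <- smooth_topograph(topograph(m, 1), 1.5, 3.5)$heights
  want <- convolve_dense(m, 1.5, 3.5)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("masking is monotone in the threshold and labels components", {
  curves <- plant_molecules(6, 256, seed = 11)
  img <- render_afm_image(curves, pixel_size = 2, n_px = 128,
                          noise_sd = 0.08, seed = 11)
  sm <- smooth_topograph(flatten_topograph(img))
  n1 <- attr(mask_and_label(sm, sigma_mult = 1), "n_grains")
  n3 <- attr(mask_and_label(sm, sigma_mult = 3), "n_grains")
  expect_lte(n3, n1)

  ## blank image: pure noise components exist but the area filters kill them
  set.seed(42)
  blank <- topograph(matrix(rnorm(128 * 128, sd = 0.05), 128, 128), 2)
  labb <- mask_and_label(blank)
  expect_gt(attr(labb, "n_grains"), 0)
  expect_equal(attr(filter_grains(labb), "n_grains"), 0)

  ## an empty mask is not an error
  flat0 <- topograph(matrix(0, 32, 32), 1)
  expect_equal(max(mask_and_label(flat0)), 0)
})

test_that("8-connectivity joins diagonals, 4-connectivity does not", {
  m <- matrix(0, 16, 16)
  m[4, 4] <- 1; m[5, 5] <- 1                       # diagonal pair
  t8 <- topograph(m, 1)
  expect_equal(attr(mask_and_label(t8, sigma_mult = 1, connectivity = 8),
                    "n_grains"), 1)
  expect_equal(attr(mask_and_label(t8, sigma_mult = 1, connectivity = 4),
                    "n_grains"), 2)
})

test_that("grain filtering applies border, area floor and median band in order", {
  psz <- 2
  lab <- matrix(0L, 100, 100)
  ## normal grains ~ 400 nm2 (10x10 px)
  lab[10:19, 10:19] <- 1L
  lab[10:19, 40:49] <- 2L
  lab[40:49, 10:19] <- 3L
  ## small decoy: 6x6 px = 144 nm2 < 200
  lab[70:75, 70:75] <- 4L
  ## oversized decoy: 20x30 px = 2400 nm2, outside 150% of median
  lab[60:79, 30:59] <- 5L
  ## border-touching grain
  lab[1:10, 80:89] <- 6L
  attr(lab, "pixel_size") <- psz
  out <- filter_grains(lab, pixel_size = psz)
  expect_equal(attr(out, "n_grains"), 3)
  removed <- attr(out, "removed")
  expect_equal(sort(removed$id), c(4L, 5L, 6L))
  expect_equal(removed$reason[removed$id == 4], "min_area")
  expect_equal(removed$reason[removed$id == 5], "median_band")
  expect_equal(removed$reason[removed$id == 6], "border")

  ## grain at 40% of the median area is removed by the band filter
  lab2 <- matrix(0L, 100, 100)
  lab2[10:19, 10:19] <- 1L                        # 400 nm2
  lab2[40:49, 40:49] <- 2L                        # 400 nm2
  lab2[70:77, 70:77] <- 3L                        # 256 nm2 = 64% of median
  lab2[30:37, 70:74] <- 4L                        # 160 nm2: under the floor
  attr(lab2, "pixel_size") <- psz
  out2 <- filter_grains(lab2, pixel_size = psz)
  expect_equal(attr(out2, "n_grains"), 3)         # 64% is inside 50-150%
  lab3 <- lab2
  lab3[70:77, 70:77] <- 0L
  lab3[70:75, 70:71] <- 3L                        # 48 nm2 -> floor removes it
  attr(lab3, "pixel_size") <- psz
  out3 <- filter_grains(lab3, pixel_size = psz)
  expect_equal(sort(attr(out3, "removed")$id), c(3L, 4L))

  ## raising the area floor never increases the grain count
  counts <- vapply(c(100, 200, 300, 420), function(a)
    attr(filter_grains(lab, pixel_size = psz, min_area_nm2 = a), "n_grains"),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("grain morphometrics recover planted disc and ellipse shapes", {
  psz <- 2
  mk <- function(curve) {
    img <- render_afm_image(list(curve), pixel_size = psz, n_px = 128,
                            noise_sd = 0.03, seed = 13)
    sm <- smooth_topograph(flatten_topograph(img))
    grain_stats(filter_grains(mask_and_label(sm)), sm)
  }
  gdisc <- mk(circle_xy(128, 128, 20))
  expect_equal(nrow(gdisc), 1)
  expect_equal(gdisc$aspect_ratio, 1, tolerance = 0.05)
  expect_equal(gdisc$longest_axis, 42, tolerance = 6)   # 2r + tube width

  gell <- mk(ellipse_xy(128, 128, 40, 20))
  expect_lt(abs(gell$aspect_ratio - 0.5), 0.1)

  ## relaxed open rings have higher aspect ratio than compact ellipses
  expect_gt(gdisc$aspect_ratio, gell$aspect_ratio)
})

test_that("crops are centred, clipped crops are flagged", {
  curves <- list(circle_xy(100, 100, 15), circle_xy(230, 230, 15))
  img <- render_afm_image(curves, pixel_size = 2, n_px = 128,
                          noise_sd = 0.03, seed = 17)
  sm <- smooth_topograph(flatten_topograph(img))
  gs <- grain_stats(filter_grains(mask_and_label(sm), median_band = NULL,
                                  remove_border = FALSE), sm)
  crops <- crop_grains(sm, gs, crop_nm = 80)
  expect_length(crops, 2)
  central <- crops[[which(gs$centroid_x < 128)]]
  expect_equal(dim(central$heights), c(40, 40))        # 80 nm at 2 nm/px
  expect_false(central$metadata$clipped)
  edge <- crops[[which(gs$centroid_x > 128)]]
  expect_true(edge$metadata$clipped)

  expect_length(crop_grains(sm, gs[0, ], 80), 0)
})

test_that("tracing recovers closed circumference, hairpin angle and straightness", {
  ## closed minicircle of known circumference
  cur <- circle_xy(64, 64, 108 / (2 * pi))
  img <- render_afm_image(list(cur), pixel_size = 1, n_px = 128,
                          noise_sd = 0.04, seed = 19)
  sm <- smooth_topograph(flatten_topograph(img))
  tr <- trace_molecule(sm)
  expect_true(tr$closed)
  expect_equal(tr$length_nm, 108, tolerance = 5 / 108)

  ## hairpin with a 110-degree directional change between two 45-nm arms
  arm <- 45
  turn <- 110 * pi / 180
  p1 <- cbind(seq(15, 15 + arm, length.out = 60), 40, 0)
  p2 <- cbind(15 + arm + seq(0, arm, length.out = 60) * cos(turn),
              40 + seq(0, arm, length.out = 60) * sin(turn), 0)
  hp <- closed_curve(rbind(p1, p2[-1, ]), closed = FALSE)
  img2 <- render_afm_image(list(hp), pixel_size = 1, n_px = 110,
                           noise_sd = 0.02, seed = 23)
  tr2 <- trace_molecule(smooth_topograph(flatten_topograph(img2)))
  expect_false(tr2$closed)
  big <- unname(tr2$angles[tr2$angles > 30])
  expect_length(big, 1)
  expect_equal(big, 110, tolerance = 10 / 110)

  ## straight rod: no angles above 10 degrees
  rod <- closed_curve(cbind(seq(15, 85, length.out = 60), 50, 0),
                      closed = FALSE)
  img3 <- render_afm_image(list(rod), pixel_size = 1, n_px = 100,
                           noise_sd = 0.02, seed = 29)
  tr3 <- trace_molecule(smooth_topograph(flatten_topograph(img3)))
  expect_true(all(tr3$angles <= 10))
})

test_that("branched (self-crossing) projections raise a trace error", {
  cross1 <- closed_curve(cbind(seq(20, 80, length.out = 50), 50, 0),
                         closed = FALSE)
  cross2 <- closed_curve(cbind(50, seq(20, 80, length.out = 50), 0),
                         closed = FALSE)
  img <- render_afm_image(list(cross1, cross2), pixel_size = 1, n_px = 100,
                          noise_sd = 0, seed = 31)
  expect_error(trace_molecule(img), "branched skeleton")
})

test_that("protrusions are localized, with circular wrap-around", {
  ## open trace: heights stepped up over a contiguous third
  cur <- circle_xy(64, 64, 108 / (2 * pi))
  img <- render_afm_image(list(cur), pixel_size = 1, n_px = 128,
                          noise_sd = 0.03, seed = 37)
  sm <- smooth_topograph(flatten_topograph(img))
  tr <- trace_molecule(sm)

  ## uniform-height trace: nothing to find
  expect_null(locate_protrusion(tr, 0.4))

  ## plant a synthetic protrusion on the height profile, wrapping the origin
  np <- length(tr$heights)
  idx <- c((np - 9):np, 1:15)                       # 25 points across origin
  tr2 <- tr
  tr2$heights[idx] <- tr2$heights[idx] + 1
  pr <- locate_protrusion(tr2, 0.5)
  expect_false(is.null(pr))
  expect_equal(pr$length_frac, length(idx) / np, tolerance = 0.1)
  expect_gt(pr$start_frac, 0.8)                     # starts before the origin
})
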