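test_that("bend profiles on circles match the analytic value everywhere", {
  ## on an n-point circle, tangents separated by k points differ by 360 k/n
  for (case in list(c(360, 16), c(339, 16), c(200, 10))) {
    n <- case[1]; sep <- case[2]
    prof <- bend_profile(make_planar_circle(n, 10), sep)
    expect_length(prof$angles, n)
    expect_equal(prof$angles, rep(360 * sep / n, n), tolerance = 1e-9)
  }
  ## the 339-bp minicircle value quoted everywhere in the bending analysis
  prof <- bend_profile(make_planar_circle(339, 18.35), 16)
  expect_equal(prof$angles[1], 16.99, tolerance = 0.01)
})

test_that("bend profile of a straight open segment is zero in the interior", {
  line <- closed_curve(cbind(seq(0, 50, length.out = 60), 0, 0),
                       closed = FALSE)
  prof <- bend_profile(line, 16)
  expect_true(all(abs(prof$angles) < 1e-9))
})

test_that("bend profile reports degenerate (repeated) points by index", {
  pts <- make_planar_circle(50, 5)$points
  pts[10, ] <- pts[9, ]
  expect_error(bend_profile(structure(list(points = pts, closed = TRUE,
                                           labels = NULL),
                                      class = "closed_curve"), 16),
               "repeated point at index 8")
})

test_that("feature finding merges runs and ignores flat profiles", {
  flat <- bend_profile(make_planar_circle(339, 18.35), 16)  # all 17 degrees
  expect_equal(nrow(find_bend_features(flat, 35)), 0)
  expect_error(find_bend_features(flat, 0), "peak_threshold")

  ## two nearby runs separated by less than sep/2 merge into one feature
  prof <- structure(list(angles = c(rep(10, 50), rep(40, 5), rep(10, 3),
                                    rep(50, 5), rep(10, 37)),
                         separation_bp = 16L, n = 100L, closed = TRUE),
                    class = "bend_profile")
  feats <- find_bend_features(prof, 35)
  expect_equal(nrow(feats), 1)
  expect_equal(feats$angle, 50)
})

test_that("classification by angle uses the 75-degree defect cutoff", {
  feats <- structure(
    data.frame(position = c(10L, 60L), angle = c(106, 69),
               span_start = c(5L, 55L), span_length = c(10L, 10L),
               klass = NA_character_, evidence = NA_character_),
    class = c("bend_features", "data.frame"))
  attr(feats, "n") <- 100L
  out <- classify_bend_features(feats, "angle_only")
  expect_equal(out$klass, c("defect", "b_bend"))

  ## monotone: raising the cutoff never converts a b_bend into a defect
  for (cut in c(40, 60, 75, 90, 110, 130)) {
    lo <- classify_bend_features(feats, "angle_only", defect_cutoff = cut)
    hi <- classify_bend_features(feats, "angle_only", defect_cutoff = cut + 10)
    expect_true(all(!(lo$klass == "b_bend" & hi$klass == "defect")))
  }
})

test_that("classification by interactions needs spans and uses overlap only", {
  feats <- structure(
    data.frame(position = 10L, angle = 120, span_start = 5L,
               span_length = 10L, klass = NA_character_,
               evidence = NA_character_),
    class = c("bend_features", "data.frame"))
  attr(feats, "n") <- 100L
  expect_error(classify_bend_features(feats, "interactions"), "defect_spans")

  ## a 120-degree bend with no overlapping broken span stays a B-DNA bend
  out <- classify_bend_features(feats, "interactions",
                                defect_spans = list(c(40L, 3L)))
  expect_equal(out$klass, "b_bend")
  out2 <- classify_bend_features(feats, "interactions",
                                 defect_spans = list(c(12L, 2L)))
  expect_equal(out2$klass, "defect")
  expect_equal(out2$evidence, "broken_interactions")
})

test_that("writhe obeys chirality, scaling and refinement convergence", {
  sol <- make_supercoiled_curve(400, 3, 3, 12)
  w <- writhe(sol)
  mirrored <- closed_curve(sol$points %*% diag(c(1, 1, -1)))
  expect_equal(writhe(mirrored), -w, tolerance = 1e-9)
  scaled <- closed_curve(sol$points * 7.3)
  expect_equal(writhe(scaled), w, tolerance = 1e-9)

  ## doubling the sampling changes the estimate by < 0.01 (smooth curve)
  w2 <- writhe(make_supercoiled_curve(800, 3, 3, 12))
  expect_lt(abs(w - w2), 0.01)

  expect_error(writhe(closed_curve(cbind(1:20, 0:19, 0), closed = FALSE)),
               "closed")
})

test_that("writhe matches the midpoint-quadrature oracle on a solenoid", {
  sol <- make_supercoiled_curve(500, 4, 3, 12)
  dense <- make_supercoiled_curve(2000, 4, 3, 12)
  expect_equal(writhe(sol), writhe_quadrature(dense$points), tolerance = 0.02)
})

test_that("twist, writhe and linking number partition correctly", {
  ## planar circle with normals winding 24 times: Tw=24, Wr=0, Lk=24
  n <- 200
  circ <- make_planar_circle(n, 11)
  th <- 2 * pi * (seq_len(n) - 1) / n
  zhat <- matrix(c(0, 0, 1), n, 3, byrow = TRUE)
  ## in-plane direction orthogonal to the discrete (segment) tangents
  tang <- circ$points[c(2:n, 1), ] - circ$points
  tang <- tang / sqrt(rowSums(tang^2))
  radial <- cbind(tang[, 2], -tang[, 1], 0)
  ## wind the normal 24 times in the positive-twist sense
  normals <- cos(24 * th) * zhat - sin(24 * th) * radial
  rib <- ribbon_frames(circ, normals)
  tl <- twist_and_link(rib)
  expect_equal(unname(tl["tw"]), 24, tolerance = 1e-9)
  expect_equal(unname(tl["wr"]), 0, tolerance = 1e-9)
  expect_equal(unname(tl["lk"]), 24, tolerance = 1e-9)

  ## untwisted planar ribbon
  tl0 <- twist_and_link(ribbon_frames(circ, zhat))
  expect_equal(unname(tl0), c(0, 0, 0), tolerance = 1e-9)

  ## prescribed linking number on a writhed axis: Tw = Lk - Wr
  sol <- make_supercoiled_curve(400, 3, 3, 12)
  rib30 <- make_ribbon(sol, 30)
  tl30 <- twist_and_link(rib30)
  expect_equal(unname(tl30["lk"]), 30, tolerance = 1e-3)
  expect_equal(unname(tl30["tw"]), 30 - writhe(sol), tolerance = 1e-3)

  ## zero linking number framing of a planar circle carries no twist
  tlz <- twist_and_link(make_ribbon(circ, 0))
  expect_equal(unname(tlz["tw"]), 0, tolerance = 1e-3)

  expect_error(make_ribbon(closed_curve(cbind(1:10, 0, 0), closed = FALSE), 5),
               "closed")
  expect_error(ribbon_frames(circ, matrix(c(1, 0, 0), n, 3, byrow = TRUE)),
               "orthogonal")
})

test_that("shape metrics reproduce analytic values", {
  circ <- make_planar_circle(300, 18.35)
  sm <- shape_metrics(circ)
  expect_equal(sm$rg, 18.35, tolerance = 1e-9)
  expect_equal(sm$aspect_ratio, 1, tolerance = 1e-6)
  expect_equal(sm$planarity_pct, 0, tolerance = 1e-9)

  ell <- ellipse_xy(0, 0, 20, 10, n = 400)
  expect_equal(shape_metrics(ell)$aspect_ratio, 0.5, tolerance = 1e-3)

  ## in-plane rotation invariance
  sm0 <- shape_metrics(ell)
  for (ang in c(0.3, 1.2, 2.5)) {
    R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1),
                3, 3)
    smr <- shape_metrics(closed_curve(ell$points %*% R))
    expect_equal(smr$aspect_ratio, sm0$aspect_ratio, tolerance = 1e-9)
  }

  expect_error(shape_metrics(closed_curve(cbind(1:10, 2 * (1:10), 0),
                                          closed = FALSE)), "colinear")
})

test_that("superhelical density arithmetic follows sigma = dLk/Lk0", {
  rec <- sigma_from_topology(339, -1)
  expect_equal(rec$lk0, 339 / 10.5)
  expect_equal(round(rec$sigma, 2), -0.03)
  expect_equal(round(sigma_from_topology(339, -2)$sigma, 2), -0.06)
  expect_equal(sigma_from_topology(251, 0)$sigma, 0)
  expect_error(sigma_from_topology(339, -1, helical_repeat = 0), "repeat")
  expect_error(sigma_from_topology(0, -1), "n_bp")
  expect_equal(helical_repeat(251, 24), 251 / 24)
})
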