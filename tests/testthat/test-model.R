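test_that("defect-free minicircles are fully paired and stacked", {
  m <- build_minicircle_model(339, 0)
  hb <- detect_hbonds(m)
  expect_equal(sum(hb$triad_role == "wc"), 339)
  st <- basepair_states(m, hb)
  expect_true(all(st$paired))
  expect_true(all(st$stacked_5p & st$stacked_3p))
  expect_false(any(st$flipped))
  expect_equal(nrow(classify_defects(st)), 0)
})

test_that("model construction is deterministic given its seed", {
  a <- build_minicircle_model(120, -1, seed = 42)
  b <- build_minicircle_model(120, -1, seed = 42)
  expect_identical(a$atoms, b$atoms)
  c <- build_minicircle_model(120, -1, seed = 43)
  expect_false(identical(a$sequence$A, c$sequence$A))
})

test_that("base frames are orthonormal", {
  m <- build_minicircle_model(150, -2,
                              defects = list(list(span = c(40, 2),
                                                  kind = "bubble")))
  nrm <- m$frame_normal
  lng <- m$frame_long
  expect_true(all(abs(sqrt(rowSums(nrm^2)) - 1) < 1e-6))
  expect_true(all(abs(sqrt(rowSums(lng^2)) - 1) < 1e-6))
  expect_true(all(abs(rowSums(nrm * lng)) < 1e-6))
})

test_that("planted bubbles are flipped and recovered as one record", {
  m <- build_minicircle_model(339, -2,
                              defects = list(list(span = c(170, 3),
                                                  kind = "bubble")))
  st <- basepair_states(m)
  expect_true(all(st$flipped[171:173]))   # 0-based 170..172
  expect_true(all(!st$paired[171:173]))
  rec <- classify_defects(st)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$kind, "bubble")
  expect_equal(rec$span_start, 170)
  expect_equal(rec$span_length, 3)
})

test_that("planted kink types carry their defining state signatures", {
  m <- build_minicircle_model(339, -3,
                              defects = list(list(span = c(60, 1),
                                                  kind = "kink1"),
                                             list(span = c(250, 2),
                                                  kind = "kink2")))
  st <- basepair_states(m)
  ## kink1: single unpaired bp with at least one broken stack, not flipped
  expect_false(st$paired[61])
  expect_false(st$flipped[61])
  expect_true(!st$stacked_5p[61] || !st$stacked_3p[61])
  ## kink2: two consecutive unpaired, not flipped, 5' stacking intact
  expect_true(all(!st$paired[251:252]))
  expect_true(all(!st$flipped[251:252]))
  expect_true(all(st$stacked_5p[251:252]))
  rec <- classify_defects(st)
  expect_setequal(rec$kind, c("kink1", "kink2"))
})

test_that("triplex construction yields one Hoogsteen-bonded triad per TBS bp", {
  m <- build_minicircle_model(339, 0, with_tfo = TRUE, tbs = c(170, 16))
  hb <- detect_hbonds(m)
  hoog <- hb[hb$triad_role == "hoogsteen", ]
  tbs_bp <- sort(unique(c(hoog$donor_resid, hoog$acceptor_resid)))
  expect_length(tbs_bp, 16)
  expect_true(all(hoog$distance <= 3.0))
  ## the TBS duplex carries the purine-tract sequence the third strand reads
  expect_equal(m$sequence$A[171:186], rep(c("G", "A"), 8))
  expect_equal(m$sequence$T, rep(c("C", "T"), 8))
  ## Watson-Crick pairing is untouched by the third strand
  expect_equal(sum(hb$triad_role == "wc"), 339)
})

test_that("defect specification errors are caught", {
  expect_error(build_minicircle_model(50, 0), "n_bp")
  expect_error(build_minicircle_model(100, 0,
                                      defects = list(list(span = c(0, 60),
                                                          kind = "bubble"))),
               "span exceeding")
  expect_error(build_minicircle_model(100, 0,
                                      defects = list(list(span = c(10, 2),
                                                          kind = "bubble"),
                                                     list(span = c(11, 1),
                                                          kind = "kink1"))),
               "disjoint")
  expect_error(build_minicircle_model(100, 0,
                                      defects = list(list(span = c(10, 2),
                                                          kind = "kink1"))),
               "kink1")
})

test_that("models can be laid on an arbitrary closed axis", {
  sol <- make_supercoiled_curve(120, 2, 2, 6.5)
  m <- build_minicircle_model(120, -2, axis_curve = sol)
  expect_equal(nrow(m$atoms), 120 * 6)
  st <- basepair_states(m)
  expect_true(all(st$paired))
  expect_error(build_minicircle_model(150, 0, axis_curve = sol),
               "one point per base pair")
})
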