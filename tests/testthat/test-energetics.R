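test_that("the Coulomb convention gives -332.06 kcal/mol for unit charges at 1 A", {
  m <- toy_model(list(
    list(chain = "A", resid = 1, positions = list(B = c(0, 0, 0)),
         charges = list(B = 1)),
    list(chain = "B", resid = 1, positions = list(B = c(1, 0, 0)),
         charges = list(B = -1))))
  p <- nonbonded_params(dielectric = 1, debye_length = NULL, cutoff = 10)
  e <- nonbonded_energy(m, params = p)
  ## LJ contribution at 1 A is enormous; check the electrostatic part alone
  expect_equal(unname(e["elec"]), -332.06, tolerance = 1e-9)
})

test_that("Lennard-Jones roots and minimum sit where they should", {
  lj1 <- function(r) {
    m <- toy_model(list(
      list(chain = "A", resid = 1, positions = list(B = c(0, 0, 0)),
           charges = list(B = 0)),
      list(chain = "B", resid = 1, positions = list(B = c(r, 0, 0)),
           charges = list(B = 0))))
    p <- nonbonded_params(dielectric = 1, debye_length = NULL, cutoff = 50)
    unname(nonbonded_energy(m, params = p)["lj"])
  }
  sigma <- pseudo_atom_params()$lj$sigma[3]     # type B
  eps <- pseudo_atom_params()$lj$epsilon[3]
  expect_equal(lj1(sigma), 0, tolerance = 1e-9)
  expect_equal(lj1(2^(1 / 6) * sigma), -eps, tolerance = 1e-9)
})

test_that("pair sums agree with the all-pairs brute-force oracle", {
  ## <= 500 atoms with a third strand bound
  m <- build_minicircle_model(75, -1, with_tfo = TRUE, tbs = c(20, 8),
                              seed = 7)
  expect_lte(nrow(m$atoms), 500)
  p <- nonbonded_params(cutoff = 40)
  got <- nonbonded_energy(m, params = p)
  want <- nonbonded_bruteforce(m, p)
  expect_equal(unname(got["elec"]), unname(want["elec"]), tolerance = 1e-6)
  expect_equal(unname(got["lj"]), unname(want["lj"]), tolerance = 1e-6)
})

test_that("electrostatics are invariant under rigid motion", {
  m <- build_minicircle_model(80, 0, seed = 3)
  p <- nonbonded_params()
  e0 <- nonbonded_energy(m, params = p)
  R <- random_rotation(21)
  m2 <- m
  xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% R
  m2$atoms$x <- xyz[, 1] + 5; m2$atoms$y <- xyz[, 2] - 3
  m2$atoms$z <- xyz[, 3] + 11
  e1 <- nonbonded_energy(m2, params = p)
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("selection handling: disjoint or identical only, clashes rejected", {
  m <- build_minicircle_model(80, 0)
  a <- which(m$atoms$resid <= 10)
  b <- which(m$atoms$resid %in% 5:20)
  expect_error(nonbonded_energy(m, a, b), "disjoint")
  m2 <- m
  i <- which(m$atoms$chain == "A" & m$atoms$resid == 1 & m$atoms$name == "P")
  j <- which(m$atoms$chain == "B" & m$atoms$resid == 40 & m$atoms$name == "P")
  m2$atoms[j, c("x", "y", "z")] <- m2$atoms[i, c("x", "y", "z")] +
    c(0.01, 0, 0)
  expect_error(nonbonded_energy(m2, params = nonbonded_params()),
               "overlapping atoms")
})

test_that("binding energy of a model against itself is exactly zero", {
  m <- build_minicircle_model(100, 0, tbs = c(30, 16), seed = 2)
  er <- triplex_binding_energy(m, m)
  expect_identical(er$e_bind, 0)
  expect_identical(er$in_plane + er$adjacent, er$e_bind)
  expect_type(er$e_bind, "double")
})

test_that("ideal Hoogsteen geometry binds attractively, in-plane", {
  mt <- build_minicircle_model(120, 0, with_tfo = TRUE, tbs = c(40, 16),
                               seed = 3)
  m0 <- build_minicircle_model(120, 0, with_tfo = FALSE, tbs = c(40, 16),
                               seed = 3)
  er <- triplex_binding_energy(mt, m0)
  expect_lt(er$in_plane, 0)
  expect_equal(er$e_bind, er$in_plane + er$adjacent, tolerance = 1e-6)
  expect_equal(nrow(er$per_triad), 16)

  ## decomposition agrees with a brute-force pair sum over the same
  ## third-strand-base / duplex-base neighbourhood pairs
  p <- nonbonded_params()
  at <- mt$atoms
  manual <- 0
  for (r in unique(at$resid[at$chain == "T"])) {
    tb <- which(at$chain == "T" & at$resid == r & at$name == "B")
    nb <- which(at$chain %in% c("A", "B") & at$name == "B" &
                  (at$resid == r |
                     at$resid %in% (((c(r - 1, r + 1) - 1) %% 120) + 1)))
    for (j in nb) {
      dr <- sqrt(sum((as.numeric(at[tb, c("x", "y", "z")]) -
                        as.numeric(at[j, c("x", "y", "z")]))^2))
      if (dr > p$cutoff) next
      manual <- manual + 332.06 * at$charge[tb] * at$charge[j] *
        exp(-dr / p$debye_length) / (p$dielectric * dr)
      s <- (2.5 + 2.5) / 2; e <- 0.1
      manual <- manual + 4 * e * ((s / dr)^12 - (s / dr)^6)
    }
  }
  expect_equal(er$e_bind, manual, tolerance = 1e-6)
})

test_that("pulling the third strand out of the groove weakens binding monotonically", {
  mt <- build_minicircle_model(120, 0, with_tfo = TRUE, tbs = c(40, 16),
                               seed = 3)
  m0 <- build_minicircle_model(120, 0, with_tfo = FALSE, tbs = c(40, 16),
                               seed = 3)
  ## displace every third-strand residue along its own groove direction
  displace_tfo <- function(model, dist) {
    at <- model$atoms
    for (r in unique(at$resid[at$chain == "T"])) {
      tb <- at$chain == "T" & at$resid == r & at$name == "B"
      ab <- at$chain == "A" & at$resid == r & at$name == "B"
      dir <- as.numeric(at[tb, c("x", "y", "z")]) -
        as.numeric(at[ab, c("x", "y", "z")])
      dir <- dir / sqrt(sum(dir^2))
      sel <- at$chain == "T" & at$resid == r
      at[sel, c("x", "y", "z")] <- sweep(at[sel, c("x", "y", "z")], 2,
                                         -dist * dir)
    }
    model$atoms <- at
    model
  }
  mags <- vapply(c(0, 1, 2, 3.5, 5), function(d)
    abs(triplex_binding_energy(displace_tfo(mt, d), m0)$e_bind), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("compaction raises the electrostatic self-energy magnitude", {
  ## a topoisomer-like series of increasingly writhed (compact) conformers
  p <- nonbonded_params()
  n <- 200
  L <- 0.34 * n                            # fixed contour length, nm
  solenoid_fixed_length <- function(a) {
    if (a == 0) return(make_planar_circle(n, L / (2 * pi)))
    r <- stats::uniroot(function(rc)
      curve_length(make_supercoiled_curve(n, 3, a, rc)) - L,
      c(6, L / (2 * pi)))$root
    make_supercoiled_curve(n, 3, a, r)
  }
  amps <- c(0, 1, 2)
  res <- t(vapply(amps, function(a) {
    ax <- solenoid_fixed_length(a)
    m <- build_minicircle_model(n, 0, axis_curve = ax, seed = 1)
    c(rg = shape_metrics(ax)$rg,
      elec = abs(nonbonded_energy(m, params = p)[["elec"]]))
  }, numeric(2)))
  expect_true(all(diff(res[, "rg"]) < 0))        # Rg falls...
  expect_true(all(diff(res[, "elec"]) >= 0))     # ...self-repulsion rises
})

test_that("reference deltas zero the reference and respect order", {
  expect_equal(reference_delta(c("0" = -10, "-1" = -12), "0"),
               c("0" = 0, "-1" = -2))
  expect_equal(reference_delta(c(lin = 4.2), "lin"), c(lin = 0))
  a <- c("0" = 1, "-1" = 5, "-2" = -3)
  expect_equal(reference_delta(a, "-1")[names(a)],
               reference_delta(a[c(2, 3, 1)], "-1")[names(a)])
  expect_error(reference_delta(c(a = 1), "b"), "missing reference")
})
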