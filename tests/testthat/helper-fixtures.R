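# Fixture builders shared across the suite. Everything is generated in code;
# nothing is read from disk.

## a planar circle in the image plane, centred at (cx, cy), nm
circle_xy <- function(cx, cy, r, n = 150) {
  th <- 2 * pi * (0:(n - 1)) / n
  closed_curve(cbind(cx + r * cos(th), cy + r * sin(th), 0))
}

## in-plane ellipse with semi-axes a >= b
ellipse_xy <- function(cx, cy, a, b, n = 200) {
  th <- 2 * pi * (0:(n - 1)) / n
  closed_curve(cbind(cx + a * cos(th), cy + b * sin(th), 0))
}

## random rigid rotation matrix from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3))) * sample(c(-1, 1), 1)
}

## lay n molecules on a jittered grid inside a square field of view,
## returning a list of closed curves (mixture of circles and ellipses)
plant_molecules <- function(n, fov, seed, r_range = c(16, 22)) {
  set.seed(seed)
  k <- ceiling(sqrt(max(n, 4)))
  cell <- fov / k
  slots <- sample(k * k, n)
  lapply(seq_len(n), function(i) {
    s <- slots[i] - 1
    cx <- (s %% k + 0.5) * cell + runif(1, -4, 4)
    cy <- (s %/% k + 0.5) * cell + runif(1, -4, 4)
    r <- runif(1, r_range[1], r_range[2])
    ratio <- runif(1, 0.55, 1)
    ellipse_xy(cx, cy, r, r * ratio)
  })
}

## a minimal hand-built pseudo-atomic model: one residue per entry of `spec`,
## each a list(chain, resid, base, positions = named list P/S/B, charges)
toy_model <- function(spec, circular = FALSE) {
  rows <- lapply(spec, function(s) {
    nm <- names(s$positions)
    do.call(rbind, lapply(nm, function(a) {
      data.frame(chain = s$chain, resid = s$resid, base = s$base %||% "A",
                 name = a,
                 x = s$positions[[a]][1], y = s$positions[[a]][2],
                 z = s$positions[[a]][3],
                 charge = s$charges[[a]] %||% 0, type = substr(a, 1, 1),
                 stringsAsFactors = FALSE)
    }))
  })
  atoms <- do.call(rbind, rows)
  n_bp <- max(atoms$resid)
  structure(list(n_bp = n_bp, circular = circular,
                 sequence = list(A = rep("A", n_bp), B = rep("T", n_bp),
                                 T = NULL),
                 atoms = atoms,
                 frame_origin = matrix(0, n_bp, 3),
                 frame_normal = matrix(rep(c(0, 0, 1), each = n_bp), n_bp, 3),
                 frame_long = matrix(rep(c(1, 0, 0), each = n_bp), n_bp, 3),
                 pairing = rep("paired", n_bp), tbs = NULL,
                 delta_lk = 0, helical_repeat = 10.5,
                 defects = list(), seed = NULL, axis = NULL),
            class = "pseudo_atomic_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
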