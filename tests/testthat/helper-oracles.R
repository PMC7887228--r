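# Independent oracles. These deliberately use the plainest possible
# formulations (midpoint quadrature, all-pairs loops, dense convolution) and
# share no code with the package internals they check.

## Gauss-integral writhe by midpoint quadrature over segment midpoints
writhe_quadrature <- function(points) {
  p <- points
  n <- nrow(p)
  nxt <- c(2:n, 1)
  mid <- (p + p[nxt, ]) / 2
  d <- p[nxt, ] - p
  i <- rep.int(seq_len(n - 2), (n - 2):1)
  j <- sequence((n - 2):1) + i + 1
  keep <- !(j - i == 1 | (i == 1 & j == n))
  i <- i[keep]; j <- j[keep]
  r <- mid[j, , drop = FALSE] - mid[i, , drop = FALSE]
  cr <- cbind(d[i, 2] * d[j, 3] - d[i, 3] * d[j, 2],
              d[i, 3] * d[j, 1] - d[i, 1] * d[j, 3],
              d[i, 1] * d[j, 2] - d[i, 2] * d[j, 1])
  2 * sum(rowSums(cr * r) / rowSums(r * r)^1.5) / (4 * pi)
}

## all-pairs non-bonded energy with explicit loops over the atom table
nonbonded_bruteforce <- function(model, params) {
  at <- model$atoms
  n <- nrow(at)
  sig <- setNames(params$lj_table$sigma, params$lj_table$type)
  eps <- setNames(params$lj_table$epsilon, params$lj_table$type)
  elec <- 0; lj <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (at$chain[i] == at$chain[j]) {
        dr <- abs(at$resid[i] - at$resid[j])
        if (model$circular) dr <- min(dr, model$n_bp - dr)
        if (dr <= 1) next
      }
      r <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (r > params$cutoff) next
      scr <- if (is.null(params$debye_length)) 1 else
        exp(-r / params$debye_length)
      elec <- elec + params$coulomb_constant * at$charge[i] * at$charge[j] *
        scr / (params$dielectric * r)
      s <- (sig[[at$type[i]]] + sig[[at$type[j]]]) / 2
      e <- sqrt(eps[[at$type[i]]] * eps[[at$type[j]]])
      lj <- lj + 4 * e * ((s / r)^12 - (s / r)^6)
    }
  }
  c(elec = elec, lj = lj)
}

## dense direct 2D convolution with periodic boundary, normalized kernel
convolve_dense <- function(m, sigma_px, truncate_px) {
  r <- max(1, floor(truncate_px))
  k1 <- dnorm(-r:r, sd = sigma_px); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- ((i + di - 1) %% nr) + 1
      jj <- ((j + dj - 1) %% nc) + 1
      acc <- acc + K[di + r + 1, dj + r + 1] * m[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}
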