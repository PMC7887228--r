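#' Closed molecular contour
#'
#' A `closed_curve` is an ordered set of 3D points (nm) tracing a molecular
#' contour, typically the helical axis of a DNA minicircle. When `closed`,
#' indexing is circular (modulo the number of points) and the segment from the
#' last point back to the first belongs to the curve.
#'
#' @param points numeric matrix (n x 3) of positions in nm.
#' @param closed logical; is the contour a closed loop?
#' @param labels optional integer vector of 0-based base-pair indices.
#' @return An object of class `closed_curve`.
#' @export
closed_curve <- function(points, closed = TRUE, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (nrow(points) < 3) stop("a curve needs at least 3 points")
  stopifnot_finite(points, "curve points")
  d <- points[c(2:nrow(points), 1), ] - points
  if (!closed) d <- d[-nrow(points), , drop = FALSE]
  if (any(row_norm(d) < 1e-12)) stop("consecutive curve points must be distinct")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("labels must match the number of points")
  structure(list(points = points, closed = closed, labels = labels),
            class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("<closed_curve: %d points, %s, length %.2f nm>\n",
              nrow(x$points), if (x$closed) "closed" else "open",
              curve_length(x)))
  invisible(x)
}

#' Total arc length of a curve (nm)
#' @param curve a [closed_curve()].
#' @return numeric scalar, nm.
#' @export
curve_length <- function(curve) {
  p <- curve$points
  d <- p[c(2:nrow(p), 1), ] - p
  if (!curve$closed) d <- d[-nrow(p), , drop = FALSE]
  sum(row_norm(d))
}

## Unit tangents z_i = normalize(r_{i+1} - r_i), circular for closed curves.
## For open curves the last tangent repeats so lengths match.
curve_tangents <- function(curve) {
  p <- curve$points
  n <- nrow(p)
  d <- p[c(2:n, 1), ] - p
  if (!curve$closed) d[n, ] <- d[n - 1, ]
  nn <- row_norm(d)
  if (any(nn < 1e-12)) {
    bad <- which(nn < 1e-12)[1]
    stop(sprintf("degenerate geometry: repeated point at index %d", bad - 1))
  }
  d / nn
}

#' Planar circle fixture
#'
#' Equally spaced points on a circle of the given radius lying in the plane
#' perpendicular to `plane_normal`. A planar circle has writhe 0, planarity
#' deviation 0 and aspect ratio 1, which makes it the reference state for the
#' relaxed minicircle topoisomer.
#'
#' @param n_points number of contour points (>= 3).
#' @param radius circle radius, nm (> 0).
#' @param plane_normal 3-vector normal of the circle plane (default +z).
#' @return A closed [closed_curve()] with 0-based labels.
#' @export
make_planar_circle <- function(n_points, radius, plane_normal = c(0, 0, 1)) {
  if (!all(is.finite(c(n_points, radius, plane_normal))))
    stop("non-finite argument")
  if (n_points < 3) stop("n_points must be >= 3")
  if (radius <= 0) stop("radius must be > 0")
  th <- 2 * pi * (seq_len(n_points) - 1) / n_points
  pts <- cbind(radius * cos(th), radius * sin(th), 0)
  nrm <- unit3(plane_normal)
  if (abs(nrm[3]) < 1 - 1e-12) {           # rotate +z onto plane_normal
    axis <- unit3(cross3(c(0, 0, 1), nrm))
    ang <- acos(clamp(nrm[3], -1, 1))
    pts <- rotate_about(pts, matrix(axis, nrow(pts), 3, byrow = TRUE), ang)
  } else if (nrm[3] < 0) {
    pts[, 3] <- -pts[, 3]; pts[, 2] <- -pts[, 2]
  }
  closed_curve(pts, closed = TRUE, labels = seq_len(n_points) - 1L)
}

#' Solenoidal (writhed) closed curve
#'
#' A toroidal solenoid emulating the writhed conformers of supercoiled
#' minicircles: a core circle of radius `core_radius` modulated by `n_lobes`
#' helical excursions of the given amplitude. Writhe magnitude grows with both
#' the lobe count and the amplitude; `handedness = -1` (default) gives negative
#' writhe, as for negatively supercoiled DNA. Deterministic for fixed
#' parameters, so the same geometry can be regenerated at any point density
#' (used by the brute-force writhe oracle at 4x density).
#'
#' @param n_points number of contour points.
#' @param n_lobes number of superhelical lobes (>= 1).
#' @param amplitude excursion amplitude, nm (0 degenerates to a planar circle).
#' @param core_radius radius of the core circle, nm.
#' @param handedness +1 or -1 chirality (sign of the writhe).
#' @param clash_radius minimum allowed distance between non-neighbouring
#'   points, nm; closer approaches raise a generation error.
#' @return A closed [closed_curve()].
#' @export
make_supercoiled_curve <- function(n_points, n_lobes, amplitude, core_radius,
                                   handedness = -1, clash_radius = 1) {
  if (!all(is.finite(c(n_points, n_lobes, amplitude, core_radius))))
    stop("non-finite argument")
  if (n_lobes < 1) stop("n_lobes must be >= 1")
  if (n_points < 3) stop("n_points must be >= 3")
  t <- 2 * pi * (seq_len(n_points) - 1) / n_points
  r <- core_radius + amplitude * cos(n_lobes * t)
  z <- handedness * amplitude * sin(n_lobes * t)
  pts <- cbind(r * cos(t), r * sin(t), z)
  cur <- closed_curve(pts, closed = TRUE, labels = seq_len(n_points) - 1L)
  if (amplitude > 0 && n_points <= 2000) {
    dmin <- min_distant_pair_distance(pts, curve_length(cur), clash_radius)
    if (dmin < clash_radius)
      stop(sprintf(paste0("self-intersecting parameters: minimum non-local",
                          " approach %.3f nm < clash radius %.3f nm"),
                   dmin, clash_radius))
  }
  cur
}

## Minimum distance between pairs of points that are far apart along the
## curve (arc separation > 2.5 clash radii), i.e. genuine self-approaches.
min_distant_pair_distance <- function(pts, len, clash_radius) {
  n <- nrow(pts)
  spacing <- len / n
  k_excl <- ceiling(2.5 * clash_radius / spacing)
  if (k_excl >= floor((n - 1) / 2)) return(Inf)
  d <- as.matrix(stats::dist(pts))
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx <- pmin(idx, n - idx)                # circular separation
  d[idx <= k_excl] <- Inf
  min(d)
}

#' Inject a localized kink into a planar closed curve
#'
#' Rebuilds the curve from its turning-angle profile: the requested bend angle
#' is concentrated over `span` consecutive vertices at `position`, the
#' remaining turning (the total turning of a simple closed planar curve is
#' 360 degrees) is spread uniformly elsewhere, and segment lengths are
#' adjusted by a minimal least-squares correction so the polygon closes
#' exactly at the original total arc length. Previously injected kinks are
#' recorded on the curve and re-applied, so repeated injection composes;
#' overlapping kinks are an error.
#'
#' @param curve a planar closed [closed_curve()].
#' @param position 0-based index of the kink centre.
#' @param angle bend angle in degrees (0 < angle <= 180; 0 returns the curve
#'   unchanged).
#' @param span number of vertices over which the bend is spread (>= 1).
#' @return A closed [closed_curve()] with a `kinks` attribute listing all
#'   planted kinks.
#' @export
inject_kink <- function(curve, position, angle, span = 1) {
  stopifnot(inherits(curve, "closed_curve"), curve$closed)
  if (!all(is.finite(c(position, angle, span)))) stop("non-finite argument")
  if (angle == 0) return(curve)
  if (angle < 0 || angle > 180) stop("angle must be in (0, 180] degrees")
  if (span < 1) stop("span must be >= 1")
  n <- nrow(curve$points)
  kinks <- attr(curve, "kinks") %||% list()
  newk <- list(position = as.integer(position) %% n, angle = angle,
               span = as.integer(span))
  for (k in kinks) {
    sep <- abs(((newk$position - k$position + n / 2) %% n) - n / 2)
    if (sep < (k$span + newk$span) / 2 + 1)
      stop("overlapping kinks are not allowed")
  }
  kinks <- c(kinks, list(newk))
  out <- kinked_closed_curve(n, curve_length(curve), kinks)
  ## keep the centroid where the input curve was
  shift <- colMeans(curve$points) - colMeans(out$points)
  out$points <- sweep(out$points, 2, -shift)
  out$labels <- curve$labels
  attr(out, "kinks") <- kinks
  out
}

## Build a closed planar curve of n vertices and total length len with corner
## turns given by `kinks` (list of position/angle/span) and uniform turning
## elsewhere. Closure is enforced by the minimum-norm segment-length
## correction subject to sum(L t) = 0 and sum(L) = len.
kinked_closed_curve <- function(n, len, kinks) {
  tau <- rep(NA_real_, n)
  kinkv <- rep(FALSE, n)
  for (k in kinks) {
    idx <- cyc(k$position + 1 + seq_len(k$span) - ceiling(k$span / 2), n)
    if (any(kinkv[idx])) stop("overlapping kinks are not allowed")
    kinkv[idx] <- TRUE
    tau[idx] <- rad(k$angle) / k$span
  }
  total_kink <- sum(tau[kinkv])
  if (total_kink >= 2 * pi) stop("total kink turning exceeds 360 degrees")
  tau[!kinkv] <- (2 * pi - total_kink) / sum(!kinkv)
  ## Segment lengths stay uniform (so per-point spacing, e.g. the helical
  ## rise, is preserved); the polygon is closed by smoothly modulating the
  ## background curvature with one Fourier harmonic, tau_i proportional to
  ## 1 + c1 cos(alpha_i) + c2 sin(alpha_i) on non-kink vertices, solving the
  ## two position-closure equations for (c1, c2) by Newton iteration. This
  ## reproduces the teardrop/lens shapes of kinked rings at uniform arc
  ## sampling.
  Lbar <- len / n
  alpha <- 2 * pi * (seq_len(n) - 1) / n
  theta_tot <- total_kink
  basis <- cbind(cos(alpha), sin(alpha), cos(2 * alpha), sin(2 * alpha))
  weights <- function(cc) 1 + as.numeric(basis %*% cc)
  gap <- function(cc) {
    w <- weights(cc)
    tt <- tau
    tt[!kinkv] <- (2 * pi - theta_tot) * w[!kinkv] / sum(w[!kinkv])
    phi <- cumsum(tt)
    c(sum(cos(phi)), sum(sin(phi))) * Lbar
  }
  cc <- numeric(4)
  h <- 1e-6
  converged <- FALSE
  for (iter in 1:200) {
    g <- gap(cc)
    if (max(abs(g)) < 1e-10 * len) { converged <- TRUE; break }
    J <- vapply(seq_along(cc), function(j) {
      e <- numeric(4); e[j] <- h
      (gap(cc + e) - g) / h
    }, numeric(2))
    ## minimal-norm Gauss-Newton step (2 equations, 4 coefficients)
    step <- tryCatch(as.numeric(t(J) %*% solve(J %*% t(J) +
                                                 1e-12 * diag(2), g)),
                     error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
    cc <- cc - step
  }
  if (!converged && max(abs(gap(cc))) > 1e-8 * len)
    stop("kink configuration cannot close the curve")
  w <- weights(cc)
  tau[!kinkv] <- (2 * pi - theta_tot) * w[!kinkv] / sum(w[!kinkv])
  phi <- cumsum(tau)
  pts <- cbind(apply(rbind(0, Lbar * cbind(cos(phi), sin(phi))),
                     2, cumsum)[seq_len(n), ], 0)
  ## indices, not coordinates, carry the kink position.
  closed_curve(pts, closed = TRUE, labels = seq_len(n) - 1L)
}
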