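#' Discretized Gauss-integral writhe of a closed curve
#'
#' Writhe quantifies the coiling of the helical axis in space. It is computed
#' as the discretized Gauss double integral over all non-adjacent segment
#' pairs, using the exact pairwise-segment solid-angle formula (the signed
#' solid angle subtended by one segment at the other, from the tetrahedral
#' construction of Klenin and Langowski). The exact per-pair solid angle, as
#' opposed to midpoint quadrature, keeps twist + writhe consistent with an
#' integer linking number even at coarse discretization. Writhe is invariant
#' under rigid motion and uniform scaling and changes sign under mirror
#' reflection.
#'
#' @param curve a closed [closed_curve()] with >= 10 points.
#' @return numeric scalar: the writhe, in turns.
#' @export
writhe <- function(curve) {
  stopifnot(inherits(curve, "closed_curve"))
  if (!curve$closed) stop("writhe requires a closed curve")
  p <- curve$points
  n <- nrow(p)
  if (n < 10) stop("writhe requires at least 10 points")
  s <- p
  e <- p[c(2:n, 1), ]
  ## all unordered non-adjacent segment pairs (circular adjacency excluded)
  i <- rep.int(seq_len(n - 2), (n - 2):1)
  j <- sequence((n - 2):1) + i + 1
  keep <- !(j - i == 1 | (i == 1 & j == n))
  i <- i[keep]; j <- j[keep]

  r13 <- s[j, , drop = FALSE] - s[i, , drop = FALSE]
  r14 <- e[j, , drop = FALSE] - s[i, , drop = FALSE]
  r23 <- s[j, , drop = FALSE] - e[i, , drop = FALSE]
  r24 <- e[j, , drop = FALSE] - e[i, , drop = FALSE]
  if (any(row_norm(r13) < 1e-9) || any(row_norm(r24) < 1e-9))
    stop("degenerate geometry: coincident points between distant segments")
  r12 <- e[i, , drop = FALSE] - s[i, , drop = FALSE]
  r34 <- e[j, , drop = FALSE] - s[j, , drop = FALSE]

  unit_or_zero <- function(v) {
    nn <- row_norm(v)
    nn[nn < 1e-14] <- Inf
    v / nn
  }
  n1 <- unit_or_zero(row_cross(r13, r14))
  n2 <- unit_or_zero(row_cross(r14, r24))
  n3 <- unit_or_zero(row_cross(r24, r23))
  n4 <- unit_or_zero(row_cross(r23, r13))
  omega <- asin(clamp(row_dot(n1, n2), -1, 1)) +
           asin(clamp(row_dot(n2, n3), -1, 1)) +
           asin(clamp(row_dot(n3, n4), -1, 1)) +
           asin(clamp(row_dot(n4, n1), -1, 1))
  sgn <- sign(row_dot(row_cross(r12, r34), r13))
  sum(omega * sgn) / (2 * pi)
}

#' Ribbon frames: a closed axis plus reference normals
#'
#' Carries the discrete framing of a DNA duplex: the helical-axis contour and
#' one unit normal per point (perpendicular to the local tangent). The framing
#' determines the twist Tw; together with the writhe Wr of the axis it gives
#' the linking number Lk = Tw + Wr (White-Fuller).
#'
#' @param axis a closed [closed_curve()].
#' @param normals numeric matrix (n x 3) of unit normals, one per axis point.
#' @param lk_target optional integer linking number the framing was built for.
#' @return An object of class `ribbon_frames`.
#' @export
ribbon_frames <- function(axis, normals, lk_target = NULL) {
  stopifnot(inherits(axis, "closed_curve"))
  normals <- as.matrix(normals)
  if (nrow(normals) != nrow(axis$points) || ncol(normals) != 3)
    stop("normals must be one 3-vector per axis point")
  t <- curve_tangents(axis)
  if (any(abs(row_norm(normals) - 1) > 1e-6) ||
      any(abs(row_dot(normals, t)) > 1e-6))
    stop("validation error: frames must be unit length and orthogonal to the tangent")
  structure(list(axis = axis, normals = normals, lk_target = lk_target),
            class = "ribbon_frames")
}

## Parallel-transport frame around a (closed) curve, seeded by any vector not
## parallel to the first tangent. Returns an n x 3 matrix of unit normals.
parallel_transport_normals <- function(curve) {
  t <- curve_tangents(curve)
  n <- nrow(t)
  u <- matrix(0, n, 3)
  seed <- c(0, 0, 1)
  if (abs(sum(seed * t[1, ])) > 0.9) seed <- c(1, 0, 0)
  u[1, ] <- unit3(seed - sum(seed * t[1, ]) * t[1, ])
  for (k in seq_len(n - 1)) {
    u[k + 1, ] <- transport_vec(u[k, ], t[k, ], t[k + 1, ])
  }
  u
}

transport_vec <- function(u, t0, t1) {
  a <- cross3(t0, t1)
  s <- sqrt(sum(a^2))
  if (s < 1e-14) return(u)
  axis <- a / s
  ang <- atan2(s, sum(t0 * t1))
  drop(rotate_about(matrix(u, 1, 3), matrix(axis, 1, 3), ang))
}

#' Frame a closed axis at a prescribed linking number
#'
#' Builds normals by parallel transport (a twist-free framing up to the closure
#' holonomy, whose linking number with the axis is an integer) and then adds a
#' uniform extra rotation of an integer number of turns so that the framing's
#' linking number equals `lk`. The resulting ribbon satisfies
#' Tw + Wr = lk to within the discretization tolerance, i.e. Tw = lk - Wr(axis).
#'
#' @param axis a closed [closed_curve()].
#' @param lk integer target linking number.
#' @return A [ribbon_frames()] object.
#' @export
make_ribbon <- function(axis, lk) {
  stopifnot(inherits(axis, "closed_curve"))
  if (!axis$closed) stop("make_ribbon requires a closed axis")
  if (abs(lk - round(lk)) > 1e-9) stop("lk must be an integer")
  u <- parallel_transport_normals(axis)
  n <- nrow(u)
  t <- curve_tangents(axis)
  ## The transport holonomy sits entirely in the closure step; spread it
  ## uniformly over all steps first, so that adding the integer winding can
  ## never push any single step past the principal branch of the angle.
  phi <- twist_step_angles(axis, u)
  mu <- mean(phi)
  spread <- cumsum(c(0, phi[seq_len(n - 1)] - mu))
  wr <- writhe(axis)
  m <- round(lk) - round(sum(phi) / (2 * pi) + wr)
  phase <- spread - 2 * pi * m * (seq_len(n) - 1) / n
  u <- rotate_about(u, t, phase)
  ribbon_frames(axis, u, lk_target = as.integer(round(lk)))
}

#' Twist, writhe and linking number of a ribbon
#'
#' Twist is the accumulated signed rotation of the reference normal about the
#' tangent between consecutive points, measured against a parallel-transported
#' reference (so that axis bending contributes nothing); writhe is the Gauss
#' integral of the axis; their sum is the linking number, an integer for any
#' closed framing.
#'
#' @param ribbon a [ribbon_frames()] object.
#' @return Named numeric vector `c(tw=, wr=, lk=)`, all in turns.
#' @export
twist_and_link <- function(ribbon) {
  stopifnot(inherits(ribbon, "ribbon_frames"))
  ax <- ribbon$axis
  u <- ribbon$normals
  t <- curve_tangents(ax)
  if (any(abs(row_norm(u) - 1) > 1e-6) || any(abs(row_dot(u, t)) > 1e-6))
    stop("validation error: non-orthogonal frames")
  tw <- sum(twist_step_angles(ax, u)) / (2 * pi)
  wr <- writhe(ax)
  c(tw = tw, wr = wr, lk = tw + wr)
}

## Per-step twist angles of a framing: the signed rotation of the normal
## about the tangent between consecutive points, measured against a
## parallel-transported reference, in the handedness that matches the
## Gauss-integral writhe sign (so that Tw + Wr = Lk exactly for polygons).
twist_step_angles <- function(axis, u) {
  t <- curve_tangents(axis)
  n <- nrow(u)
  nxt <- c(2:n, 1)
  phi <- numeric(n)
  for (k in seq_len(n)) {
    ut <- transport_vec(u[k, ], t[k, ], t[nxt[k], ])
    un <- u[nxt[k], ]
    phi[k] <- atan2(sum(cross3(un, ut) * t[nxt[k], ]), sum(ut * un))
  }
  phi
}

#' Bend-angle profile of a molecular contour
#'
#' The bending angle at position i is the directional change between the two
#' tangent vectors z_i and z_(i+sep), where z_i = normalize(r_(i+1) - r_i) and
#' the separation defaults to 16 nucleotides (about one and a half DNA helical
#' turns), a compromise length that captures the overall bend produced by a
#' defect or by canonical B-DNA. Indexing is circular on closed contours.
#'
#' @param curve a [closed_curve()] with more than `separation_bp` points.
#' @param separation_bp tangent separation in points (default 16).
#' @return An object of class `bend_profile`: list with `angles` (degrees, one
#'   per position for closed curves), `separation_bp`, and `n`.
#' @export
bend_profile <- function(curve, separation_bp = 16) {
  stopifnot(inherits(curve, "closed_curve"))
  n <- nrow(curve$points)
  if (n <= separation_bp) stop("curve must have more points than the separation")
  z <- curve_tangents(curve)
  if (curve$closed) {
    zj <- z[cyc(seq_len(n) + separation_bp, n), , drop = FALSE]
    ang <- deg(acos(clamp(row_dot(z, zj), -1, 1)))
  } else {
    m <- n - 1L                       # last tangent is a repeat
    idx <- seq_len(m - separation_bp)
    ang <- deg(acos(clamp(row_dot(z[idx, , drop = FALSE],
                                  z[idx + separation_bp, , drop = FALSE]), -1, 1)))
  }
  structure(list(angles = ang, separation_bp = as.integer(separation_bp),
                 n = n, closed = curve$closed),
            class = "bend_profile")
}

#' Find bend features (peaks) in a bend profile
#'
#' Contiguous runs of angles above the peak threshold (35 degrees by default)
#' are merged into one feature each; runs separated by fewer than half the
#' tangent separation are considered one physical bend, because a single point
#' kink spreads over about one separation window of profile positions.
#' The reported feature position is the centre of the maximal sub-fragment,
#' i.e. the profile argmax shifted by half the separation, which localizes the
#' physical bend on the contour.
#'
#' @param profile a [bend_profile()].
#' @param peak_threshold degrees in (0, 180); default 35.
#' @return A data.frame of class `bend_features` with columns `position`
#'   (0-based bp), `angle` (degrees), `span_start`, `span_length` (0-based,
#'   circular, in bp, shifted like `position`), `klass`, `evidence`.
#' @export
find_bend_features <- function(profile, peak_threshold = 35) {
  stopifnot(inherits(profile, "bend_profile"))
  if (peak_threshold <= 0 || peak_threshold >= 180)
    stop("peak_threshold must be in (0, 180)")
  ang <- profile$angles
  n <- length(ang)
  above <- ang > peak_threshold
  empty <- data.frame(position = integer(0), angle = numeric(0),
                      span_start = integer(0), span_length = integer(0),
                      klass = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  attr(empty, "n") <- profile$n
  class(empty) <- c("bend_features", class(empty))
  if (!any(above)) return(empty)
  runs <- circular_runs(above)
  ## merge runs separated by < separation/2 below-threshold positions
  gap_max <- profile$separation_bp / 2
  runs <- merge_runs(runs, n, gap_max, circular = profile$closed)
  shift <- floor(profile$separation_bp / 2)
  rows <- lapply(runs, function(r) {
    idx <- cyc(r$start + seq_len(r$length) - 1, n)   # 1-based profile indices
    a <- ang[idx]
    mx <- max(a)
    ties <- which(a >= mx - 1e-12)
    pick <- ties[ceiling(length(ties) / 2)]          # middle of tied maxima
    pos <- (r$start - 1 + pick - 1 + shift) %% profile$n
    data.frame(position = as.integer(pos), angle = mx,
               span_start = as.integer((r$start - 1 + shift) %% profile$n),
               span_length = as.integer(r$length),
               klass = NA_character_, evidence = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- profile$n
  class(out) <- c("bend_features", class(out))
  out
}

## runs of TRUE in a logical vector, treating it as circular
circular_runs <- function(x) {
  n <- length(x)
  r <- rle(x)
  starts <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  runs <- Map(function(s, l, v) if (v) list(start = s, length = l),
              starts, r$lengths, r$values)
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) >= 2 && x[1] && x[n]) {      # wrap-around run
    first <- runs[[1]]; last <- runs[[length(runs)]]
    if (last$start + last$length - 1 == n && first$start == 1) {
      runs[[1]] <- list(start = last$start, length = last$length + first$length)
      runs[[length(runs)]] <- NULL
    }
  }
  runs
}

merge_runs <- function(runs, n, gap_max, circular = TRUE) {
  if (length(runs) <= 1) return(runs)
  ord <- order(vapply(runs, `[[`, 1, "start"))
  runs <- runs[ord]
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    gap <- r$start - (last$start + last$length)
    if (gap < gap_max && gap >= 0) {
      merged[[length(merged)]] <- list(start = last$start,
                                       length = r$start + r$length - last$start)
    } else merged <- c(merged, list(r))
  }
  if (circular && length(merged) >= 2) {        # wrap gap between last and first
    first <- merged[[1]]; last <- merged[[length(merged)]]
    gap <- (first$start + n) - (last$start + last$length)
    if (gap < gap_max && gap >= 0) {
      merged[[1]] <- list(start = last$start,
                          length = first$start + first$length + n - last$start)
      merged[[length(merged)]] <- NULL
    }
  }
  merged
}

#' Classify bend features as B-DNA bends or defects
#'
#' In `angle_only` mode a feature is a defect iff its peak angle reaches the
#' defect cutoff (about 75 degrees separates canonical B-DNA bends from
#' defective DNA). In `interactions` mode a feature is a defect iff its span
#' overlaps a span of broken canonical interactions (from the defects module),
#' regardless of angle.
#'
#' @param features a `bend_features` data.frame from [find_bend_features()].
#' @param mode `"angle_only"` or `"interactions"`.
#' @param defect_cutoff degrees; default 75.
#' @param defect_spans for `interactions` mode: list of `c(start, length)`
#'   0-based circular bp spans with broken interactions (or a `defect_records`
#'   data.frame, whose spans are used).
#' @return The features with `klass` (`"b_bend"`/`"defect"`) and `evidence`
#'   filled in.
#' @export
classify_bend_features <- function(features,
                                   mode = c("angle_only", "interactions"),
                                   defect_cutoff = 75, defect_spans = NULL) {
  mode <- match.arg(mode)
  n <- attr(features, "n")
  if (nrow(features) == 0) return(features)
  if (mode == "angle_only") {
    features$klass <- ifelse(features$angle >= defect_cutoff, "defect", "b_bend")
    features$evidence <- "angle_only"
  } else {
    if (is.null(defect_spans))
      stop("interactions mode requires defect_spans")
    if (is.data.frame(defect_spans))
      defect_spans <- Map(c, defect_spans$span_start, defect_spans$span_length)
    features$klass <- vapply(seq_len(nrow(features)), function(k) {
      f <- circular_span_members(features$span_start[k],
                                 features$span_length[k], n)
      hit <- any(vapply(defect_spans, function(sp)
        length(intersect(f, circular_span_members(sp[1], sp[2], n))) > 0,
        logical(1)))
      if (hit) "defect" else "b_bend"
    }, character(1))
    features$evidence <- "broken_interactions"
  }
  features
}

circular_span_members <- function(start, length, n) (start + seq_len(length) - 1) %% n

#' Global shape metrics of a molecular contour
#'
#' The best-fitting plane is found from the principal axes of the centred
#' points (normal = smallest-variance direction). Planarity is reported as
#' the mean perpendicular distance to that plane as a percentage of the
#' longest in-plane axis. The longest axis is the maximum pairwise distance
#' between in-plane projections; the shortest axis is the maximal in-plane
#' extent perpendicular to the longest-axis direction; their ratio
#' (shortest/longest, in (0,1]) is the aspect ratio, which is 1 for an open
#' circle and small for compact writhed forms. Rg is the root-mean-square
#' 3D distance of the points from their centroid.
#'
#' @param curve a [closed_curve()] with >= 4 non-colinear points.
#' @return A list of class `shape_metrics`: `aspect_ratio`, `planarity_pct`,
#'   `rg`, `longest_axis`, `shortest_axis` (nm).
#' @export
shape_metrics <- function(curve) {
  stopifnot(inherits(curve, "closed_curve"))
  p <- curve$points
  if (nrow(p) < 4) stop("shape metrics require at least 4 points")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  sv <- svd(q)
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("degenerate geometry: colinear points")
  proj <- q %*% sv$v[, 1:2]                  # in-plane coordinates
  perp <- q %*% sv$v[, 3]                    # signed distance from plane
  dmat <- as.matrix(stats::dist(proj))
  ij <- which(dmat == max(dmat), arr.ind = TRUE)[1, ]
  longest <- dmat[ij[1], ij[2]]
  dir_long <- (proj[ij[2], ] - proj[ij[1], ]) / longest
  dir_perp <- c(-dir_long[2], dir_long[1])
  tcoord <- proj %*% dir_perp
  shortest <- max(tcoord) - min(tcoord)
  structure(list(aspect_ratio = shortest / longest,
                 planarity_pct = 100 * mean(abs(perp)) / longest,
                 rg = sqrt(mean(rowSums(q^2))),
                 longest_axis = longest,
                 shortest_axis = shortest),
            class = "shape_metrics")
}

#' @export
print.shape_metrics <- function(x, ...) {
  cat(sprintf(paste0("<shape_metrics: aspect %.3f, planarity %.1f%%, ",
                     "Rg %.2f nm, axes %.2f x %.2f nm>\n"),
              x$aspect_ratio, x$planarity_pct, x$rg,
              x$longest_axis, x$shortest_axis))
  invisible(x)
}

#' Topology record from base-pair count and linking difference
#'
#' Fixes the arithmetic convention Lk0 = n_bp / helical repeat (relaxed
#' helical repeat 10.5 bp/turn) and the superhelical density
#' sigma = delta Lk / Lk0.
#'
#' @param n_bp number of base pairs (> 0).
#' @param delta_lk linking-number difference from relaxed.
#' @param helical_repeat bp per turn (default 10.5).
#' @param tw,wr optional twist and writhe to carry along (turns).
#' @return A list of class `topology_record` with `n_bp`, `lk`, `lk0`,
#'   `delta_lk`, `sigma`, `tw`, `wr`.
#' @export
sigma_from_topology <- function(n_bp, delta_lk, helical_repeat = 10.5,
                                tw = NA_real_, wr = NA_real_) {
  if (n_bp <= 0) stop("n_bp must be > 0")
  if (helical_repeat == 0) stop("helical repeat must be non-zero")
  lk0 <- n_bp / helical_repeat
  rec <- list(n_bp = as.integer(n_bp), lk = lk0 + delta_lk, lk0 = lk0,
              delta_lk = delta_lk, sigma = delta_lk / lk0, tw = tw, wr = wr)
  if (is.finite(tw) && is.finite(wr) && abs(tw + wr - rec$lk) > 1e-3)
    warning("tw + wr differs from lk beyond tolerance")
  structure(rec, class = "topology_record")
}

#' Helical repeat from a twist count
#'
#' The helical repeat (bp/turn) measured by counting helix turns around a
#' minicircle, e.g. 24 turns counted on a 251 bp minicircle give 10.5 bp/turn,
#' canonical B-form.
#'
#' @param n_bp number of base pairs.
#' @param turns counted number of helix turns.
#' @return bp per turn.
#' @export
helical_repeat <- function(n_bp, turns) {
  if (turns <= 0) stop("turns must be > 0")
  n_bp / turns
}
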