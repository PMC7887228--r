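#' AFM topograph container
#'
#' A 2D height grid in nm with its pixel size. Rows are scan lines (row-major,
#' origin top-left, y increasing downward); all published statistics are in
#' nm via `pixel_size`.
#'
#' @param heights numeric matrix of heights, nm.
#' @param pixel_size nm per pixel (> 0).
#' @param metadata free-form list (simulation seed, planted ground truth, ...).
#' @return An object of class `topograph`.
#' @export
topograph <- function(heights, pixel_size, metadata = list()) {
  heights <- as.matrix(heights)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  stopifnot_finite(heights, "topograph heights")
  structure(list(heights = heights, pixel_size = pixel_size,
                 metadata = metadata),
            class = "topograph")
}

#' @export
print.topograph <- function(x, ...) {
  cat(sprintf("<topograph: %d x %d px, %.3g nm/px, heights %.2f..%.2f nm>\n",
              nrow(x$heights), ncol(x$heights), x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Simulate an AFM topograph of deposited DNA molecules
#'
#' Rasterizes each molecule contour (projected to the image plane) as a tube
#' of the given height and radius, convolves with a Gaussian tip kernel
#' (tip broadening), then adds the classic AFM artefacts: per-scan-line
#' offsets, a linear background tilt across the image, and pixel noise.
#' The metadata records the seed, all planted parameters and per-molecule
#' ground-truth morphometrics (centroid, aspect ratio from the planted
#' contour, contour length), sufficient to recompute every planted
#' morphometric without re-reading the image.
#'
#' @param curves list of [closed_curve()] objects; their x/y coordinates (nm)
#'   must lie inside the field of view with a tube-radius margin.
#' @param pixel_size nm per pixel.
#' @param n_px image size in pixels (square image).
#' @param tip_sigma Gaussian tip broadening sigma, nm (0 disables).
#' @param noise_sd pixel noise standard deviation, nm.
#' @param row_offsets_sd per-scan-line offset standard deviation, nm.
#' @param tilt background tilt, nm per image width.
#' @param molecule_height tube height, nm (DNA measures about 1.5 nm in
#'   liquid AFM); recycled over curves, so a taller sub-contour can model a
#'   bound third strand protruding from the duplex.
#' @param tube_radius tube radius, nm.
#' @param seed integer seed; the simulation is deterministic given it.
#' @return A [topograph()].
#' @export
render_afm_image <- function(curves, pixel_size = 1, n_px = 512,
                             tip_sigma = 1, noise_sd = 0.05,
                             row_offsets_sd = 0, tilt = 0,
                             molecule_height = 1.5, tube_radius = 1,
                             seed = 1) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (tip_sigma < 0) stop("tip_sigma must be >= 0")
  if (inherits(curves, "closed_curve")) curves <- list(curves)
  fov <- n_px * pixel_size
  h <- matrix(0, n_px, n_px)

  truth <- lapply(seq_along(curves), function(k) {
    cur <- curves[[k]]
    xy <- cur$points[, 1:2, drop = FALSE]
    if (any(xy < tube_radius) || any(xy > fov - tube_radius))
      stop(sprintf("curve %d outside the field of view", k))
    sm <- tryCatch(shape_metrics(closed_curve(cbind(xy, 0))),
                   error = function(e) NULL)
    data.frame(id = k,
               centroid_x = mean(xy[, 1]), centroid_y = mean(xy[, 2]),
               aspect_ratio = if (is.null(sm)) NA_real_ else sm$aspect_ratio,
               length_nm = curve_length(cur), closed = cur$closed)
  })
  truth <- do.call(rbind, truth)

  molecule_height <- rep_len(molecule_height, length(curves))
  for (k in seq_along(curves)) {
    xy <- curves[[k]]$points[, 1:2, drop = FALSE]
    h <- pmax(h, rasterize_tube(xy, curves[[k]]$closed, n_px, pixel_size,
                                tube_radius, molecule_height[k]))
  }
  if (tip_sigma > 0)
    h <- gaussian_filter_matrix(h, sigma_px = tip_sigma / pixel_size,
                                truncate_px = 4 * tip_sigma / pixel_size)
  ## artefact order: deterministic tilt, then seeded row offsets and noise
  if (tilt != 0)
    h <- h + matrix(rep(tilt * (seq_len(n_px) - 1) / (n_px - 1), each = n_px),
                    n_px, n_px)
  h <- with_seed(seed, {
    if (row_offsets_sd > 0)
      h <- h + matrix(stats::rnorm(n_px, sd = row_offsets_sd), n_px, n_px,
                      byrow = FALSE)
    if (noise_sd > 0)
      h <- h + matrix(stats::rnorm(n_px * n_px, sd = noise_sd), n_px, n_px)
    h
  })
  topograph(h, pixel_size,
            metadata = list(seed = seed, pixel_size = pixel_size,
                            n_px = n_px, tip_sigma = tip_sigma,
                            noise_sd = noise_sd,
                            row_offsets_sd = row_offsets_sd, tilt = tilt,
                            molecule_height = molecule_height,
                            tube_radius = tube_radius,
                            n_molecules = nrow(truth),
                            molecules = truth))
}

## Mark pixels within `radius` of the (optionally closed) polyline and return
## a height map. Pixel (row r, col c) has centre ((c-0.5), (r-0.5)) * psz with
## x along columns and y along rows.
rasterize_tube <- function(xy, closed, n_px, psz, radius, height) {
  n <- nrow(xy)
  segs <- cbind(xy, xy[c(2:n, 1), , drop = FALSE])
  if (!closed) segs <- segs[-n, , drop = FALSE]
  ## densify: sample each segment at ~psz/4 spacing
  len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  pts <- do.call(rbind, lapply(seq_len(nrow(segs)), function(k) {
    m <- max(1L, ceiling(len[k] / (psz / 4)))
    tt <- seq(0, 1, length.out = m + 1)[-(m + 1)]
    cbind(segs[k, 1] + tt * (segs[k, 3] - segs[k, 1]),
          segs[k, 2] + tt * (segs[k, 4] - segs[k, 2]))
  }))
  w <- ceiling((radius + psz) / psz)
  offs <- expand.grid(dr = -w:w, dc = -w:w)
  h <- matrix(0, n_px, n_px)
  pc <- ceiling(pts[, 1] / psz)              # column of containing pixel
  pr <- ceiling(pts[, 2] / psz)
  for (k in seq_len(nrow(offs))) {
    rr <- pr + offs$dr[k]; cc <- pc + offs$dc[k]
    ok <- rr >= 1 & rr <= n_px & cc >= 1 & cc <= n_px
    if (!any(ok)) next
    cx <- (cc[ok] - 0.5) * psz; cy <- (rr[ok] - 0.5) * psz
    inside <- (cx - pts[ok, 1])^2 + (cy - pts[ok, 2])^2 <= radius^2
    if (any(inside))
      h[cbind(rr[ok][inside], cc[ok][inside])] <- height
  }
  h
}
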