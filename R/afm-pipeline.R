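## ---- shared raster helpers -------------------------------------------

## Separable Gaussian convolution with periodic padding (preserves the image
## mean exactly); kernel truncated at truncate_px.
gaussian_filter_matrix <- function(m, sigma_px, truncate_px = 3.5) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, floor(truncate_px))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(x) {           # circular convolution along rows of x
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (d in -r:r) out <- out + k[d + r + 1] * x[cyc(seq_len(n) + d, n), ,
                                                  drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

#' Flatten an AFM topograph
#'
#' The standard AFM image corrections: per-scan-line (row) median subtraction
#' to remove offsets between scan lines ("align rows"), removal of the sample
#' tilt as a first-order polynomial ("level"; the scan-direction component is
#' absorbed by the row medians, the slow-axis component by a line fitted to
#' the column medians), and a zero-mean shift so that the background sits at
#' 0 nm. Medians, not means, so that raised molecules do not bias the
#' background estimate. The two median corrections are iterated to a joint
#' fixed point, which makes the operation idempotent to numerical precision.
#'
#' @param topo a [topograph()] with at least 8 x 8 pixels.
#' @return The flattened [topograph()].
#' @export
flatten_topograph <- function(topo) {
  stopifnot(inherits(topo, "topograph"))
  h <- topo$heights
  if (nrow(h) < 8 || ncol(h) < 8) stop("image must be at least 8 x 8 pixels")
  nc <- ncol(h)
  jj <- seq_len(nc) - (nc + 1) / 2
  for (iter in 1:100) {
    rowmed <- apply(h, 1, stats::median)
    h <- h - rowmed
    colmed <- apply(h, 2, stats::median)
    fit <- stats::lm.fit(cbind(1, jj), colmed)$fitted.values
    h <- h - rep(fit, each = nrow(h))
    if (max(abs(rowmed)) < 1e-12 && max(abs(fit)) < 1e-12) break
  }
  h <- h - mean(h)
  topograph(h, topo$pixel_size, topo$metadata)
}

#' Gaussian-smooth an AFM topograph
#'
#' Removes pixel errors and high-frequency noise with a Gaussian filter of
#' sigma 1.5 pixels truncated at 3.5 pixels (1-2 nm at typical scan
#' resolutions). The image mean is preserved.
#'
#' @param topo a [topograph()].
#' @param sigma_px Gaussian sigma in pixels (default 1.5).
#' @param truncate_px kernel truncation radius in pixels (default 3.5).
#' @return The smoothed [topograph()].
#' @export
smooth_topograph <- function(topo, sigma_px = 1.5, truncate_px = 3.5) {
  stopifnot(inherits(topo, "topograph"))
  if (sigma_px <= 0) stop("sigma_px must be > 0")
  topograph(gaussian_filter_matrix(topo$heights, sigma_px, truncate_px),
            topo$pixel_size, topo$metadata)
}

#' Mask molecules and label connected components
#'
#' Masks pixels whose height exceeds the image mean by more than
#' `sigma_mult` standard deviations (one-sided: deposited molecules are
#' raised above the flattened background) and labels connected components
#' (grains).
#'
#' @param topo a flattened [topograph()].
#' @param sigma_mult threshold in standard deviations above the mean
#'   (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix (0 = background) with attributes
#'   `pixel_size` and `n_grains`.
#' @export
mask_and_label <- function(topo, sigma_mult = 1, connectivity = 8) {
  stopifnot(inherits(topo, "topograph"))
  h <- topo$heights
  mask <- h > mean(h) + sigma_mult * stats::sd(h)
  lab <- label_components(mask, connectivity)
  attr(lab, "pixel_size") <- topo$pixel_size
  attr(lab, "n_grains") <- max(lab)
  lab
}

## Connected-component labelling on a logical matrix via igraph: nodes are
## mask pixels, edges join neighbouring mask pixels.
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  px <- which(mask)
  if (!length(px)) return(lab)
  id <- matrix(0L, nr, nc)
  id[px] <- seq_along(px)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  r0 <- ((px - 1L) %% nr) + 1L
  c0 <- ((px - 1L) %/% nr) + 1L
  edges <- integer(0)
  for (o in offs) {
    r1 <- r0 + o[1]; c1 <- c0 + o[2]
    ok <- r1 >= 1 & r1 <= nr & c1 >= 1 & c1 <= nc
    nb <- id[cbind(r1[ok], c1[ok])]
    has <- nb > 0L
    if (any(has))
      edges <- c(edges, rbind(id[px[ok][has]], nb[has]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(px) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(px)]
  lab[px] <- as.integer(comp)
  lab
}

#' Filter grains by border contact, area floor and median band
#'
#' The grain-cleaning sequence applied in this fixed order: (1) grains
#' touching the image border (incomplete molecules) are removed; (2) grains
#' smaller than `min_area_nm2` (200 nm^2) are removed; (3) the median area
#' of the remaining grains is computed once, and grains outside
#' `median_band` (50-150%) of that median are removed.
#'
#' @param labelled label matrix from [mask_and_label()].
#' @param pixel_size nm per pixel (default: taken from the label attributes).
#' @param min_area_nm2 area floor, nm^2 (default 200).
#' @param remove_border drop border-touching grains (default TRUE)?
#' @param median_band numeric length-2 multiplier band around the median
#'   grain area (default `c(0.5, 1.5)`).
#' @return Relabelled matrix (labels compacted to 1..k) with attribute
#'   `removed`, a data.frame of removed grain ids and reasons.
#' @export
filter_grains <- function(labelled, pixel_size = attr(labelled, "pixel_size"),
                          min_area_nm2 = 200, remove_border = TRUE,
                          median_band = c(0.5, 1.5)) {
  if (is.null(pixel_size)) stop("pixel_size required")
  nlab <- max(labelled)
  if (nlab == 0) return(labelled)
  ids <- seq_len(nlab)
  areas <- tabulate(labelled[labelled > 0], nbins = nlab) * pixel_size^2
  border <- unique(c(labelled[1, ], labelled[nrow(labelled), ],
                     labelled[, 1], labelled[, ncol(labelled)]))
  border <- border[border > 0]
  removed <- data.frame(id = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- rep(TRUE, nlab)
  if (remove_border && length(border)) {
    keep[border] <- FALSE
    removed <- rbind(removed, data.frame(id = border, reason = "border"))
  }
  small <- ids[keep & areas < min_area_nm2]
  if (length(small)) {
    keep[small] <- FALSE
    removed <- rbind(removed, data.frame(id = small, reason = "min_area"))
  }
  if (any(keep) && !is.null(median_band)) {
    med <- stats::median(areas[keep])          # computed once, after the floor
    out_band <- ids[keep & (areas < median_band[1] * med |
                              areas > median_band[2] * med)]
    if (length(out_band)) {
      keep[out_band] <- FALSE
      removed <- rbind(removed,
                       data.frame(id = out_band, reason = "median_band"))
    }
  }
  map <- integer(nlab)
  map[ids[keep]] <- seq_len(sum(keep))
  out <- labelled
  out[out > 0] <- map[out[out > 0]]
  attr(out, "pixel_size") <- pixel_size
  attr(out, "n_grains") <- sum(keep)
  attr(out, "removed") <- removed
  out
}

#' Per-grain morphometrics
#'
#' For each labelled grain: area (pixel count x pixel area), centroid (nm),
#' longest axis (maximum pairwise distance between boundary pixel centres),
#' shortest axis (maximal extent perpendicular to the longest-axis
#' direction), aspect ratio (shortest/longest, in (0,1]), mean and maximum
#' height over the grain, and whether it touches the image border.
#'
#' @param labelled label matrix ([mask_and_label()] / [filter_grains()]).
#' @param topo the [topograph()] the labels refer to.
#' @return data.frame of class `grain_records`, one row per grain.
#' @export
grain_stats <- function(labelled, topo) {
  stopifnot(inherits(topo, "topograph"))
  psz <- topo$pixel_size
  nlab <- max(labelled)
  h <- topo$heights
  nr <- nrow(labelled); nc <- ncol(labelled)
  rows <- lapply(seq_len(nlab), function(id) {
    px <- which(labelled == id)
    r <- ((px - 1L) %% nr) + 1L
    c <- ((px - 1L) %/% nr) + 1L
    x <- (c - 0.5) * psz; y <- (r - 0.5) * psz
    ## boundary pixels: any 4-neighbour outside the grain (or image edge)
    ing <- function(rr, cc) rr >= 1 & rr <= nr & cc >= 1 & cc <= nc &
      labelled[cbind(pmin(pmax(rr, 1), nr), pmin(pmax(cc, 1), nc))] == id
    bnd <- !(ing(r - 1, c) & ing(r + 1, c) & ing(r, c - 1) & ing(r, c + 1))
    xb <- x[bnd]; yb <- y[bnd]
    if (length(xb) >= 2) {
      dm <- as.matrix(stats::dist(cbind(xb, yb)))
      ij <- which(dm == max(dm), arr.ind = TRUE)[1, ]
      longest <- dm[ij[1], ij[2]]
      dl <- c(xb[ij[2]] - xb[ij[1]], yb[ij[2]] - yb[ij[1]]) / longest
      tp <- cbind(xb, yb) %*% c(-dl[2], dl[1])
      shortest <- max(tp) - min(tp)
      longest <- longest + psz          # extreme pixel centres -> outer edges
      shortest <- shortest + psz
    } else longest <- shortest <- psz
    data.frame(label = id, area = length(px) * psz^2,
               centroid_x = mean(x), centroid_y = mean(y),
               longest_axis = longest, shortest_axis = shortest,
               aspect_ratio = shortest / longest,
               mean_height = mean(h[px]), max_height = max(h[px]),
               touches_border = any(r == 1 | r == nr | c == 1 | c == nc))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(label = integer(0), area = numeric(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      longest_axis = numeric(0), shortest_axis = numeric(0),
                      aspect_ratio = numeric(0), mean_height = numeric(0),
                      max_height = numeric(0), touches_border = logical(0))
  class(out) <- c("grain_records", class(out))
  out
}

#' Crop square sub-images around grain centroids
#'
#' One square crop of side `crop_nm` (80 nm by default) per grain, centred on
#' the grain centroid; crops running over the image edge are clipped and
#' flagged.
#'
#' @param topo a [topograph()].
#' @param records `grain_records` from [grain_stats()].
#' @param crop_nm crop side length, nm (default 80).
#' @return List of [topograph()] crops; each carries `grain_id` and
#'   `clipped` in its metadata.
#' @export
crop_grains <- function(topo, records, crop_nm = 80) {
  stopifnot(inherits(topo, "topograph"))
  psz <- topo$pixel_size
  half <- round(crop_nm / psz / 2)
  nr <- nrow(topo$heights); nc <- ncol(topo$heights)
  lapply(seq_len(nrow(records)), function(k) {
    rc <- round(records$centroid_y[k] / psz)
    cc <- round(records$centroid_x[k] / psz)
    r0 <- rc - half + 1; r1 <- rc + half
    c0 <- cc - half + 1; c1 <- cc + half
    clipped <- r0 < 1 || c0 < 1 || r1 > nr || c1 > nc
    sub <- topo$heights[max(1, r0):min(nr, r1), max(1, c0):min(nc, c1),
                        drop = FALSE]
    topograph(sub, psz, metadata = list(grain_id = records$label[k],
                                        clipped = clipped,
                                        origin_nm = c((max(1, c0) - 1) * psz,
                                                      (max(1, r0) - 1) * psz)))
  })
}
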