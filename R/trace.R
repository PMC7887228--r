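## ---- morphological thinning (Zhang-Suen) ------------------------------

## Thin a logical matrix to a 1-pixel-wide 8-connected skeleton.
skeletonize_mask <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  m <- pad
  shift <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
      if (phase == 1) {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nr + 1), 2:(nc + 1)]
}

## number of 8-neighbours of each skeleton pixel
skeleton_degree <- function(sk) {
  deg <- matrix(0L, nrow(sk), ncol(sk))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- nrow(sk); nc <- ncol(sk)
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    sh[rs, cs] <- sk[rs + dr, cs + dc]
    deg <- deg + sh
  }
  deg * sk
}

## Crossing number: count of 0->1 transitions in the circular neighbour ring.
## 1 = endpoint, 2 = simple path (staircase corners included), >= 3 = branch.
skeleton_crossings <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  sh <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- sk[rs + dr, cs + dc]
    out
  }
  ring <- list(sh(-1, 0), sh(-1, 1), sh(0, 1), sh(1, 1),
               sh(1, 0), sh(1, -1), sh(0, -1), sh(-1, -1), sh(-1, 0))
  A <- matrix(0L, nr, nc)
  for (k in 1:8) A <- A + (!ring[[k]] & ring[[k + 1]])
  A * sk
}

## prune short spurs (branches from a junction ending in an endpoint)
prune_spurs <- function(sk, max_len = 6) {
  repeat {
    deg <- skeleton_degree(sk)
    ends <- which(sk & deg == 1)
    if (!length(ends)) return(sk)
    removed_any <- FALSE
    for (e in ends) {
      path <- integer(0)
      cur <- e
      prev <- -1L
      for (step in seq_len(max_len + 1)) {
        path <- c(path, cur)
        nb <- pixel_neighbours(cur, sk)
        nb <- setdiff(nb, prev)
        if (length(nb) != 1) break
        if (skeleton_crossings(sk)[nb] >= 3) {  # reached a junction: spur

          if (length(path) <= max_len) {
            sk[path] <- FALSE
            removed_any <- TRUE
          }
          path <- NULL
          break
        }
        prev <- cur
        cur <- nb
      }
    }
    if (!removed_any) return(sk)
  }
}

pixel_neighbours <- function(px, sk) {
  nr <- nrow(sk)
  r <- ((px - 1L) %% nr) + 1L
  c <- ((px - 1L) %/% nr) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= ncol(sk) && sk[rr, cc])
      out <- c(out, (cc - 1L) * nr + rr)
  }
  out
}

skeleton_degree_at <- function(sk, px) length(pixel_neighbours(px, sk))

## ---- tracing ----------------------------------------------------------

#' Trace a single molecule in a cropped topograph
#'
#' Masks the molecule (half-maximum height threshold), thins the mask to a
#' 1-pixel skeleton, orders the skeleton pixels into a path (closed when no
#' endpoints remain), smooths the path with a short moving average to remove
#' pixel staircase bias, and fits maximal straight segments (RMS orthogonal
#' deviation < 1 pixel) of at least `min_segment_nm` (5 nm, about one and a
#' half DNA turns). Angles between consecutive straight segments are
#' reported as the directional change in degrees. The height profile along
#' the path is sampled from the image by bilinear interpolation.
#'
#' @param crop a [topograph()] containing exactly one molecule.
#' @param min_segment_nm minimum straight-segment length, nm (default 5).
#' @param mask_frac mask threshold as a fraction of the maximum height above
#'   the background median (default 0.5).
#' @param smooth_window odd moving-average window for the path, in points.
#' @return An object of class `molecule_trace`: `path` (nm), `closed`,
#'   `heights` (nm along the path), `length_nm`, `segments` (data.frame) and
#'   `angles` (degrees between consecutive segments).
#' @export
trace_molecule <- function(crop, min_segment_nm = 5, mask_frac = 0.5,
                           smooth_window = 7) {
  stopifnot(inherits(crop, "topograph"))
  h <- crop$heights
  psz <- crop$pixel_size
  base <- stats::median(h)
  mask <- h > base + mask_frac * (max(h) - base)
  lab <- label_components(mask, 8)
  if (max(lab) == 0) stop("trace error: no molecule found in crop")
  main <- which.max(tabulate(lab[lab > 0]))
  sk <- skeletonize_mask(lab == main)
  sk <- prune_spurs(sk)
  deg <- skeleton_degree(sk)
  branches <- sum(skeleton_crossings(sk) >= 3)
  if (branches > 0)
    stop(sprintf("trace error: branched skeleton (%d branch pixels)",
                 branches))
  px <- which(sk)
  if (length(px) < 5) stop("trace error: skeleton too short")
  ends <- which(sk & deg == 1)
  closed <- length(ends) == 0

  ## walk the path
  start <- if (closed) px[1] else ends[1]
  n <- length(px)
  path_px <- integer(n)
  visited <- matrix(FALSE, nrow(sk), ncol(sk))
  cur <- start
  for (k in seq_len(n)) {
    path_px[k] <- cur
    visited[cur] <- TRUE
    nb <- pixel_neighbours(cur, sk)
    nb <- nb[!visited[nb]]
    if (!length(nb)) { path_px <- path_px[seq_len(k)]; break }
    if (length(nb) > 1) {          # prefer 4-connected continuation
      nr <- nrow(sk)
      rc <- ((cur - 1L) %% nr) + 1L; cc <- ((cur - 1L) %/% nr) + 1L
      rb <- ((nb - 1L) %% nr) + 1L; cb <- ((nb - 1L) %/% nr) + 1L
      nb <- nb[order(abs(rb - rc) + abs(cb - cc))]
    }
    cur <- nb[1]
  }
  nr <- nrow(sk)
  rr <- ((path_px - 1L) %% nr) + 1L
  cc <- ((path_px - 1L) %/% nr) + 1L
  path <- cbind(x = (cc - 0.5) * psz, y = (rr - 0.5) * psz)

  ## moving-average smoothing removes the staircase length bias
  w <- smooth_window
  if (w > 1 && nrow(path) > w) {
    half <- (w - 1) %/% 2
    np <- nrow(path)
    sm <- path
    for (k in seq_len(np)) {
      idx <- k + (-half:half)
      if (closed) idx <- cyc(idx, np) else idx <- idx[idx >= 1 & idx <= np]
      sm[k, ] <- colMeans(path[idx, , drop = FALSE])
    }
    path <- sm
  }

  ## skeletonization retreats from the tips of open molecules by about the
  ## local half-width; extend each end along its direction while still on
  ## the mask so the traced length covers the whole molecule
  if (!closed && nrow(path) > 5) {
    on_mask <- function(p) {
      cpx <- ceiling(p[1] / psz); rpx <- ceiling(p[2] / psz)
      cpx >= 1 && cpx <= ncol(mask) && rpx >= 1 && rpx <= nrow(mask) &&
        mask[rpx, cpx]
    }
    extend <- function(path, head) {
      if (head) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
      np0 <- nrow(path)
      dir <- path[np0, ] - path[np0 - 4, ]
      dir <- dir / sqrt(sum(dir^2))
      p <- path[np0, ]
      for (s in seq_len(30)) {
        q <- p + 0.5 * psz * dir
        if (!on_mask(q)) break
        p <- q
        path <- rbind(path, q)
      }
      if (head) path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
      path
    }
    path <- extend(extend(path, head = FALSE), head = TRUE)
  }

  dseg <- diff(rbind(path, if (closed) path[1, , drop = FALSE]))
  step_len <- sqrt(rowSums(dseg^2))
  length_nm <- sum(step_len)

  heights <- bilinear_sample(h, path / psz)
  segments <- fit_straight_segments(path, closed, min_segment_nm,
                                    max_rms = psz)
  angles <- segment_angles(segments)
  structure(list(path = path, closed = closed, heights = heights,
                 length_nm = length_nm, segments = segments,
                 angles = angles, pixel_size = psz),
            class = "molecule_trace")
}

#' @export
print.molecule_trace <- function(x, ...) {
  cat(sprintf("<molecule_trace: %s, %.1f nm, %d straight segments>\n",
              if (x$closed) "closed" else "open", x$length_nm,
              nrow(x$segments)))
  invisible(x)
}

## sample matrix h (row=y, col=x; pixel centres at (i-0.5)) at fractional
## pixel coordinates xy (columns x, y)
bilinear_sample <- function(h, xy) {
  nr <- nrow(h); nc <- ncol(h)
  x <- clamp(xy[, 1] - 0.5, 0, nc - 1)
  y <- clamp(xy[, 2] - 0.5, 0, nr - 1)
  c0 <- clamp(floor(x) + 1, 1, nc); c1 <- clamp(c0 + 1, 1, nc)
  r0 <- clamp(floor(y) + 1, 1, nr); r1 <- clamp(r0 + 1, 1, nr)
  fx <- x - (c0 - 1); fy <- y - (r0 - 1)
  h[cbind(r0, c0)] * (1 - fx) * (1 - fy) + h[cbind(r0, c1)] * fx * (1 - fy) +
    h[cbind(r1, c0)] * (1 - fx) * fy + h[cbind(r1, c1)] * fx * fy
}

## Greedy maximal straight runs: extend while the RMS orthogonal deviation of
## the run to its best-fit line stays below max_rms; keep runs >= min_len.
fit_straight_segments <- function(path, closed, min_len, max_rms) {
  np <- nrow(path)
  pts <- if (closed) rbind(path, path) else path    # allow wrap-around runs
  limit <- if (closed) np else np
  segs <- list()
  start <- 1
  used_end <- 0
  while (start <= limit) {
    end <- start + 1
    best_end <- start
    while (end <= nrow(pts) && (end - start) < limit) {
      seg <- pts[start:end, , drop = FALSE]
      if (line_rms(seg) < max_rms) best_end <- end else break
      end <- end + 1
    }
    seg <- pts[start:best_end, , drop = FALSE]
    len <- sum(sqrt(rowSums(diff(seg)^2)))
    if (best_end > start && len >= min_len) {
      d <- seg[nrow(seg), ] - seg[1, ]
      segs <- c(segs, list(data.frame(
        start_idx = cyc(start, np) - 1L, end_idx = cyc(best_end, np) - 1L,
        length_nm = len,
        dir_x = d[1] / sqrt(sum(d^2)), dir_y = d[2] / sqrt(sum(d^2)))))
      start <- best_end + 1
    } else start <- start + 1
    if (closed && start > np) break
  }
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(start_idx = integer(0), end_idx = integer(0),
                      length_nm = numeric(0), dir_x = numeric(0),
                      dir_y = numeric(0))
  out
}

line_rms <- function(seg) {
  q <- sweep(seg, 2, colMeans(seg))
  sv <- svd(q)
  if (length(sv$d) < 2) return(0)
  sqrt(sum((q %*% sv$v[, 2])^2) / nrow(seg))
}

segment_angles <- function(segments) {
  k <- nrow(segments)
  if (k < 2) return(numeric(0))
  d <- as.matrix(segments[, c("dir_x", "dir_y")])
  dots <- rowSums(d[-k, , drop = FALSE] * d[-1, , drop = FALSE])
  deg(acos(clamp(dots, -1, 1)))
}

#' Locate a height protrusion along a molecule trace
#'
#' Finds the maximal contiguous run of path points whose height exceeds the
#' baseline (median path height) by more than the threshold; on closed traces
#' the run may wrap across the index origin. Triplex third strands show up as
#' such sub-nanometre protrusions on traced minicircles.
#'
#' @param trace a [trace_molecule()] result carrying a height profile.
#' @param height_threshold_nm threshold above the baseline median, nm.
#' @return `NULL` when no run is found, otherwise a list with `start_frac`,
#'   `length_frac` (fractions of the total trace length) and `length_nm`.
#' @export
locate_protrusion <- function(trace, height_threshold_nm = 0.3) {
  stopifnot(inherits(trace, "molecule_trace"))
  hh <- trace$heights
  base <- stats::median(hh)
  above <- hh > base + height_threshold_nm
  if (!any(above)) return(NULL)
  runs <- if (trace$closed) circular_runs(above) else {
    r <- rle(above)
    st <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
    Filter(Negate(is.null),
           Map(function(s, l, v) if (v) list(start = s, length = l),
               st, r$lengths, r$values))
  }
  lens <- vapply(runs, `[[`, numeric(1), "length")
  run <- runs[[which.max(lens)]]
  np <- nrow(trace$path)
  idx <- if (trace$closed) cyc(run$start + seq_len(run$length) - 1, np) else
    run$start + seq_len(run$length) - 1
  pp <- trace$path[idx, , drop = FALSE]
  run_len <- sum(sqrt(rowSums(diff(pp)^2)))
  ## wrap-around runs have one long jump in diff(); measure via step lengths
  if (trace$closed) {
    steps <- sqrt(rowSums((trace$path[cyc(idx + 1, np), , drop = FALSE] -
                             trace$path[idx, , drop = FALSE])^2))
    run_len <- sum(steps[-length(steps)])
  }
  list(start_frac = (run$start - 1) / np,
       length_frac = run_len / trace$length_nm,
       length_nm = run_len)
}
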