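#' Helical-axis contour of a pseudo-atomic model
#'
#' Extracts a smoothed helical-axis contour with one point per base pair: the
#' weighted circular-window average of the Watson-Crick base-pair midpoints.
#' The window spans about one helical turn (11 bp by default), which averages
#' out the helical wobble of individual base pairs so that downstream bending
#' and writhe statistics see the axis, not the helix. Flipped (bubble) base
#' pairs are excluded from the midpoints and the window weights renormalized
#' over the remaining members.
#'
#' @param model a `pseudo_atomic_model` with a paired duplex over at least
#'   `window_bp` base pairs.
#' @param window_bp odd window width in bp (>= 3, default 11).
#' @param weighting `"uniform"` or `"cosine"` (cosine-tapered Hann window).
#' @return A [closed_curve()] in nm (closed iff the model is circular), with
#'   0-based bp labels.
#' @export
helical_axis <- function(model, window_bp = 11,
                         weighting = c("uniform", "cosine")) {
  stopifnot(inherits(model, "pseudo_atomic_model"))
  weighting <- match.arg(weighting)
  window_bp <- as.integer(window_bp)
  if (window_bp < 3 || window_bp %% 2 == 0)
    stop("window_bp must be odd and >= 3")
  n <- model$n_bp
  if (window_bp > n) stop("window larger than the molecule")

  at <- model$atoms
  getB <- function(chain) {
    sel <- at$chain == chain & at$name == "B"
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    xyz[order(at$resid[sel]), , drop = FALSE]
  }
  mid <- (getB("A") + getB("B")) / 2                 # Angstrom
  ok <- model$pairing != "flipped"
  if (sum(ok) < window_bp) stop("model must have a paired duplex over the window")

  half <- (window_bp - 1L) / 2L
  offs <- -half:half
  w <- if (weighting == "uniform") rep(1, window_bp) else
    0.5 * (1 + cos(2 * pi * offs / window_bp))
  axis <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    idx <- if (model$circular) cyc(i + offs, n) else (i + offs)
    if (!model$circular) {
      keep <- idx >= 1 & idx <= n
      idx <- idx[keep]; ww <- w[keep]
    } else ww <- w
    use <- ok[idx]
    if (!any(use)) { axis[i, ] <- mid[i, ]; next }
    ww <- ww[use] / sum(ww[use])
    axis[i, ] <- colSums(mid[idx[use], , drop = FALSE] * ww)
  }
  closed_curve(axis / 10, closed = model$circular, labels = seq_len(n) - 1L)
}
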