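#' Default pseudo-atom parameter table
#'
#' Coarse-grained nucleotide model: three pseudo-atoms per nucleotide
#' (phosphate `P`, sugar centroid `S`, base centroid `B`). Charges are in
#' elementary charges: the phosphate carries the full -1 e backbone charge;
#' base centroids carry small partial charges per base type (the protonated
#' cytosine of a pyrimidine third strand is distinctly positive, which is what
#' lets it act as a Hoogsteen donor towards guanine). Lennard-Jones types are
#' per pseudo-atom kind. Base atoms are hydrogen-bond donors and acceptors
#' (hydrogens are implicit; the sugar is the donor antecedent used for the
#' angle); phosphates are acceptors only.
#'
#' @return A list with `base_charges`, `tfo_base_charges`, `atom_charges`,
#'   `lj` (per-type sigma/epsilon, Angstrom and kcal/mol) and geometry
#'   constants used by [build_minicircle_model()].
#' @export
pseudo_atom_params <- function() {
  list(
    base_charges = c(A = 0.06, T = -0.06, G = -0.10, C = 0.10),
    tfo_base_charges = c(C = 0.25, T = -0.06),   # C is protonated (C+)
    atom_charges = c(P = -1, S = 0),
    lj = data.frame(type = c("P", "S", "B"),
                    sigma = c(4.0, 3.5, 2.5),
                    epsilon = c(0.2, 0.1, 0.1),
                    stringsAsFactors = FALSE),
    donors = "B", acceptors = c("B", "P"), antecedent = c(B = "S"),
    rise = 3.4,            # Angstrom per bp
    relaxed_repeat = 10.5, # bp per turn
    r_base = 1.45, r_sugar = 7.0, r_phos = 9.5,  # Angstrom from the axis
    bubble_push = 8.0,     # Angstrom radial base displacement in a bubble
    kink1_push = 4.5,      # Angstrom lateral base displacement (type I kink)
    kink2_pull = 1.5       # Angstrom strand separation (type II kink)
  )
}

#' Build a pseudo-atomic closed-circular DNA (minicircle) model
#'
#' Lays a coarse-grained duplex on an ideal circular axis (rise 0.34 nm/bp;
#' helical repeat 10.5 bp/turn, modified by the imposed linking difference so
#' that the twist change is distributed uniformly), optionally with planted
#' defects and a major-groove third strand:
#'
#' * `bubble` (span >= 2): base pairs flipped out of the duplex - both base
#'   centroids displaced radially by 0.8 nm, beyond the hydrogen-bond cutoff
#'   and the flipped-base threshold.
#' * `kink1` (span 1): a single base pair with broken pairing and broken
#'   stacking (one base displaced laterally), plus a local bend of the axis.
#' * `kink2` (span 2): two consecutive base pairs with broken Watson-Crick
#'   hydrogen bonds whose bases stay within stacking distance of their 5'
#'   neighbours (strands pulled apart along the base-pair long axis), plus a
#'   local axis bend.
#'
#' When `with_tfo` is set, a pyrimidine third-strand residue is placed in the
#' major groove of every base pair of the triplex-binding site (TBS), with
#' Hoogsteen donor-acceptor distances of 2.9 Angstrom (<= 3.0).
#'
#' @param n_bp number of base pairs (>= 60).
#' @param delta_lk linking-number difference from the relaxed topoisomer.
#' @param defects list of defects, each `list(span = c(start, length), kind =
#'   "bubble"|"kink1"|"kink2", angle = <optional axis bend, degrees>)`; spans
#'   are 0-based circular bp indices and must be disjoint.
#' @param with_tfo place a (CT)-type third strand over the TBS?
#' @param tbs 0-based `c(start, length)` span of the triplex-binding site
#'   (default: 16 bp starting opposite bp 0).
#' @param seed integer seed for the (sequence) randomness; the model geometry
#'   is deterministic given its arguments.
#' @param params parameter table from [pseudo_atom_params()].
#' @param axis_curve optional closed [closed_curve()] (nm) to lay the duplex
#'   on instead of the ideal planar circle (e.g. a writhed solenoid).
#' @return An object of class `pseudo_atomic_model`.
#' @export
build_minicircle_model <- function(n_bp, delta_lk = 0, defects = list(),
                                   with_tfo = FALSE, tbs = NULL, seed = 1,
                                   params = pseudo_atom_params(),
                                   axis_curve = NULL) {
  if (n_bp < 60) stop("n_bp must be >= 60")
  n_bp <- as.integer(n_bp)
  defects <- validate_defects(defects, n_bp)
  if (with_tfo && is.null(tbs)) tbs <- c(n_bp %/% 2, 16L)
  if (!is.null(tbs)) {
    tbs <- as.integer(tbs)
    if (tbs[2] < 1 || tbs[2] > n_bp) stop("invalid tbs span")
  }

  ## --- axis ------------------------------------------------------------
  if (is.null(axis_curve)) {
    radius_nm <- params$rise * n_bp / (2 * pi) / 10
    axis_curve <- make_planar_circle(n_bp, radius_nm)
    for (d in defects) {
      ang <- d$angle %||% switch(d$kind, kink1 = 110, kink2 = 100, bubble = 0)
      ## The axis bend is spread over a few bp so that per-step bending stays
      ## compatible with intact stacking right next to the defect. Some
      ## crowded multi-kink configurations admit no closed ring at uniform
      ## spacing; the hinge is cosmetic for defect detection (the broken
      ## pairing/stacking displacements carry the signal), so such defects
      ## fall back to an unbent axis.
      if (ang > 0)
        axis_curve <- tryCatch(
          inject_kink(axis_curve, d$span[1], ang, span = d$span[2] + 6L),
          error = function(e) axis_curve)
    }
  } else {
    stopifnot(inherits(axis_curve, "closed_curve"), axis_curve$closed)
    if (nrow(axis_curve$points) != n_bp)
      stop("axis_curve must have one point per base pair")
  }
  ctr <- axis_curve$points * 10                 # nm -> Angstrom
  tng <- curve_tangents(axis_curve)
  up <- parallel_transport_normals(axis_curve)  # z-like reference field

  ## --- frames and helix phase ------------------------------------------
  lk0 <- n_bp / params$relaxed_repeat
  h_eff <- n_bp / (lk0 + delta_lk)              # bp/turn actually imposed
  psi <- 2 * pi * (seq_len(n_bp) - 1) / h_eff
  m <- row_cross(tng, up)                       # radial-like direction
  a <- cos(psi) * m + sin(psi) * up             # base-pair long axis
  b <- row_cross(tng, a)                        # groove direction

  ## --- sequence ---------------------------------------------------------
  seqA <- with_seed(seed, sample(c("A", "T", "G", "C"), n_bp, replace = TRUE))
  if (!is.null(tbs)) {
    idx <- cyc(tbs[1] + seq_len(tbs[2]), n_bp)
    seqA[idx] <- rep(c("G", "A"), length.out = tbs[2])
  }
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  seqB <- unname(comp[seqA])

  ## --- duplex atoms ------------------------------------------------------
  g <- params
  baseA <- ctr + g$r_base * a;  baseB <- ctr - g$r_base * a
  sugA <- ctr + g$r_sugar * a;  sugB <- ctr - g$r_sugar * a
  phoA <- ctr + g$r_phos * a + 1.0 * tng
  phoB <- ctr - g$r_phos * a - 1.0 * tng

  pairing <- rep("paired", n_bp)
  for (d in defects) {
    idx <- cyc(d$span[1] + seq_len(d$span[2]), n_bp)
    if (d$kind == "bubble") {
      baseA[idx, ] <- baseA[idx, ] + g$bubble_push * a[idx, , drop = FALSE]
      baseB[idx, ] <- baseB[idx, ] - g$bubble_push * a[idx, , drop = FALSE]
      pairing[idx] <- "flipped"
    } else if (d$kind == "kink1") {
      baseA[idx, ] <- baseA[idx, ] + g$kink1_push * b[idx, , drop = FALSE]
      pairing[idx] <- "broken"
    } else if (d$kind == "kink2") {
      baseA[idx, ] <- baseA[idx, ] + g$kink2_pull * a[idx, , drop = FALSE]
      baseB[idx, ] <- baseB[idx, ] - g$kink2_pull * a[idx, , drop = FALSE]
      pairing[idx] <- "broken"
    }
  }

  mk <- function(chain, name, xyz, charge, base) {
    data.frame(chain = chain, resid = seq_len(n_bp), base = base, name = name,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               charge = charge, type = substr(name, 1, 1),
               stringsAsFactors = FALSE)
  }
  qA <- unname(params$base_charges[seqA])
  qB <- unname(params$base_charges[seqB])
  atoms <- rbind(
    mk("A", "P", phoA, params$atom_charges[["P"]], seqA),
    mk("A", "S", sugA, params$atom_charges[["S"]], seqA),
    mk("A", "B", baseA, qA, seqA),
    mk("B", "P", phoB, params$atom_charges[["P"]], seqB),
    mk("B", "S", sugB, params$atom_charges[["S"]], seqB),
    mk("B", "B", baseB, qB, seqB))

  seqT <- NULL
  if (with_tfo) {
    idx <- cyc(tbs[1] + seq_len(tbs[2]), n_bp)
    ## Hoogsteen partner of the purine strand base, approached from the groove
    seqT <- ifelse(seqA[idx] == "G", "C", "T")
    bT <- b[idx, , drop = FALSE]
    tT <- tng[idx, , drop = FALSE]
    baseT <- baseA[idx, , drop = FALSE] + 2.9 * bT
    sugT <- baseT + 4.0 * bT
    phoT <- baseT + 6.5 * bT + 1.0 * tT
    qT <- unname(params$tfo_base_charges[seqT])
    at <- rbind(
      data.frame(chain = "T", resid = idx, base = seqT, name = "P",
                 x = phoT[, 1], y = phoT[, 2], z = phoT[, 3],
                 charge = params$atom_charges[["P"]], type = "P",
                 stringsAsFactors = FALSE),
      data.frame(chain = "T", resid = idx, base = seqT, name = "S",
                 x = sugT[, 1], y = sugT[, 2], z = sugT[, 3],
                 charge = params$atom_charges[["S"]], type = "S",
                 stringsAsFactors = FALSE),
      data.frame(chain = "T", resid = idx, base = seqT, name = "B",
                 x = baseT[, 1], y = baseT[, 2], z = baseT[, 3],
                 charge = qT, type = "B", stringsAsFactors = FALSE))
    atoms <- rbind(atoms, at)
  }
  rownames(atoms) <- NULL

  structure(list(
    n_bp = n_bp, circular = TRUE,
    sequence = list(A = seqA, B = seqB, T = seqT),
    atoms = atoms,
    frame_origin = ctr, frame_normal = tng, frame_long = a,
    pairing = pairing,
    tbs = if (is.null(tbs)) NULL else tbs,
    delta_lk = delta_lk, helical_repeat = params$relaxed_repeat,
    defects = defects, seed = seed,
    axis = axis_curve),
    class = "pseudo_atomic_model")
}

validate_defects <- function(defects, n_bp) {
  if (length(defects) == 0) return(list())
  occupied <- integer(0)
  out <- lapply(defects, function(d) {
    if (is.null(d$span) || is.null(d$kind)) stop("defect needs span and kind")
    kind <- match.arg(d$kind, c("bubble", "kink1", "kink2"))
    span <- as.integer(d$span)
    if (length(span) == 1) span <- c(span, switch(kind, kink1 = 1L,
                                                  kink2 = 2L, bubble = 2L))
    if (span[2] < 1 || span[2] > n_bp %/% 2)
      stop("defect span exceeding circle")
    if (kind == "kink1" && span[2] != 1) stop("kink1 spans exactly 1 bp")
    if (kind == "kink2" && span[2] != 2) stop("kink2 spans exactly 2 bp")
    if (kind == "bubble" && span[2] < 2) stop("a bubble spans >= 2 bp")
    list(span = span, kind = kind, angle = d$angle)
  })
  for (d in out) {
    idx <- (d$span[1] + seq_len(d$span[2]) - 1) %% n_bp
    if (any(idx %in% occupied)) stop("defect spans must be disjoint")
    ## keep a 2-bp guard band so local displacements stay attributable
    occupied <- c(occupied, idx, (idx + 1) %% n_bp, (idx - 1) %% n_bp,
                  (idx + 2) %% n_bp, (idx - 2) %% n_bp)
  }
  out
}

#' @export
print.pseudo_atomic_model <- function(x, ...) {
  cat(sprintf(paste0("<pseudo_atomic_model: %d bp, dLk %+g, %d defect(s), ",
                     "TFO %s, %d pseudo-atoms>\n"),
              x$n_bp, x$delta_lk, length(x$defects),
              if (is.null(x$sequence$T)) "absent" else "bound",
              nrow(x$atoms)))
  invisible(x)
}
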