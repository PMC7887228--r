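#' Non-bonded interaction parameters
#'
#' Units are kcal/mol, Angstrom and elementary charges; the Coulomb constant
#' is 332.06 kcal A / (mol e^2). Solvent is represented implicitly by a
#' relative dielectric (78.5) and an optional Debye screening length
#' (9.6 Angstrom, about 100 mM ionic strength, matching the optimal
#' triplex-binding salt conditions). Pairs within the same residue or between
#' adjacent residues of one strand are excluded, the pseudo-atomic analogue
#' of bonded 1-2/1-3 exclusions.
#'
#' @param dielectric relative dielectric constant (> 0).
#' @param debye_length Angstrom, or `NULL` for unscreened Coulomb.
#' @param cutoff pair cutoff, Angstrom (> 0).
#' @param lj_table per-type `sigma` (Angstrom) and `epsilon` (kcal/mol);
#'   pair parameters by Lorentz-Berthelot combination.
#' @return A list of class `nonbonded_params`.
#' @export
nonbonded_params <- function(dielectric = 78.5, debye_length = 9.6,
                             cutoff = 100,
                             lj_table = pseudo_atom_params()$lj) {
  if (dielectric <= 0) stop("dielectric must be > 0")
  if (cutoff <= 0) stop("cutoff must be > 0")
  structure(list(coulomb_constant = 332.06, dielectric = dielectric,
                 debye_length = debye_length, cutoff = cutoff,
                 lj_table = lj_table),
            class = "nonbonded_params")
}

#' Non-bonded energy between two atom selections
#'
#' Screened-Coulomb electrostatics and Lennard-Jones energy summed over atom
#' pairs within the cutoff:
#' `elec = sum k q_i q_j exp(-r/lambda_D) / (eps r)` and
#' `lj = sum 4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6)`.
#' With identical selections the self-energy is computed (each unordered pair
#' once); selections must otherwise be disjoint. Bonded exclusions (same
#' residue; adjacent residues of the same strand, circularly) always apply.
#'
#' @param model a `pseudo_atomic_model`.
#' @param selection_a,selection_b integer or logical indices into
#'   `model$atoms` (default: all atoms).
#' @param params a [nonbonded_params()] object.
#' @return Named numeric vector `c(elec=, lj=)` in kcal/mol.
#' @export
nonbonded_energy <- function(model, selection_a = NULL, selection_b = NULL,
                             params = nonbonded_params()) {
  stopifnot(inherits(model, "pseudo_atomic_model"))
  at <- model$atoms
  na <- nrow(at)
  norm_sel <- function(s) {
    if (is.null(s)) return(seq_len(na))
    if (is.logical(s)) return(which(s))
    as.integer(s)
  }
  ia <- norm_sel(selection_a)
  ib <- norm_sel(selection_b)
  self_mode <- identical(sort(ia), sort(ib))
  if (!self_mode && length(intersect(ia, ib)))
    stop("selections must be disjoint or identical")

  if (self_mode) {
    n <- length(ia)
    if (n < 2) return(c(elec = 0, lj = 0))
    i <- rep.int(seq_len(n - 1), (n - 1):1)
    j <- sequence((n - 1):1) + i
    pi_ <- ia[i]; pj <- ia[j]
  } else {
    g <- expand.grid(pi_ = ia, pj = ib, KEEP.OUT.ATTRS = FALSE)
    pi_ <- g$pi_; pj <- g$pj
  }

  ## bonded exclusions: same residue, or adjacent residue on the same strand
  same_chain <- at$chain[pi_] == at$chain[pj]
  dres <- abs(at$resid[pi_] - at$resid[pj])
  if (model$circular) dres <- pmin(dres, model$n_bp - dres)
  excl <- same_chain & dres <= 1
  pi_ <- pi_[!excl]; pj <- pj[!excl]
  if (!length(pi_)) return(c(elec = 0, lj = 0))

  xyz <- as.matrix(at[, c("x", "y", "z")])
  dv <- xyz[pj, , drop = FALSE] - xyz[pi_, , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  if (any(r < 0.1))
    stop("degenerate geometry: overlapping atoms (r < 0.1 Angstrom)")
  keep <- r <= params$cutoff
  pi_ <- pi_[keep]; pj <- pj[keep]; r <- r[keep]
  if (!length(r)) return(c(elec = 0, lj = 0))

  scr <- if (is.null(params$debye_length)) 1 else exp(-r / params$debye_length)
  elec <- sum(params$coulomb_constant * at$charge[pi_] * at$charge[pj] *
                scr / (params$dielectric * r))

  lj <- params$lj_table
  sig <- stats::setNames(lj$sigma, lj$type)
  eps <- stats::setNames(lj$epsilon, lj$type)
  sij <- (sig[at$type[pi_]] + sig[at$type[pj]]) / 2
  eij <- sqrt(eps[at$type[pi_]] * eps[at$type[pj]])
  sr6 <- (sij / r)^6
  ljE <- sum(4 * eij * (sr6^2 - sr6))
  c(elec = elec, lj = unname(ljE))
}

#' Triplex binding-energy decomposition at the binding site
#'
#' Compares a triplex-bound model with its DNA-only counterpart (identical
#' outside the third strand) and decomposes the third-strand interaction
#' energy over the triplex-binding site, using for each third-strand base a
#' 9-base neighbourhood: the three bases of its own plane plus the planes
#' directly above and below. `in_plane` collects interactions within a triad
#' plane (the Hoogsteen and Watson-Crick proxies); `adjacent` collects
#' interactions to the planes above and below (stacking, bifurcated and
#' backbone proxies at pseudo-atom resolution). The binding energy discards
#' the self-energy of the unbound third strand:
#' `e_bind = E(with TFO) - E(without TFO) = in_plane + adjacent`.
#' `e_elec` reports the whole-molecule electrostatic self-energy of the bound
#' model, the quantity referenced across topoisomers.
#'
#' @param with_tfo model with the third strand bound.
#' @param without_tfo the same model without the third strand.
#' @param params a [nonbonded_params()] object.
#' @param include_lj include the Lennard-Jones term (default TRUE).
#' @return A list of class `energy_report`: `e_elec`, `e_bind`, `in_plane`,
#'   `adjacent`, `references` (deltas, NA until referenced), and a
#'   `per_triad` data.frame breakdown.
#' @export
triplex_binding_energy <- function(with_tfo, without_tfo,
                                   params = nonbonded_params(),
                                   include_lj = TRUE) {
  stopifnot(inherits(with_tfo, "pseudo_atomic_model"),
            inherits(without_tfo, "pseudo_atomic_model"))
  dup_w <- with_tfo$atoms[with_tfo$atoms$chain != "T", ]
  dup_o <- without_tfo$atoms[without_tfo$atoms$chain != "T", ]
  if (nrow(dup_w) != nrow(dup_o) ||
      max(abs(as.matrix(dup_w[, c("x", "y", "z")]) -
                as.matrix(dup_o[, c("x", "y", "z")]))) > 1e-6)
    stop("models must be identical outside the third strand")
  if (!is.null(with_tfo$tbs) && !is.null(without_tfo$tbs) &&
      !identical(with_tfo$tbs, without_tfo$tbs))
    stop("tbs spans must match")

  at <- with_tfo$atoms
  tfo_res <- sort(unique(at$resid[at$chain == "T"]))
  n <- with_tfo$n_bp
  term <- function(sel_a, sel_b) {
    if (!length(sel_a) || !length(sel_b)) return(0)
    e <- nonbonded_energy(with_tfo, sel_a, sel_b, params)
    if (include_lj) sum(e) else e[["elec"]]
  }
  per <- lapply(tfo_res, function(r) {
    tfo_i <- which(at$chain == "T" & at$resid == r)
    plane <- which(at$chain %in% c("A", "B") & at$resid == r & at$name == "B")
    nbr_res <- cyc(c(r - 1, r + 1), n)
    ## third-strand self-interactions cancel in E(with) - E(without), so the
    ## adjacent planes contribute their duplex bases only
    adj <- which(at$resid %in% nbr_res & at$name == "B" &
                   at$chain %in% c("A", "B"))
    tfo_base <- tfo_i[at$name[tfo_i] == "B"]
    data.frame(triad = r - 1L,
               in_plane = term(tfo_base, plane),
               adjacent = term(tfo_base, adj))
  })
  per <- do.call(rbind, per)
  if (is.null(per))
    per <- data.frame(triad = integer(0), in_plane = numeric(0),
                      adjacent = numeric(0))
  in_plane <- sum(as.numeric(per$in_plane))
  adjacent <- sum(as.numeric(per$adjacent))
  e_elec <- nonbonded_energy(with_tfo, params = params)[["elec"]]
  structure(list(e_elec = e_elec,
                 e_bind = in_plane + adjacent,
                 in_plane = in_plane, adjacent = adjacent,
                 references = list(d_elec_0 = NA_real_, d_bind_L = NA_real_),
                 per_triad = per),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0("<energy_report: e_bind %.3f (in-plane %.3f + adjacent ",
                     "%.3f), whole-circle elec %.1f kcal/mol>\n"),
              x$e_bind, x$in_plane, x$adjacent, x$e_elec))
  invisible(x)
}

#' Reference an energy series to one of its members
#'
#' The topoisomer-comparison convention: energies are reported as differences
#' from a reference state (the relaxed DNA-only topoisomer for whole-circle
#' electrostatics; the linear fragment for binding energies), so the
#' reference maps to exactly 0.
#'
#' @param values named numeric vector or list (names = topoisomer keys).
#' @param reference_key name of the reference entry.
#' @return Named numeric vector of differences, same order as `values`.
#' @export
reference_delta <- function(values, reference_key) {
  v <- unlist(values)
  reference_key <- as.character(reference_key)
  if (!reference_key %in% names(v)) stop("missing reference key")
  v - v[[reference_key]]
}
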