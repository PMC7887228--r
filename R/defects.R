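#' Detect hydrogen bonds in a pseudo-atomic model
#'
#' Geometric hydrogen-bond criterion with the standard cutoffs: donor-acceptor
#' distance <= 3.5 Angstrom and angle >= 140 degrees. Hydrogens are implicit,
#' so the angle is measured at the donor heavy atom between its antecedent
#' (the sugar pseudo-atom of the same residue) and the acceptor. Each
#' donor/acceptor pair is reported at most once (whichever direction passes
#' first); the triad role is assigned from the residue pair's geometry class:
#' Watson-Crick (duplex strands, same bp), Hoogsteen (third strand to purine
#' strand, same bp), bifurcated (third strand to pyrimidine strand, or
#' base-base contacts between adjacent planes), backbone (any contact to a
#' phosphate).
#'
#' @param model a `pseudo_atomic_model`.
#' @param dist_cutoff Angstrom (default 3.5).
#' @param angle_cutoff degrees (default 140).
#' @param params pseudo-atom configuration (donor/acceptor/antecedent table).
#' @return data.frame of class `hbond_table`: donor/acceptor chain, resid
#'   (1-based bp), atom names, `distance` (Angstrom), `angle` (degrees),
#'   `triad_role`.
#' @export
detect_hbonds <- function(model, dist_cutoff = 3.5, angle_cutoff = 140,
                          params = pseudo_atom_params()) {
  stopifnot(inherits(model, "pseudo_atomic_model"))
  if (is.null(params$donors) || is.null(params$antecedent))
    stop("configuration error: missing donor/acceptor table")
  at <- model$atoms
  don <- which(at$type %in% params$donors)
  acc <- which(at$type %in% params$acceptors)
  xyz <- as.matrix(at[, c("x", "y", "z")])

  ## antecedent (sugar) of each donor residue
  key <- paste(at$chain, at$resid, at$name)
  sug <- match(paste(at$chain[don], at$resid[don], "S"), key)

  ## candidate pairs within the distance cutoff (donors are few; loop donors)
  res <- vector("list", length(don))
  seen <- character(0)
  for (k in seq_along(don)) {
    d <- don[k]
    dv <- xyz[acc, , drop = FALSE] -
      matrix(xyz[d, ], length(acc), 3, byrow = TRUE)
    dist <- sqrt(rowSums(dv^2))
    cand <- which(dist <= dist_cutoff & acc != d &
                    !(at$chain[acc] == at$chain[d] &
                        at$resid[acc] == at$resid[d]))
    if (!length(cand)) next
    v1 <- xyz[sug[k], ] - xyz[d, ]
    rows <- lapply(cand, function(ci) {
      a <- acc[ci]
      v2 <- xyz[a, ] - xyz[d, ]
      ang <- deg(acos(clamp(sum(v1 * v2) /
                              sqrt(sum(v1^2) * sum(v2^2)), -1, 1)))
      if (ang < angle_cutoff) return(NULL)
      pair_id <- paste(sort(c(paste(at$chain[d], at$resid[d], at$name[d]),
                              paste(at$chain[a], at$resid[a], at$name[a]))),
                       collapse = "|")
      if (pair_id %in% seen) return(NULL)
      seen <<- c(seen, pair_id)
      data.frame(donor_chain = at$chain[d], donor_resid = at$resid[d],
                 donor_atom = at$name[d],
                 acceptor_chain = at$chain[a], acceptor_resid = at$resid[a],
                 acceptor_atom = at$name[a],
                 distance = dist[ci], angle = ang,
                 triad_role = hbond_role(at$chain[d], at$resid[d], at$name[d],
                                         at$chain[a], at$resid[a], at$name[a],
                                         model$n_bp),
                 stringsAsFactors = FALSE)
    })
    res[[k]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(donor_chain = character(0), donor_resid = integer(0),
                      donor_atom = character(0), acceptor_chain = character(0),
                      acceptor_resid = integer(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      triad_role = character(0), stringsAsFactors = FALSE)
  class(out) <- c("hbond_table", class(out))
  out
}

hbond_role <- function(ch_d, rs_d, nm_d, ch_a, rs_a, nm_a, n_bp) {
  if (nm_d == "P" || nm_a == "P") return("backbone")
  same_plane <- rs_d == rs_a
  chains <- sort(c(ch_d, ch_a))
  if (same_plane) {
    if (identical(chains, c("A", "B"))) return("wc")
    if (identical(chains, c("A", "T"))) return("hoogsteen")
    return("bifurcated")
  }
  "bifurcated"
}

#' Per-base-pair pairing, stacking and flipped states
#'
#' A base pair is `paired` iff it retains at least one Watson-Crick hydrogen
#' bond. Stacking between neighbouring bases of one strand uses a geometric
#' proxy: base-centroid separation <= 4.5 Angstrom and base-normal alignment
#' |n_i . n_j| >= 0.7. `stacked_5p` (`_3p`) is true when both strands' bases
#' are stacked towards their respective 5' (3') neighbours (the strands are
#' antiparallel, so the two directions run opposite ways around the circle).
#' A base pair is `flipped` when either base centroid lies more than 8
#' Angstrom from the local helical axis (the generator's 0.8-nm bubble
#' displacement, with margin).
#'
#' @param model a `pseudo_atomic_model`.
#' @param hbonds result of [detect_hbonds()] on the same model.
#' @param stack_dist Angstrom (default 4.5).
#' @param stack_align minimum |normal . normal| (default 0.7).
#' @param flip_dist Angstrom from the local axis (default 8).
#' @return data.frame of class `basepair_states`: `bp_index` (0-based),
#'   `paired`, `stacked_5p`, `stacked_3p`, `flipped`.
#' @export
basepair_states <- function(model, hbonds = detect_hbonds(model),
                            stack_dist = 4.5, stack_align = 0.7,
                            flip_dist = 8) {
  stopifnot(inherits(model, "pseudo_atomic_model"))
  n <- model$n_bp
  at <- model$atoms
  wc <- hbonds[hbonds$triad_role == "wc", , drop = FALSE]
  paired <- seq_len(n) %in% c(wc$donor_resid, wc$acceptor_resid)

  getB <- function(chain) {
    sel <- at$chain == chain & at$name == "B"
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    xyz[order(at$resid[sel]), , drop = FALSE]
  }
  bA <- getB("A"); bB <- getB("B")
  nrm <- model$frame_normal
  nxt <- c(2:n, 1)
  stack_ok <- function(b) {
    d <- row_norm(b[nxt, , drop = FALSE] - b)
    algn <- abs(row_dot(nrm[nxt, , drop = FALSE], nrm))
    d <= stack_dist & algn >= stack_align          # step i -> i+1
  }
  stA <- stack_ok(bA)        # strand A: 5' neighbour of i is i-1
  stB <- stack_ok(bB)        # strand B antiparallel: 5' neighbour of i is i+1
  prv <- c(n, 1:(n - 1))
  stacked_5p <- stA[prv] & stB          # A: step (i-1)->i ; B: step i->(i+1)
  stacked_3p <- stA & stB[prv]

  dispA <- row_norm(bA - model$frame_origin)
  dispB <- row_norm(bB - model$frame_origin)
  flipped <- pmax(dispA, dispB) > flip_dist

  out <- data.frame(bp_index = seq_len(n) - 1L, paired = paired,
                    stacked_5p = stacked_5p, stacked_3p = stacked_3p,
                    flipped = flipped)
  class(out) <- c("basepair_states", class(out))
  out
}

#' Type supercoiling-induced defects from base-pair states
#'
#' Rule-based typing on the circular sequence of per-bp states:
#' * denaturation bubble - a maximal run of two or more flipped base pairs;
#' * type II kink - exactly two consecutive base pairs with broken pairing
#'   (not flipped) whose bases remain stacked on their 5' neighbours;
#' * type I kink - an isolated unpaired base pair with at least one broken
#'   stack.
#' A single unpaired base pair with both stacks intact is a sub-threshold
#' perturbation and yields no record.
#'
#' @param states result of [basepair_states()] covering the whole circle.
#' @return data.frame of class `defect_records`: `span_start`, `span_length`
#'   (0-based, circular), `kind`, `broken_hbonds`.
#' @export
classify_defects <- function(states) {
  n <- nrow(states)
  flip <- states$flipped
  unp <- !states$paired

  records <- list()
  for (r in circular_runs(flip)) {
    if (r$length >= 2)
      records <- c(records, list(list(start = r$start - 1L, len = r$length,
                                      kind = "bubble")))
  }
  in_bubble <- rep(FALSE, n)
  for (rec in records)
    in_bubble[cyc(rec$start + seq_len(rec$len), n)] <- TRUE

  cand <- unp & !flip & !in_bubble
  for (r in circular_runs(cand)) {
    idx <- cyc(r$start + seq_len(r$length) - 1, n)   # 1-based rows of the run
    if (r$length == 2 && all(states$stacked_5p[idx])) {
      records <- c(records, list(list(start = r$start - 1L, len = 2L,
                                      kind = "kink2")))
    } else if (r$length == 1 &&
               (!states$stacked_5p[idx] || !states$stacked_3p[idx])) {
      records <- c(records, list(list(start = r$start - 1L, len = 1L,
                                      kind = "kink1")))
    }
  }
  if (!length(records)) {
    out <- data.frame(span_start = integer(0), span_length = integer(0),
                      kind = character(0), broken_hbonds = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(
      span_start = vapply(records, function(r) as.integer(r$start %% n),
                          integer(1)),
      span_length = vapply(records, `[[`, integer(1), "len"),
      kind = vapply(records, `[[`, character(1), "kind"),
      stringsAsFactors = FALSE)
    out$broken_hbonds <- vapply(seq_len(nrow(out)), function(k) {
      idx <- cyc(out$span_start[k] + seq_len(out$span_length[k]), n)
      sum(!states$paired[idx])
    }, integer(1))
    out <- out[order(out$span_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("defect_records", class(out))
  out
}
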