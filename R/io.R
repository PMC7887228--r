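## ---- pseudo-atomic models: PDB -----------------------------------------

#' Write a pseudo-atomic model as PDB
#'
#' One chain per strand (A and B for the duplex, T for the third strand),
#' residue names `DA`/`DT`/`DG`/`DC`, pseudo-atom names `P`/`S`/`B`.
#' Partial charges are stored in the B-factor column. Circular topology and
#' the model's bookkeeping (bp count, linking difference, helical repeat,
#' TBS span) go into `REMARK 300` header lines so a model round-trips
#' through [read_model()].
#'
#' @param model a `pseudo_atomic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "pseudo_atomic_model"))
  at <- model$atoms
  ord <- order(match(at$chain, c("A", "B", "T")), at$resid,
               match(at$name, c("P", "S", "B")))
  at <- at[ord, ]
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  resid_names <- paste0("D", at$base)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resid, chain = at$chain,
                   resid = resid_names, elety = at$name,
                   o = rep(1, nrow(at)), b = at$charge)
  hdr <- c(sprintf("REMARK 300 CIRCULAR %s", if (model$circular) "TRUE" else "FALSE"),
           sprintf("REMARK 300 NBP %d", model$n_bp),
           sprintf("REMARK 300 DELTALK %g", model$delta_lk),
           sprintf("REMARK 300 HELICALREPEAT %g", model$helical_repeat))
  if (!is.null(model$tbs))
    hdr <- c(hdr, sprintf("REMARK 300 TBS %d %d", model$tbs[1], model$tbs[2]))
  body <- readLines(path)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pseudo-atomic model from PDB
#'
#' Inverse of [write_model()]: rebuilds the atom table (charges from the
#' B-factor column), the per-bp base frames (origin = midpoint of the two
#' sugar pseudo-atoms, normal = local tangent of the origin sequence, long
#' axis = unit vector between the sugars) and the pairing states (from the
#' package's own hydrogen-bond and flipped-base detectors), so that a model
#' written and re-read behaves identically under the defect and energetics
#' analyses.
#'
#' @param path PDB file written by [write_model()].
#' @return A `pseudo_atomic_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parse error: no such file: %s", path))
  lines <- readLines(path, n = 50)
  rem <- grep("^REMARK 300 ", lines, value = TRUE)
  get_rem <- function(key) {
    m <- grep(paste0("^REMARK 300 ", key, " "), rem, value = TRUE)
    if (!length(m)) return(NULL)
    strsplit(sub(paste0("^REMARK 300 ", key, " "), "", m[1]), " ")[[1]]
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    stop(sprintf("parse error reading %s: %s", path,
                                 conditionMessage(e))))
  a <- pdb$atom
  chains <- unique(a$chain)
  if (!all(c("A", "B") %in% chains))
    stop("parse error: model must contain duplex chains A and B")
  atoms <- data.frame(chain = a$chain, resid = a$resno,
                      base = sub("^D", "", a$resid),
                      name = a$elety,
                      x = a$x, y = a$y, z = a$z,
                      charge = a$b, type = substr(a$elety, 1, 1),
                      stringsAsFactors = FALSE)
  n_bp <- as.integer(get_rem("NBP") %||% max(atoms$resid))
  circular <- identical(get_rem("CIRCULAR"), "TRUE")
  delta_lk <- as.numeric(get_rem("DELTALK") %||% NA)
  hrep <- as.numeric(get_rem("HELICALREPEAT") %||% 10.5)
  tbs <- get_rem("TBS")
  if (!is.null(tbs)) tbs <- as.integer(tbs)

  getXYZ <- function(chain, name) {
    sel <- atoms$chain == chain & atoms$name == name
    xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
    xyz[order(atoms$resid[sel]), , drop = FALSE]
  }
  sA <- getXYZ("A", "S"); sB <- getXYZ("B", "S")
  if (nrow(sA) != n_bp || nrow(sB) != n_bp)
    stop("parse error: every bp needs one residue per duplex chain")
  origin <- (sA + sB) / 2
  ocurve <- closed_curve(origin, closed = circular)
  normal <- curve_tangents(ocurve)
  long <- row_unit(sA - sB)

  seqA <- atoms$base[atoms$chain == "A" & atoms$name == "B"][order(atoms$resid[atoms$chain == "A" & atoms$name == "B"])]
  seqB <- atoms$base[atoms$chain == "B" & atoms$name == "B"][order(atoms$resid[atoms$chain == "B" & atoms$name == "B"])]
  seqT <- if ("T" %in% chains)
    atoms$base[atoms$chain == "T" & atoms$name == "B"] else NULL

  model <- structure(list(
    n_bp = n_bp, circular = circular,
    sequence = list(A = seqA, B = seqB, T = seqT),
    atoms = atoms,
    frame_origin = origin, frame_normal = normal, frame_long = long,
    pairing = NULL, tbs = tbs, delta_lk = delta_lk, helical_repeat = hrep,
    defects = NULL, seed = NULL,
    axis = closed_curve(origin / 10, closed = circular)),
    class = "pseudo_atomic_model")
  st <- basepair_states(model)
  model$pairing <- ifelse(st$flipped, "flipped",
                          ifelse(st$paired, "paired", "broken"))
  model
}

## ---- contours: XYZ / CSV -----------------------------------------------

#' Write / read a contour as XYZ or CSV
#'
#' XYZ: standard element-x-y-z block with a count header (element "C", nm).
#' CSV: `index,x,y,z` with a header row; `index` keeps the 0-based bp labels.
#'
#' @param curve a [closed_curve()].
#' @param path file path; format chosen by extension (`.xyz` else CSV).
#' @param closed when reading: is the contour closed (default TRUE)?
#' @return `path` (write) or a [closed_curve()] (read).
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "closed_curve"))
  p <- curve$points
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    writeLines(c(nrow(p), "closed DNA contour (nm)",
                 sprintf("C %.6f %.6f %.6f", p[, 1], p[, 2], p[, 3])), path)
  } else {
    df <- data.frame(index = curve$labels %||% (seq_len(nrow(p)) - 1L),
                     x = p[, 1], y = p[, 2], z = p[, 3])
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, closed = TRUE) {
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    n <- as.integer(lines[1])
    toks <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
    pts <- unname(matrix(as.numeric(toks[, 2:4]), ncol = 3))
    closed_curve(pts, closed = closed)
  } else {
    df <- utils::read.csv(path)
    closed_curve(unname(as.matrix(df[, c("x", "y", "z")])), closed = closed,
                 labels = as.integer(df$index))
  }
}

## ---- topographs: float TIFF / text grid + JSON sidecar ------------------

#' Write / read an AFM topograph
#'
#' Two formats by extension: a whitespace-delimited text grid (lossless at
#' double precision; `#` comment lines allowed) or TIFF. TIFF storage is
#' 32-bit float of heights affinely rescaled to [0, 1]; the offset and scale
#' are recorded in the JSON sidecar (`<path>.json`, which also carries the
#' pixel size and metadata), so the round trip is exact at single precision.
#'
#' @param topo a [topograph()].
#' @param path output path (`.tif`/`.tiff` for TIFF, anything else is text).
#' @param pixel_size when reading: overrides/supplies the pixel size if no
#'   sidecar is present.
#' @return `path` (write) or a [topograph()] (read).
#' @export
write_topograph <- function(topo, path) {
  stopifnot(inherits(topo, "topograph"))
  h <- topo$heights
  side <- list(pixel_size = topo$pixel_size, metadata = topo$metadata)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    lo <- min(h); hi <- max(h)
    scale <- if (hi > lo) hi - lo else 1
    side$tiff_offset <- lo
    side$tiff_scale <- scale
    suppressWarnings(tiff::writeTIFF((h - lo) / scale, path,
                                     bits.per.sample = 32L, reduce = FALSE))
  } else {
    ## full 17-significant-digit formatting: the text grid is the lossless
    ## storage format for heights
    body <- apply(h, 1, function(r) paste(sprintf("%.17g", r),
                                          collapse = " "))
    writeLines(c("# AFM topograph heights (nm), one scan line per row",
                 sprintf("# pixel_size_nm %.17g", topo$pixel_size), body),
               path)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topograph
#' @export
read_topograph <- function(path, pixel_size = NULL) {
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
  else list()
  psz <- pixel_size %||% side$pixel_size
  if (is.null(psz)) {
    ## text grids may carry the pixel size as a header comment
    if (!grepl("\\.tiff?$", path, ignore.case = TRUE)) {
      hdr <- grep("^#", readLines(path, n = 10), value = TRUE)
      m <- grep("pixel_size_nm", hdr, value = TRUE)
      if (length(m)) psz <- as.numeric(sub(".*pixel_size_nm\\s+", "", m[1]))
    }
  }
  if (is.null(psz) || !is.finite(psz) || psz <= 0)
    stop("configuration error: missing or invalid pixel size")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    h <- tiff::readTIFF(path)
    if (!is.null(side$tiff_scale))
      h <- h * side$tiff_scale + side$tiff_offset
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    h <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  }
  topograph(h, psz, metadata = side$metadata %||% list())
}

## ---- reports ------------------------------------------------------------

#' Write defect records as BED-like text
#'
#' Tab-separated `name  start  end  kind` using 0-based half-open spans on
#' the circular bp coordinate (spans crossing the origin keep start > end-1).
#'
#' @param records `defect_records` from [classify_defects()].
#' @param path output path.
#' @param name circle name for the first column.
#' @return `path`, invisibly.
#' @export
write_defects_bed <- function(records, path, name = "minicircle") {
  lines <- sprintf("%s\t%d\t%d\t%s", name, records$span_start,
                   records$span_start + records$span_length, records$kind)
  writeLines(lines, path)
  invisible(path)
}
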