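#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis pipeline, each defaulting
#' to its standard value: 16-bp bend separation, 35 degree peak threshold,
#' 75 degree defect cutoff, 3.5 Angstrom / 140 degree hydrogen-bond cutoffs,
#' 200 nm^2 grain floor with the 50-150% median band, 80 nm crops, 5 nm
#' minimum straight segments. Unknown keys are rejected.
#'
#' @param ... overrides for any of the defaults (see
#'   `names(pipeline_config())`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    models = character(0),          # paths to PDB models (or model objects)
    images = character(0),          # paths to topographs (or objects)
    out_dir = NULL,
    seed = 1L,
    separation_bp = 16L,
    peak_threshold = 35,
    defect_cutoff = 75,
    classify_mode = "interactions",
    hbond_dist = 3.5,
    hbond_angle = 140,
    axis_window_bp = 11L,
    axis_weighting = "uniform",
    helical_repeat = 10.5,
    mask_sigma_mult = 1,
    grain_min_area_nm2 = 200,
    grain_median_band = c(0.5, 1.5),
    crop_nm = 80,
    min_segment_nm = 5,
    smooth_sigma_px = 1.5,
    smooth_truncate_px = 3.5,
    protrusion_threshold_nm = 0.3,
    run_energetics = FALSE,
    nonbonded = nonbonded_params())
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = c("pipeline_config", "list"))
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip load(dump(config)) is the identity (function-valued
#' entries such as the non-bonded parameter object are stored as plain
#' lists and revalidated on load).
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$nonbonded <- unclass(x$nonbonded)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  nb <- x$nonbonded
  x$nonbonded <- NULL
  ## yaml reads empty sequences back as list(); path vectors are character
  for (key in c("models", "images"))
    if (is.list(x[[key]])) x[[key]] <- as.character(unlist(x[[key]]))
  cfg <- do.call(pipeline_config, x)
  if (!is.null(nb)) {
    nb$lj_table <- as.data.frame(nb$lj_table)
    cfg$nonbonded <- do.call(nonbonded_params,
                             nb[c("dielectric", "debye_length", "cutoff",
                                  "lj_table")])
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' For each model input: helical axis, bend profile, bend features, defect
#' detection and typing, feature classification (broken-interaction
#' evidence), shape metrics, writhe and topology record, and optionally the
#' triplex energetics when the model carries a third strand. For each image
#' input: flatten, smooth, mask and label, grain filtering, grain
#' morphometrics, cropping and molecule tracing with protrusion
#' localisation. Per-input failures are reported in the bundle without
#' aborting the batch. When `config$out_dir` is set, the bundle is written
#' as JSON plus CSV tables.
#'
#' @param config a [pipeline_config()]. Model/image entries may be paths or
#'   in-memory objects.
#' @return A list of class `pipeline_report`: `models` (per-input results),
#'   `images`, `pooled` (pooled grain statistics), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  model_reports <- lapply(seq_along(config$models), function(k) {
    input <- config$models[[k]]
    tryCatch(analyze_model_input(input, config),
             error = function(e) list(input = describe_input(input),
                                      error = conditionMessage(e)))
  })
  image_reports <- lapply(seq_along(config$images), function(k) {
    input <- config$images[[k]]
    tryCatch(analyze_image_input(input, config),
             error = function(e) list(input = describe_input(input),
                                      error = conditionMessage(e)))
  })
  pooled <- NULL
  grains <- lapply(image_reports, function(r) r$grains)
  grains <- grains[!vapply(grains, is.null, logical(1))]
  if (length(grains)) {
    all_g <- do.call(rbind, grains)
    pooled <- data.frame(n_grains = nrow(all_g),
                         mean_area = mean(all_g$area),
                         mean_aspect_ratio = mean(all_g$aspect_ratio),
                         sd_aspect_ratio = stats::sd(all_g$aspect_ratio),
                         mean_max_height = mean(all_g$max_height))
  }
  out <- structure(list(models = model_reports, images = image_reports,
                        pooled = pooled, config = config),
                   class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report_bundle(out, config$out_dir)
  out
}

describe_input <- function(input) {
  if (is.character(input)) input else class(input)[1]
}

analyze_model_input <- function(input, config) {
  model <- if (is.character(input)) read_model(input) else input
  stopifnot(inherits(model, "pseudo_atomic_model"))
  axis <- helical_axis(model, window_bp = config$axis_window_bp,
                       weighting = config$axis_weighting)
  prof <- bend_profile(axis, separation_bp = config$separation_bp)
  feats <- find_bend_features(prof, peak_threshold = config$peak_threshold)
  hb <- detect_hbonds(model, dist_cutoff = config$hbond_dist,
                      angle_cutoff = config$hbond_angle)
  states <- basepair_states(model, hb)
  defs <- classify_defects(states)
  feats <- if (config$classify_mode == "interactions")
    classify_bend_features(feats, "interactions", config$defect_cutoff,
                           defect_spans = defs)
  else classify_bend_features(feats, "angle_only", config$defect_cutoff)
  shape <- shape_metrics(axis)
  wr <- if (axis$closed) writhe(axis) else NA_real_
  topo_rec <- if (!is.null(model$delta_lk) && is.finite(model$delta_lk))
    sigma_from_topology(model$n_bp, model$delta_lk,
                        helical_repeat = config$helical_repeat, wr = wr)
  else NULL
  energy <- NULL
  if (isTRUE(config$run_energetics) && !is.null(model$sequence$T)) {
    bare <- strip_third_strand(model)
    energy <- triplex_binding_energy(model, bare, params = config$nonbonded)
  }
  list(input = describe_input(input), n_bp = model$n_bp,
       axis = axis, profile = prof, features = feats,
       hbond_count = nrow(hb), states = states, defects = defs,
       shape = shape, writhe = wr, topology = topo_rec, energy = energy)
}

## drop chain T so a bound model can be compared against its bare duplex
strip_third_strand <- function(model) {
  model$atoms <- model$atoms[model$atoms$chain != "T", , drop = FALSE]
  model$sequence$T <- NULL
  model
}

analyze_image_input <- function(input, config) {
  topo <- if (is.character(input)) read_topograph(input) else input
  stopifnot(inherits(topo, "topograph"))
  flat <- flatten_topograph(topo)
  sm <- smooth_topograph(flat, sigma_px = config$smooth_sigma_px,
                         truncate_px = config$smooth_truncate_px)
  lab <- mask_and_label(sm, sigma_mult = config$mask_sigma_mult)
  lab <- filter_grains(lab, pixel_size = topo$pixel_size,
                       min_area_nm2 = config$grain_min_area_nm2,
                       median_band = config$grain_median_band)
  grains <- grain_stats(lab, sm)
  crops <- crop_grains(sm, grains, crop_nm = config$crop_nm)
  traces <- lapply(crops, function(cr) {
    tryCatch({
      tr <- trace_molecule(cr, min_segment_nm = config$min_segment_nm)
      list(trace = tr,
           protrusion = locate_protrusion(tr,
                                          config$protrusion_threshold_nm))
    }, error = function(e) list(error = conditionMessage(e)))
  })
  list(input = describe_input(input), n_grains = nrow(grains),
       grains = grains, removed = attr(lab, "removed"), traces = traces)
}

write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  slim <- report_to_list(report)
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$pooled))
    utils::write.csv(report$pooled, file.path(out_dir, "pooled_grains.csv"),
                     row.names = FALSE)
  for (k in seq_along(report$images)) {
    g <- report$images[[k]]$grains
    if (!is.null(g) && nrow(g))
      utils::write.csv(g, file.path(out_dir, sprintf("grains_%02d.csv", k)),
                       row.names = FALSE)
  }
  for (k in seq_along(report$models)) {
    r <- report$models[[k]]
    if (!is.null(r$defects))
      write_defects_bed(r$defects,
                        file.path(out_dir, sprintf("defects_%02d.bed", k)),
                        name = sprintf("model_%02d", k))
    if (!is.null(r$profile))
      utils::write.csv(data.frame(position = seq_along(r$profile$angles) - 1L,
                                  angle = r$profile$angles),
                       file.path(out_dir, sprintf("bend_profile_%02d.csv", k)),
                       row.names = FALSE)
  }
  invisible(out_dir)
}

## a JSON-friendly summary (drops bulky raster/curve members)
report_to_list <- function(report) {
  list(
    config = {
      cfg <- unclass(report$config)
      cfg$nonbonded <- unclass(cfg$nonbonded)
      cfg$models <- vapply(cfg$models, describe_input, character(1))
      cfg$images <- vapply(cfg$images, describe_input, character(1))
      cfg
    },
    models = lapply(report$models, function(r) {
      if (!is.null(r$error)) return(r[c("input", "error")])
      list(input = r$input, n_bp = r$n_bp,
           n_features = nrow(r$features),
           features = r$features,
           defects = r$defects,
           hbond_count = r$hbond_count,
           shape = unclass(r$shape),
           writhe = r$writhe,
           topology = if (!is.null(r$topology)) unclass(r$topology),
           energy = if (!is.null(r$energy))
             r$energy[c("e_elec", "e_bind", "in_plane", "adjacent")])
    }),
    images = lapply(report$images, function(r) {
      if (!is.null(r$error)) return(r[c("input", "error")])
      list(input = r$input, n_grains = r$n_grains, grains = r$grains,
           removed = r$removed,
           traces = lapply(r$traces, function(tr) {
             if (!is.null(tr$error)) return(tr["error"])
             list(closed = tr$trace$closed, length_nm = tr$trace$length_nm,
                  n_segments = nrow(tr$trace$segments),
                  angles = tr$trace$angles,
                  protrusion = tr$protrusion)
           }))
    }),
    pooled = report$pooled)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d model(s), %d image(s)%s>\n",
              length(x$models), length(x$images),
              if (!is.null(x$pooled))
                sprintf(", %d pooled grains", x$pooled$n_grains) else ""))
  invisible(x)
}
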