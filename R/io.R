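## Configuration, serialisation and command-line plumbing.  Tabular
## outputs are CSV (header row, UTF-8, '.' decimal); model parameters
## and run configurations are flat snake_case JSON; images are TIFF.

model_param_fields <- c(
  "production_coeff", "production_exponent", "exit_threshold",
  "degradation_fraction", "commitment_size", "sensed_quantity",
  "decrement_mode", "unit_mode", "max_rounds", "null_exit_threshold",
  "overexpression_supplement", "baseline_production", "genotype")

#' Write model parameters as flat JSON
#'
#' @param params A [model_params()] object.
#' @param path Output path.
#' @export
write_model_params <- function(params, path) {
  validate_model_params(params)
  jsonlite::write_json(params[model_param_fields], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read model parameters from flat JSON
#'
#' Unknown keys are a validation error (listing them), so that typos in
#' configuration files fail loudly rather than being ignored.
#'
#' @param path Path to a JSON file written by [write_model_params()] or
#'   hand-authored with the same field names.
#' @return A validated [model_params()] object.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(x), model_param_fields)
  if (length(unknown)) {
    stop("unknown model parameter keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(model_params, x)
}

#' Write and read cell record tables
#'
#' CSV with the fixed column set `cell_id`, `volume_um3`, `committed`,
#' `division_count`, `population`, `genotype`.
#'
#' @param cells Cell records.
#' @param path File path.
#' @return `read_cell_records` returns the validated data frame.
#' @export
write_cell_records <- function(cells, path) {
  cols <- c("cell_id", "volume_um3", "committed", "division_count",
            "population", "genotype")
  stopifnot(all(cols %in% names(cells)))
  utils::write.csv(cells[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "volume_um3", "committed", "division_count",
            "population", "genotype")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("cell record file lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a division-series trajectory as CSV
#'
#' Columns: `round`, `nuclei`, `per_nucleus_amount`, `concentration`,
#' `per_dna_ratio`.
#'
#' @param outcome A `division_outcome` from [run_division_series()].
#' @param path File path.
#' @export
write_trajectory <- function(outcome, path) {
  stopifnot(inherits(outcome, "division_outcome"))
  utils::write.csv(outcome$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' TIFF image input and output
#'
#' Intensity images are written as 32-bit float TIFF after division by
#' `scale` (TIFF storage is defined on `[0, 1]`); pass the same scale
#' when reading to restore arbitrary-unit values.  Label images are
#' 16-bit integer TIFF.  Multi-page TIFFs are read as a
#' rows x cols x pages array.
#'
#' @param img Numeric matrix.
#' @param path File path.
#' @param scale Intensity scale; defaults to the image maximum (at
#'   least 1) on write and to 1 on read.
#' @return `write_image_tiff` invisibly returns the scale used.
#' @export
write_image_tiff <- function(img, path, scale = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(scale)) scale <- max(img, 1)
  stopifnot(scale > 0, max(img) <= scale, min(img) >= 0)
  tiff::writeTIFF(img / scale, path, bits.per.sample = 32)
  invisible(scale)
}

#' @rdname write_image_tiff
#' @param labels Integer label matrix (values < 2^16).
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) < 65536)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, scale = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- tiff::readTIFF(path, all = TRUE)
  if (length(x) == 1) return(x[[1]] * scale)
  array(unlist(x), dim = c(dim(x[[1]]), length(x))) * scale
}

#' @rdname write_image_tiff
#' @export
read_label_tiff <- function(path) {
  m <- read_image_tiff(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

run_config_fields <- c("subcommand", "seed", "out", "what", "genotype",
                       "n_cells", "input", "dapi", "ha", "pixel_size",
                       "background", "min_area", "params",
                       "synthetic", "growth", "grid")

#' Run a configured pipeline step
#'
#' Dispatches on the `subcommand` field of a JSON run configuration:
#' `gen-data` (synthetic tables/images), `simulate` (grow + divide a
#' population for a genotype), `quantify` (segment and measure a
#' two-channel TIFF pair), `fit` (parameter recovery from a cell-record
#' CSV), `report` (size-distribution summary of a cell-record CSV).
#' Every run writes a `manifest.json` (config, seed, package version)
#' alongside its outputs.  Unknown configuration keys are an error.
#'
#' @param config Path to a JSON configuration file, or an equivalent
#'   named list.
#' @param seed Optional seed overriding the config's.
#' @param out Optional output directory overriding the config's.
#' @param verbose Log parameters and row counts.
#' @return Invisibly, a named list of output paths.
#' @export
run <- function(config, seed = NULL, out = NULL, verbose = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("no such file: ", config, call. = FALSE)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  unknown <- setdiff(names(cfg), run_config_fields)
  if (length(unknown)) {
    stop("unknown configuration keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(out)) cfg$out <- out
  if (is.null(cfg$out)) stop("no output directory given", call. = FALSE)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  params <- if (is.null(cfg$params)) model_params()
            else do.call(model_params, cfg$params)
  syn_args <- if (is.null(cfg$synthetic)) list() else cfg$synthetic
  syn_args$seed <- cfg$seed
  syn <- do.call(synthetic_config, syn_args)

  outputs <- list()
  op <- function(name) file.path(cfg$out, name)
  sub <- cfg$subcommand
  if (is.null(sub)) stop("configuration lacks 'subcommand'", call. = FALSE)

  if (sub == "gen-data") {
    what <- if (is.null(cfg$what)) "sizes" else cfg$what
    if (what == "sizes") {
      cells <- gen_size_population(syn)
      outputs$cells <- write_cell_records(cells, op("cells.csv"))
      say("wrote ", nrow(cells), " cell records")
    } else if (what == "if") {
      rec <- gen_if_records(syn)
      utils::write.csv(rec$cells, op("if_cells.csv"), row.names = FALSE)
      utils::write.csv(rec$nuclei, op("if_nuclei.csv"), row.names = FALSE)
      utils::write.csv(rec$truth, op("if_truth.csv"), row.names = FALSE)
      outputs$cells <- op("if_cells.csv")
      say("wrote ", nrow(rec$cells), " IF cell records")
    } else if (what == "geometry") {
      geo <- gen_ble_gfp_geometry(syn)
      utils::write.csv(geo, op("geometry.csv"), row.names = FALSE)
      outputs$geometry <- op("geometry.csv")
      say("wrote ", nrow(geo), " geometry records")
    } else if (what == "images") {
      rec <- gen_if_records(syn)
      first_id <- rec$nuclei$cell_id[rec$nuclei$stage ==
                                       max(rec$nuclei$stage)][1]
      img <- render_cell_image(
        rec$nuclei[rec$nuclei$cell_id == first_id, ], syn,
        seed = cfg$seed)
      write_image_tiff(img$dapi, op("dapi.tif"))
      outputs$dapi <- op("dapi.tif")
      scale <- write_image_tiff(img$ha, op("ha.tif"))
      outputs$ha <- op("ha.tif")
      write_label_tiff(img$labels, op("labels.tif"))
      outputs$labels <- op("labels.tif")
      # background on the stored (scaled) intensity axis, for quantify
      jsonlite::write_json(list(ha_scale = scale,
                                background = img$background / scale),
                           op("image_meta.json"), auto_unbox = TRUE,
                           digits = NA)
      say("wrote image pair for cell ", first_id)
    } else stop("unknown gen-data target: ", what, call. = FALSE)
  } else if (sub == "simulate") {
    genotype <- if (is.null(cfg$genotype)) "wild_type" else cfg$genotype
    p <- scenario_params(genotype, params)
    if (!is.null(cfg$n_cells)) syn$n_cells <- as.integer(cfg$n_cells)
    daughters <- gen_size_population(syn, genotype = genotype)
    gargs <- if (is.null(cfg$growth)) list() else cfg$growth
    gargs$seed <- cfg$seed + 10L
    grown <- grow_population(daughters, do.call(growth_config, gargs), p)
    div <- divide_population(grown, p)
    outputs$mothers <- write_cell_records(div$mothers, op("mothers.csv"))
    outputs$daughters <- write_cell_records(div$daughters,
                                            op("daughters.csv"))
    h <- size_distribution(div$daughters)
    utils::write.csv(h$histogram, op("daughter_hist.csv"),
                     row.names = FALSE)
    outputs$histogram <- op("daughter_hist.csv")
    say("simulated ", nrow(div$mothers), " mothers -> ",
        nrow(div$daughters), " daughters")
  } else if (sub == "quantify") {
    for (f in c("dapi", "ha")) {
      if (is.null(cfg[[f]])) stop("quantify needs '", f, "'", call. = FALSE)
    }
    dapi <- max_projection(read_image_tiff(cfg$dapi))
    ha <- max_projection(read_image_tiff(cfg$ha))
    ps <- if (is.null(cfg$pixel_size)) 0.1 else cfg$pixel_size
    bg <- if (is.null(cfg$background)) 0 else cfg$background
    ma <- if (is.null(cfg$min_area)) 0 else cfg$min_area
    q <- quantify_cell_image(dapi, ha, pixel_size = ps, background = bg,
                             min_area = ma)
    utils::write.csv(q$nuclei, op("nuclei.csv"), row.names = FALSE)
    utils::write.csv(q$cell, op("cell.csv"), row.names = FALSE)
    outputs$nuclei <- op("nuclei.csv")
    outputs$cell <- op("cell.csv")
    say("measured ", nrow(q$nuclei), " nuclei")
  } else if (sub == "fit") {
    if (is.null(cfg$input)) stop("fit needs 'input'", call. = FALSE)
    obs <- read_cell_records(cfg$input)
    observed <- data.frame(mother_volume = obs$volume_um3,
                           n_rounds = obs$division_count)
    grid <- if (is.null(cfg$grid)) {
      list(theta = seq(0.5, 2, length.out = 13),
           delta = seq(0, 0.3, length.out = 13),
           b = seq(1, 2, length.out = 13))
    } else cfg$grid
    fit <- fit_params(observed, grid, seed = cfg$seed, base = params)
    outputs$params <- write_model_params(fit$params, op("fitted.json"))
    say("fit loss ", signif(fit$loss, 4))
  } else if (sub == "report") {
    if (is.null(cfg$input)) stop("report needs 'input'", call. = FALSE)
    cells <- read_cell_records(cfg$input)
    h <- size_distribution(cells)
    utils::write.csv(h$histogram, op("size_hist.csv"), row.names = FALSE)
    jsonlite::write_json(h[c("median", "mean", "sd", "n")],
                         op("size_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs$histogram <- op("size_hist.csv")
    say("summarised ", h$n, " cells")
  } else {
    stop("unknown subcommand: ", sub, call. = FALSE)
  }

  manifest <- list(config = cfg, seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("fissionsizer")))
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}

#' Command-line entry point
#'
#' Thin argument parser over [run()], used by the packaged
#' `inst/scripts/fissionsizer.R` launcher:
#' `Rscript fissionsizer.R --config cfg.json --seed 1 --out dir/`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, 0 on success.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  get_opt <- function(flag) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else NULL
  }
  config <- get_opt("--config")
  if (is.null(config)) {
    message("usage: --config cfg.json [--seed N] [--out dir] [--verbose]")
    return(invisible(1L))
  }
  seed <- get_opt("--seed")
  status <- tryCatch({
    run(config,
        seed = if (!is.null(seed)) as.integer(seed),
        out = get_opt("--out"),
        verbose = "--verbose" %in% args)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
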