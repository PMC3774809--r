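# File formats: multi-page TIFF stacks (one page per frame, channels as
# separate files or pages), CSV tables with header rows, JSON lineage trees
# and YAML configuration. All integer image data round-trips bit-exactly
# through 16-bit TIFF.

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file.
#' @return numeric array (y, x, frame); integer-valued for integer TIFFs.
#' @export
read_stack <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF stack '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF: pages differ in size")
  stack <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (f in seq_along(pages)) {
    p <- pages[[f]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    stack[, , f] <- p
  }
  stack
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Values are clamped to \[0, 65535\] and rounded; a written integer stack
#' reads back identically ([read_stack()]).
#'
#' @param stack array (y, x, frame) or a single matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- round(pmin(pmax(stack[, , f], 0), 65535))
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Default pipeline configuration
#'
#' Bundles the physical calibration and all stage parameters; serialises to
#' YAML and back without loss ([write_config()], [read_config()]).
#'
#' @param pixel_size um per px.
#' @param frame_interval min per frame.
#' @param segmentation list from [segmentation_params()].
#' @param tracking list: link weights, `l_min`, `max_gap`, optional
#'   `gate_radius`.
#' @param gap list: `bin_width` (px), optional `gap_interval`, `saturation`.
#' @param tissue list: marker `thresholds`, `basal_um`, `median_radius`.
#' @param seed integer seed used by `simulate` stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 1, frame_interval = 30,
                            segmentation = segmentation_params(),
                            tracking = list(alpha = 0.5, beta = 0.25,
                                            gamma = 0.25, l_min = 0.6,
                                            max_gap = 3, gate_radius = NULL),
                            gap = list(bin_width = 20, gap_interval = NULL,
                                       saturation = 0.95),
                            tissue = list(thresholds = c(300, 300),
                                          basal_um = 12, median_radius = 2),
                            seed = 1L) {
  check_positive(pixel_size, "pixel_size")
  check_positive(frame_interval, "frame_interval")
  w <- tracking$alpha + tracking$beta + tracking$gamma
  if (abs(w - 1) > 1e-9) stop("tracking weights must sum to 1")
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 segmentation = segmentation, tracking = tracking,
                 gap = gap, tissue = tissue, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "pipeline_config")
}

#' Export a lineage tree as JSON
#'
#' @param lineage a `lineage_tree`.
#' @param path output JSON file.
#' @return invisibly, the path.
#' @export
write_lineage_json <- function(lineage, path) {
  jsonlite::write_json(list(nodes = lineage$nodes, edges = lineage$edges,
                            mitoses = lineage$mitoses,
                            roots = lineage$roots),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run a pipeline stage
#'
#' Thin orchestration over the package's stages. Each run writes its outputs
#' plus a `run.log` recording the subcommand, seed and config hash, so any
#' run is reproducible from its logged configuration.
#'
#' Subcommands: `simulate` (scratch-assay movie + ground truth), `segment`
#' (stack -> objects.csv), `track` (objects.csv -> tracks.csv, mitoses.csv,
#' lineage.json), `motility` (tracks.csv -> motility.csv, msd.csv,
#' angles.csv), `gap` (tracks.csv -> kinograph CSVs, coverage.csv,
#' closure.json), `all` (simulate through gap in one go).
#'
#' @param subcommand one of "simulate", "segment", "track", "motility",
#'   "gap", "all".
#' @param config a [pipeline_config()].
#' @param inputs named list of input paths (`stack`, `objects`, `tracks` as
#'   required by the subcommand).
#' @param out_dir output directory (created if missing).
#' @param seed overrides `config$seed`.
#' @return invisibly, a named list of written files.
#' @export
run_pipeline <- function(subcommand, config = pipeline_config(),
                         inputs = list(), out_dir = ".",
                         seed = config$seed) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "segment", "track", "motility",
                            "gap", "all"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  p <- function(...) file.path(out_dir, ...)

  if (subcommand %in% c("simulate", "all")) {
    sim <- config$simulate
    if (is.null(sim)) sim <- list()
    sim$frame_interval <- config$frame_interval
    sim$seed <- seed
    truth <- do.call(simulate_scratch, sim)
    movie <- render_movie(truth, pixel_size = config$pixel_size, seed = seed)
    write_stack(movie$stack, p("movie.tif"))
    write.csv(movie$truth_px, p("truth.csv"), row.names = FALSE)
    write.csv(truth$divisions, p("divisions.csv"), row.names = FALSE)
    out <- c(out, list(movie = p("movie.tif"), truth = p("truth.csv")))
    if (subcommand == "simulate") return(finish_run(subcommand, config,
                                                    seed, out_dir, out))
    inputs$stack <- p("movie.tif")
  }

  if (subcommand %in% c("segment", "all")) {
    if (is.null(inputs$stack)) stop("segment requires inputs$stack")
    stack <- read_stack(inputs$stack)
    objects <- segment_stack(stack, config$segmentation)
    write.csv(objects, p("objects.csv"), row.names = FALSE)
    out <- c(out, list(objects = p("objects.csv")))
    if (subcommand == "segment") return(finish_run(subcommand, config,
                                                   seed, out_dir, out))
    inputs$objects <- p("objects.csv")
  }

  if (subcommand %in% c("track", "all")) {
    if (is.null(inputs$objects)) stop("track requires inputs$objects")
    objects <- read.csv(inputs$objects)
    tc <- config$tracking
    res <- track_cells(objects,
                       link_cost_params(tc$alpha, tc$beta, tc$gamma,
                                        tc$gate_radius),
                       mitosis_params(l_min = tc$l_min),
                       max_gap = tc$max_gap)
    write.csv(res$tracks, p("tracks.csv"), row.names = FALSE)
    write.csv(res$mitoses, p("mitoses.csv"), row.names = FALSE)
    write_lineage_json(res$lineage, p("lineage.json"))
    out <- c(out, list(tracks = p("tracks.csv"), lineage = p("lineage.json")))
    if (subcommand == "track") return(finish_run(subcommand, config,
                                                 seed, out_dir, out))
    inputs$tracks <- p("tracks.csv")
  }

  if (subcommand %in% c("motility", "gap", "all")) {
    if (is.null(inputs$tracks)) stop("requires inputs$tracks")
    tracks <- read.csv(inputs$tracks)
  }

  if (subcommand %in% c("motility", "all")) {
    summ <- motility_summary(tracks, config$frame_interval, config$pixel_size)
    write.csv(summ, p("motility.csv"), row.names = FALSE)
    curve <- msd(tracks, max_lag = 20, frame_interval = config$frame_interval,
                 pixel_size = config$pixel_size)
    write.csv(curve, p("msd.csv"), row.names = FALSE)
    steps <- do.call(rbind, lapply(split(tracks, tracks$track_id),
                                   function(tr)
                                     step_stats(tr, config$frame_interval,
                                                config$pixel_size)$steps))
    write.csv(angle_histogram(steps$angle), p("angles.csv"),
              row.names = FALSE)
    out <- c(out, list(motility = p("motility.csv"), msd = p("msd.csv"),
                       angles = p("angles.csv")))
    if (subcommand == "motility") return(finish_run(subcommand, config,
                                                    seed, out_dir, out))
  }

  if (subcommand %in% c("gap", "all")) {
    kin <- build_kinograph(tracks, field_width = max(tracks$x) + 1,
                           bin_width = config$gap$bin_width,
                           frame_interval = config$frame_interval,
                           pixel_size = config$pixel_size)
    write.csv(kin$density, p("kinograph_density.csv"))
    write.csv(kin$speed, p("kinograph_speed.csv"))
    series <- coverage_series(kin, config$gap$gap_interval,
                              config$frame_interval)
    series$cell_free <- 1 - series$coverage
    write.csv(series, p("coverage.csv"), row.names = FALSE)
    gap_int <- attr(series, "gap_interval")
    cls <- closure_speed(series,
                         gap_width = diff(gap_int) * config$pixel_size,
                         saturation = config$gap$saturation)
    jsonlite::write_json(cls, p("closure.json"), auto_unbox = TRUE,
                         digits = NA)
    out <- c(out, list(coverage = p("coverage.csv"),
                       closure = p("closure.json")))
  }

  finish_run(subcommand, config, seed, out_dir, out)
}

finish_run <- function(subcommand, config, seed, out_dir, out) {
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  log_lines <- c(paste("subcommand:", subcommand),
                 paste("seed:", seed),
                 paste("config_md5:", unname(tools::md5sum(cfg_path))),
                 paste("time:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  out$config <- cfg_path
  out$log <- file.path(out_dir, "run.log")
  invisible(out)
}
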