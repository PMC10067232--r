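#' Run configuration for the end-to-end pipeline
#'
#' A plain named list, serializable as JSON, describing the requested stages
#' and their parameters. The effective config is always written next to the
#' outputs for provenance.
#'
#' Recognized top-level entries:
#' * `output_dir` (required)
#' * `phantom`: list(kind, size, resolution, spacing, bone_hu, background_hu)
#'   -- generate a synthetic case instead of reading a volume
#' * `volume`: path to an NRRD volume (alternative to `phantom`)
#' * `segment`: list(low, high, connectivity, erase, label)
#' * `reduce`: list(fragments = paths, landmarks = path or matrix pairs,
#'   mirror_plane = "auto" or list(point, normal))
#' * `bone`: path to a reduced bone STL (skips segment/reduce)
#' * `plan`: list(anchors = path or matrix, unit = catalog id,
#'   catalog = path or NULL for the default library, path_params overrides,
#'   sample_density)
#' * `seed`: integer
#'
#' @param config named list or path to a JSON config file.
#' @param dry_run validate only; write nothing.
#' @return manifest list (invisibly written as `manifest.json` in
#'   `output_dir`): stages run, artifact paths, md5 content hashes.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$output_dir)) stop("config requires output_dir")
  stages <- list()
  artifacts <- character(0)
  if (is.null(config$phantom) && is.null(config$volume) && is.null(config$bone)) {
    stop("config needs one of: phantom, volume, bone")
  }
  if (!is.null(config$volume) && !file.exists(config$volume)) {
    stop("volume input not found: ", config$volume)
  }
  if (!is.null(config$bone) && !is.character(config$bone)) {
    stop("bone must be an STL path")
  }
  if (!is.null(config$bone) && !file.exists(config$bone)) {
    stop("bone STL not found: ", config$bone)
  }
  if (dry_run) {
    return(invisible(list(dry_run = TRUE, config = config, stages = list())))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)

  t0 <- proc.time()[["elapsed"]]
  bone <- NULL
  # --- stage: phantom / volume ingest -------------------------------------
  if (!is.null(config$phantom)) {
    ph <- config$phantom
    mesh <- make_phantom(kind = ph$kind %||% "swept_tube",
                         size = as.list(ph$size %||% list()),
                         resolution = ph$resolution %||% 2)
    vol <- voxelize_phantom(mesh,
                            spacing = ph$spacing %||% c(0.8, 0.8, 3.0),
                            bone_hu = ph$bone_hu %||% 1200,
                            background_hu = ph$background_hu %||% -100)
    write_nrrd(vol, out("phantom.nrrd"))
    write_stl(mesh, out("phantom_truth.stl"))
    artifacts <- c(artifacts, out("phantom.nrrd"), out("phantom_truth.stl"))
    stages$phantom <- list(ok = TRUE)
  } else if (!is.null(config$volume)) {
    vol <- load_volume(config$volume)
    stages$ingest <- list(ok = TRUE, path = config$volume)
  } else {
    vol <- NULL
  }
  # --- stage: segment ------------------------------------------------------
  if (!is.null(config$segment)) {
    if (is.null(vol)) stop("segment stage requires a volume or phantom")
    sg <- config$segment
    mask <- threshold_segment(vol, sg$low %||% 300, sg$high %||% Inf)
    comps <- split_components(mask, sg$connectivity %||% 26)
    if (!is.null(sg$erase) && length(sg$erase)) {
      comps <- erase_labels(comps, sg$erase)
    }
    lab <- sg$label %||% 1
    bone <- extract_surface(comps, lab)
    write_nrrd(comps, out("labels.nrrd"))
    write_stl(bone, out("segmented.stl"))
    artifacts <- c(artifacts, out("labels.nrrd"), out("segmented.stl"))
    stages$segment <- list(ok = TRUE, n_components = max(comps$labels))
  }
  # --- stage: reduce -------------------------------------------------------
  if (!is.null(config$reduce)) {
    rd <- config$reduce
    frs <- lapply(rd$fragments, read_stl)
    lm <- rd$landmarks
    if (is.character(lm)) lm <- jsonlite::read_json(lm, simplifyVector = TRUE)
    src <- as.matrix(lm$source)
    tgt <- as.matrix(lm$target)
    fit <- kabsch_align(src, tgt)
    moved <- c(list(list(mesh = frs[[1]])),
               lapply(frs[-1], function(m) list(mesh = m, transform = fit$transform)))
    bone <- compose_model(moved)
    write_stl(bone, out("reduced.stl"))
    jsonlite::write_json(list(rotation = fit$transform$rotation,
                              translation = fit$transform$translation,
                              rmsd = fit$rmsd),
                         out("reduction_transform.json"), digits = NA,
                         auto_unbox = TRUE)
    artifacts <- c(artifacts, out("reduced.stl"), out("reduction_transform.json"))
    stages$reduce <- list(ok = TRUE, rmsd = fit$rmsd)
  }
  if (!is.null(config$bone)) bone <- read_stl(config$bone)
  # --- stage: plan-plate ---------------------------------------------------
  if (!is.null(config$plan)) {
    if (is.null(bone)) stop("plan stage requires a bone surface (segment, reduce or bone input)")
    pl <- config$plan
    anchors <- pl$anchors
    if (is.character(anchors)) anchors <- read_anchors(anchors)
    anchors <- as.matrix(anchors)
    lib <- if (is.null(pl$catalog)) default_unit_library()
           else load_unit_library(pl$catalog)
    unit_id <- pl$unit %||% names(lib)[1]
    if (!unit_id %in% names(lib)) stop("unknown catalog unit: ", unit_id)
    spec <- lib[[unit_id]]
    if (!is.null(pl$standoff)) spec$standoff <- pl$standoff
    if (!is.null(pl$clearance)) spec$clearance_threshold <- pl$clearance
    pp <- path_params(
      sample_spacing = pl$sample_spacing %||% 0.5,
      smoothing_lambda = pl$smoothing_lambda %||% 0.5,
      smoothing_iterations = pl$smoothing_iterations %||% 10,
      wrap_distance = pl$wrap_distance %||% 5.0,
      projection_tolerance = pl$projection_tolerance %||% 0.1)
    proj <- project_anchors(bone, anchors)
    path <- build_path(bone, proj, pp)
    path <- wrap_path(path, bone, pp)
    ml <- match_length(path, spec$unit_length, bone, pp)
    frames <- compute_frames(ml$adjusted_path, bone, ml$unit_count,
                             spec$unit_length)
    template <- assemble_template(frames, spec, bone,
                                  sample_density = pl$sample_density %||% 1)
    files <- export_template(template, out("template.stl"))
    write_path_json(ml$adjusted_path, out("path.json"))
    artifacts <- c(artifacts, unname(files), out("path.json"))
    stages$plan <- list(ok = TRUE, unit_count = ml$unit_count,
                        min_clearance = min(template$clearances))
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  manifest <- list(
    package = "plateforge",
    version = as.character(utils::packageVersion("plateforge")),
    stages = stages,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p)))),
    config = config,
    elapsed_seconds = elapsed)
  jsonlite::write_json(manifest, out("manifest.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(config, out("config.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `make-phantom`, `segment`, `reduce`, `plan-plate`, `run`.
#' Each maps onto [run_pipeline()] with the corresponding stage enabled; see
#' `inst/cli/plateforge` for the Rscript launcher. All geometry is in mm.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: plateforge <command> [options]",
    "commands:",
    "  run          --config cfg.json [--dry-run]",
    "  make-phantom --kind swept_tube --out dir [--resolution mm]",
    "  segment      --in vol.nrrd --low HU [--high HU] [--connectivity 26]",
    "               [--erase 2,3] [--label 1] --out dir",
    "  plan-plate   --bone bone.stl --anchors pts.json [--unit civic]",
    "               [--catalog cat.json] [--standoff 0.5] [--clearance 0.2]",
    "               [--wrap 5.0] --out dir",
    sep = "\n")
  if (length(args) == 0) {
    message(usage)
    return(invisible(2L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  status <- tryCatch({
    cfg <- switch(cmd,
      "run" = jsonlite::read_json(opts$config, simplifyVector = TRUE),
      "make-phantom" = list(
        output_dir = opts$out,
        phantom = list(kind = opts$kind %||% "swept_tube",
                       resolution = as.numeric(opts$resolution %||% 2))),
      "segment" = list(
        output_dir = opts$out, volume = opts$`in`,
        segment = list(low = as.numeric(opts$low),
                       high = as.numeric(opts$high %||% Inf),
                       connectivity = as.integer(opts$connectivity %||% 26),
                       erase = if (is.null(opts$erase)) NULL
                               else as.integer(strsplit(opts$erase, ",")[[1]]),
                       label = as.integer(opts$label %||% 1))),
      "plan-plate" = list(
        output_dir = opts$out, bone = opts$bone,
        plan = list(anchors = opts$anchors, unit = opts$unit,
                    catalog = opts$catalog,
                    standoff = if (is.null(opts$standoff)) NULL
                               else as.numeric(opts$standoff),
                    clearance = if (is.null(opts$clearance)) NULL
                                else as.numeric(opts$clearance),
                    wrap_distance = if (is.null(opts$wrap)) NULL
                                    else as.numeric(opts$wrap))),
      stop("unknown command: ", cmd, "\n", usage))
    run_pipeline(cfg, dry_run = isTRUE(opts$`dry-run`))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
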