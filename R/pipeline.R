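#' Analyze one cell end-to-end
#'
#' Runs the full analysis chain on a calibrated intensity stack and a cell
#' body definition: whole-cell segmentation, body subtraction, largest-bleb
#' isolation, the per-frame morphometrics table, the per-cell summary, the
#' centroid trajectory with instantaneous speeds, overlap-based bleb tracks
#' with lifetimes, and the phenotype label. Precomputed masks can be passed
#' to resume partway (e.g. a hand-corrected whole-cell mask).
#'
#' @param stack An [image_stack()] (ignored when `whole` is supplied).
#' @param body A [roi_set()] or cell-body [mask_stack()].
#' @param cell_id Identifier used in all outputs.
#' @param whole Optional precomputed whole-cell [mask_stack()]; skips
#'   segmentation.
#' @param all_blebs Optional precomputed all-blebs [mask_stack()]; skips
#'   body subtraction too.
#' @param exclusions Optional [roi_set()] erased before thresholding.
#' @param method,mode,polarity,fill,size_policy,min_area_um2,open_radius_px
#'   Segmentation options, see [segment_whole_cell()].
#' @param min_bleb_area_um2 Minimum area counted as a bleb.
#' @param link_min_overlap Bleb tracking overlap fraction, see
#'   [track_blebs()].
#' @param persistence_frames,leader_area_frac,speed_min,dir_min
#'   Classification parameters, see [classify_phenotype()].
#' @return An object of class `bleb_cell`: a list with `masks` (the four
#'   compartments), `threshold_report`, `frames` (the per-frame table),
#'   `blebs` (per-object records), `summary`, `trajectory`, `speeds`,
#'   `tracks`, `lifetimes`, `phenotype`, and `parameters`.
#' @export
analyze_cell <- function(stack = NULL, body, cell_id = "cell",
                         whole = NULL, all_blebs = NULL,
                         exclusions = NULL,
                         method = "otsu", mode = "per_frame",
                         polarity = "bright_cell", fill = TRUE,
                         size_policy = "keep_largest", min_area_um2 = 0,
                         open_radius_px = 0,
                         min_bleb_area_um2 = 0,
                         link_min_overlap = 0.5,
                         persistence_frames = 5, leader_area_frac = 0.10,
                         speed_min = 0.25, dir_min = 0.5) {
  if (is.null(whole)) {
    if (is.null(stack)) abort("either `stack` or a precomputed `whole` mask is required")
    whole <- segment_whole_cell(
      stack, method = method, mode = mode, polarity = polarity, fill = fill,
      size_policy = size_policy, min_area_um2 = min_area_um2,
      open_radius_px = open_radius_px, exclusions = exclusions
    )
  }
  if (is.null(all_blebs)) {
    all_blebs <- remove_body(whole, body)
  }
  cell_body <- derive_cell_body(whole, all_blebs)
  largest <- largest_bleb(all_blebs, min_bleb_area_um2 = min_bleb_area_um2)

  frames <- compartment_table(whole, cell_body, all_blebs, largest,
                              min_bleb_area_um2 = min_bleb_area_um2)
  blebs <- measure_stack(all_blebs, min_area_um2 = min_bleb_area_um2)
  summary <- summarize_cell(frames, cell_id = cell_id)
  traj <- cell_trajectory(whole, cell_id = cell_id)
  speeds <- instantaneous_speeds(traj)
  tracks <- track_blebs(all_blebs, link_min_overlap = link_min_overlap,
                        min_bleb_area_um2 = min_bleb_area_um2)
  lifetimes <- bleb_lifetimes(tracks)
  whole_areas <- filter(frames, .data$compartment == "whole_cell")
  phenotype <- classify_phenotype(
    traj, tracks, whole_areas,
    persistence_frames = persistence_frames,
    leader_area_frac = leader_area_frac,
    speed_min = speed_min, dir_min = dir_min, cell_id = cell_id
  )
  structure(
    list(
      cell_id = cell_id,
      masks = list(whole_cell = whole, cell_body = cell_body,
                   all_blebs = all_blebs, largest_bleb = largest),
      threshold_report = threshold_report(whole),
      frames = frames,
      blebs = blebs,
      summary = summary,
      trajectory = traj,
      speeds = speeds,
      tracks = tracks,
      lifetimes = lifetimes,
      phenotype = phenotype,
      parameters = tibble(
        method = method, mode = mode, polarity = polarity,
        min_bleb_area_um2 = min_bleb_area_um2,
        link_min_overlap = link_min_overlap,
        persistence_frames = persistence_frames,
        leader_area_frac = leader_area_frac,
        speed_min = speed_min, dir_min = dir_min
      )
    ),
    class = "bleb_cell"
  )
}

#' @export
print.bleb_cell <- function(x, ...) {
  cat(sprintf("<bleb_cell '%s'> %d frame(s)\n", x$cell_id,
              n_frames(x$masks$whole_cell)))
  cat(sprintf("  phenotype: %s (leader bleb: %s, mobile: %s)\n",
              x$phenotype$label, x$phenotype$has_leader_bleb,
              x$phenotype$is_mobile))
  cat(sprintf("  mean bleb count %.2f, mean largest bleb %.1f um2, top speed %.3f um/min\n",
              x$summary$avg_bleb_count,
              x$summary$avg_largest_bleb_area_um2,
              x$phenotype$top_speed_um_min))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-frame records of an analyzed cell
#'
#' @param x A `bleb_cell` from [analyze_cell()].
#' @param ... Unused.
#' @return The per-frame, per-compartment tibble (see
#'   [compartment_table()]), with a `cell_id` column.
#' @export
tidy.bleb_cell <- function(x, ...) {
  mutate(x$frames, cell_id = x$cell_id, .before = 1)
}

#' One-row summary of an analyzed cell
#'
#' @param x A `bleb_cell` from [analyze_cell()].
#' @param ... Unused.
#' @return The per-cell means joined with the phenotype label and top speed.
#' @export
glance.bleb_cell <- function(x, ...) {
  bind_cols(
    x$summary,
    select(x$phenotype, "label", "has_leader_bleb", "is_mobile",
           "top_speed_um_min")
  )
}

#' Pipeline run configuration
#'
#' Collects every option of a full run into one serializable list: input
#' movie, calibration, segmentation choices, per-cell body/exclusion ROI
#' files, dynamics parameters, and an optional resume stage. Configs
#' round-trip through YAML ([read_run_config()] / [write_run_config()]).
#'
#' @param input Path to the movie TIFF (or, on resume, to intermediates).
#' @param output_dir Directory for all output files.
#' @param run_name Prefix for output file names.
#' @param cells List of per-cell entries, each a list with `id`, `body`
#'   (path to a ROI JSON or mask TIFF), and optional `exclusions` (ROI JSON).
#' @param pixel_size_um,frame_interval_min Calibration (NA = read defaults).
#' @param channel,n_channels,n_z,z_policy,z_slice Stack reduction, see
#'   [load_stack()].
#' @param method,mode,polarity,fill,size_policy,min_area_um2,open_radius_px
#'   Segmentation options.
#' @param min_bleb_area_um2,link_min_overlap,persistence_frames,leader_area_frac,speed_min,dir_min
#'   Dynamics options.
#' @param resume `"none"`, `"from_whole_cell"` or `"from_all_blebs"`; the
#'   resume stages expect `<run>_<cell>_Whole_cell.tif` (and
#'   `..._All_blebs.tif`) in `output_dir`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input, output_dir, run_name = "run",
                       cells = list(list(id = "cell1", body = NULL)),
                       pixel_size_um = NA_real_, frame_interval_min = NA_real_,
                       channel = NULL, n_channels = 1L, n_z = 1L,
                       z_policy = "max_projection", z_slice = 1L,
                       method = "otsu", mode = "per_frame",
                       polarity = "bright_cell", fill = TRUE,
                       size_policy = "keep_largest", min_area_um2 = 0,
                       open_radius_px = 0,
                       min_bleb_area_um2 = 0, link_min_overlap = 0.5,
                       persistence_frames = 5, leader_area_frac = 0.10,
                       speed_min = 0.25, dir_min = 0.5,
                       resume = c("none", "from_whole_cell", "from_all_blebs")) {
  resume <- match.arg(resume)
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' For each configured cell: segments (or reloads, on resume) the masks,
#' writes the four compartment TIFFs under the interactive workflow's naming
#' scheme (`<run>_<cell>_Whole_cell.tif` etc.), the per-frame and per-bleb
#' CSVs, trajectory/track/phenotype CSVs, and appends to a shared
#' one-row-per-cell summary CSV. A run log records parameters, thresholds
#' and warnings. A failing cell is logged and skipped; other cells continue.
#' All numbers are serialized with 6 significant digits so identical inputs
#' give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of `bleb_cell` results (errors replaced by the
#'   condition object), with the output file manifest in attribute
#'   `"files"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, paste0(config$run_name, "_log.txt"))
  log_line <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  log_line("run '%s' starting: input=%s resume=%s", config$run_name,
           config$input, config$resume)

  stack <- NULL
  if (config$resume == "none") {
    stack <- load_stack(
      config$input, channel = config$channel,
      n_channels = config$n_channels, n_z = config$n_z,
      z_policy = config$z_policy, z_slice = config$z_slice,
      pixel_size_um = config$pixel_size_um,
      frame_interval_min = config$frame_interval_min
    )
    log_line("loaded %d frame(s) at %g um/px, %g min/frame",
             n_frames(stack), stack$pixel_size_um, stack$frame_interval_min)
  }
  px <- if (is.null(stack)) config$pixel_size_um else stack$pixel_size_um
  dt <- if (is.null(stack)) config$frame_interval_min else stack$frame_interval_min
  if (!is.finite(px) || !is.finite(dt)) {
    px <- if (is.finite(px)) px else 1
    dt <- if (is.finite(dt)) dt else 8
  }

  files <- character(0)
  results <- list()
  summaries <- list()
  for (cell in config$cells) {
    cid <- cell$id %||% "cell"
    prefix <- file.path(config$output_dir,
                        paste0(config$run_name, "_", cid))
    res <- tryCatch({
      body <- load_body(cell$body, px, dt)
      excl <- if (!is.null(cell$exclusions)) load_rois(cell$exclusions)
      whole <- NULL; blebs <- NULL
      if (config$resume %in% c("from_whole_cell", "from_all_blebs")) {
        whole <- read_mask_stack(paste0(prefix, "_Whole_cell.tif"),
                                 "whole_cell", px, dt)
        log_line("cell %s: resumed whole-cell mask (%d frames)", cid,
                 n_frames(whole))
      }
      if (config$resume == "from_all_blebs") {
        blebs <- read_mask_stack(paste0(prefix, "_All_blebs.tif"),
                                 "all_blebs", px, dt)
      }
      withCallingHandlers(
        analyze_cell(
          stack = stack, body = body, cell_id = cid,
          whole = whole, all_blebs = blebs, exclusions = excl,
          method = config$method, mode = config$mode,
          polarity = config$polarity, fill = config$fill,
          size_policy = config$size_policy,
          min_area_um2 = config$min_area_um2,
          open_radius_px = config$open_radius_px,
          min_bleb_area_um2 = config$min_bleb_area_um2,
          link_min_overlap = config$link_min_overlap,
          persistence_frames = config$persistence_frames,
          leader_area_frac = config$leader_area_frac,
          speed_min = config$speed_min, dir_min = config$dir_min
        ),
        warning = function(w) {
          log_line("cell %s: warning: %s", cid, conditionMessage(w))
          invokeRestart("muffleWarning")
        },
        message = function(m) {
          log_line("cell %s: note: %s", cid, trimws(conditionMessage(m)))
          invokeRestart("muffleMessage")
        }
      )
    }, error = function(e) {
      log_line("cell %s: ERROR: %s (cell skipped)", cid, conditionMessage(e))
      e
    })
    results[[cid]] <- res
    if (inherits(res, "error")) next

    for (comp in names(res$masks)) {
      fn <- paste0(prefix, "_", compartment_filename(comp), ".tif")
      write_mask_stack(res$masks[[comp]], fn)
      files <- c(files, fn)
    }
    files <- c(files,
      write_csv6(res$frames, paste0(prefix, "_frames.csv")),
      write_csv6(res$blebs, paste0(prefix, "_blebs.csv")),
      write_csv6(traj_with_speeds(res), paste0(prefix, "_trajectory.csv")),
      write_csv6(res$tracks, paste0(prefix, "_tracks.csv")),
      write_csv6(res$lifetimes, paste0(prefix, "_lifetimes.csv")),
      write_csv6(res$phenotype, paste0(prefix, "_phenotype.csv"))
    )
    if (!is.null(res$threshold_report)) {
      files <- c(files, write_csv6(res$threshold_report,
                                   paste0(prefix, "_threshold.csv")))
    }
    summaries[[cid]] <- glance.bleb_cell(res)
    log_line("cell %s: done, phenotype %s", cid, res$phenotype$label)
  }
  if (length(summaries) > 0) {
    sfn <- file.path(config$output_dir,
                     paste0(config$run_name, "_summary.csv"))
    files <- c(files, write_csv6(bind_rows(summaries), sfn))
  }
  log_line("run '%s' finished: %d cell(s), %d file(s)", config$run_name,
           length(config$cells), length(files))
  attr(results, "files") <- files
  invisible(results)
}

compartment_filename <- function(comp) {
  c(whole_cell = "Whole_cell", cell_body = "Cell_body",
    all_blebs = "All_blebs", largest_bleb = "Largest_blebs")[[comp]]
}

load_body <- function(body, px, dt) {
  if (is.null(body)) abort("a cell body definition is required")
  if (inherits(body, "roi_set") || inherits(body, "mask_stack")) return(body)
  if (grepl("\\.json$", body, ignore.case = TRUE)) return(load_rois(body))
  read_mask_stack(body, "cell_body", px, dt)
}

traj_with_speeds <- function(res) {
  sp <- select(res$speeds, "frame", "speed_um_min")
  left_join(res$trajectory, sp, by = "frame")
}

# CSV writer with 6-significant-digit numeric serialization so repeated runs
# are byte-identical
write_csv6 <- function(tb, path) {
  tb <- as.data.frame(tb)
  for (j in seq_along(tb)) {
    if (is.double(tb[[j]])) tb[[j]] <- signif(tb[[j]], 6)
  }
  utils::write.csv(tb, path, row.names = FALSE)
  path
}

#' Write the standard output set for a synthetic scene
#'
#' Saves the movie TIFF, truth mask TIFFs, truth CSVs (tracks, lifetimes,
#' phenotype), the truth body ROIs as JSON, and the scene parameters as JSON.
#'
#' @param scene A `bleb_scene` from [render_scene()].
#' @param dir Output directory.
#' @param prefix File-name prefix (defaults to the scene name).
#' @return The file manifest, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = NULL) {
  stopifnot(inherits(scene, "bleb_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- prefix %||% scene$params$name
  p <- function(...) file.path(dir, paste0(prefix, "_", ...))
  files <- c(
    write_image_stack(scene$stack, p("movie.tif")),
    write_mask_stack(scene$truth$whole, p("truth_Whole_cell.tif")),
    write_mask_stack(scene$truth$body, p("truth_Cell_body.tif")),
    write_mask_stack(scene$truth$blebs, p("truth_All_blebs.tif")),
    write_mask_stack(scene$truth$largest, p("truth_Largest_blebs.tif")),
    write_csv6(scene$truth$tracks, p("truth_tracks.csv")),
    write_csv6(scene$truth$lifetimes, p("truth_lifetimes.csv")),
    write_csv6(scene$truth$phenotype, p("truth_phenotype.csv")),
    write_rois(scene$truth$body_rois, p("body_rois.json"))
  )
  pj <- p("params.json")
  par <- scene$params
  par$blebs <- as.data.frame(par$blebs)
  jsonlite::write_json(unclass(par), pj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, pj))
}
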