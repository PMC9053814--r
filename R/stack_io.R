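#' Calibrated time-lapse image stack
#'
#' An `image_stack` holds a time-ordered list of single-channel 2-D intensity
#' frames together with the physical calibration needed to report areas in
#' square microns and speeds in microns per minute. Uncalibrated stacks carry
#' the defaults of 1 micron/pixel and 8 min/frame (the frame interval at which
#' five frames span 40 minutes, the persistence window used throughout the
#' phenotype classification) and are flagged so a warning is raised once.
#'
#' @param frames List of numeric matrices, all of identical dimensions.
#' @param pixel_size_um Pixel size in microns per pixel (> 0), or `NA` for an
#'   uncalibrated stack.
#' @param frame_interval_min Frame interval in minutes (> 0), or `NA`.
#' @param name Text identifier used in output file names.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size_um = NA_real_,
                        frame_interval_min = NA_real_, name = "stack") {
  if (!is.list(frames) || length(frames) == 0L) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) abort("every frame must be a 2-D matrix")
    storage.mode(f) <- "double"
    f
  })
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) abort("all frames must share identical height x width")

  calibrated <- is.finite(pixel_size_um) && is.finite(frame_interval_min)
  if (calibrated && (pixel_size_um <= 0 || frame_interval_min <= 0)) {
    abort("pixel_size_um and frame_interval_min must be strictly positive")
  }
  if (!calibrated) {
    warn(paste0(
      "stack '", name, "' is uncalibrated; assuming 1 um/pixel and ",
      "8 min/frame (override with calibrate())"
    ))
    pixel_size_um <- 1
    frame_interval_min <- 8
  }
  structure(
    list(
      frames = frames,
      pixel_size_um = as.numeric(pixel_size_um),
      frame_interval_min = as.numeric(frame_interval_min),
      name = name,
      calibrated = calibrated
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<image_stack '%s'> %d frame(s), %d x %d px, %.4g um/px, %.4g min/frame%s\n",
    x$name, length(x$frames), d[1], d[2], x$pixel_size_um,
    x$frame_interval_min, if (x$calibrated) "" else " (uncalibrated)"
  ))
  invisible(x)
}

#' Per-frame binary masks for one subcellular compartment
#'
#' A `mask_stack` is the binary counterpart of an [image_stack()]: one logical
#' frame per time point, labelled with the compartment it isolates. The five
#' compartment classes mirror the file series the interactive workflow writes
#' (`Whole_cell`, `Cell_body`, `All_blebs`, `Largest_blebs`, plus the edited
#' `Tracer` input).
#'
#' @param frames List of logical matrices of identical dimensions.
#' @param compartment One of `"whole_cell"`, `"cell_body"`, `"all_blebs"`,
#'   `"largest_bleb"`, `"tracer"`.
#' @param pixel_size_um,frame_interval_min Calibration, as in [image_stack()].
#'
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(frames, compartment, pixel_size_um = 1,
                       frame_interval_min = 8) {
  compartment <- match.arg(
    compartment,
    c("whole_cell", "cell_body", "all_blebs", "largest_bleb", "tracer")
  )
  if (!is.list(frames) || length(frames) == 0L) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  frames <- lapply(frames, function(f) {
    if (!is.matrix(f)) abort("every frame must be a 2-D matrix")
    mode(f) <- "logical"
    f
  })
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(ok)) abort("all frames must share identical height x width")
  if (pixel_size_um <= 0 || frame_interval_min <= 0) {
    abort("pixel_size_um and frame_interval_min must be strictly positive")
  }
  structure(
    list(
      frames = frames,
      compartment = compartment,
      pixel_size_um = as.numeric(pixel_size_um),
      frame_interval_min = as.numeric(frame_interval_min)
    ),
    class = "mask_stack"
  )
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<mask_stack '%s'> %d frame(s), %d x %d px, %.4g um/px\n",
    x$compartment, length(x$frames), d[1], d[2], x$pixel_size_um
  ))
  invisible(x)
}

n_frames <- function(x) length(x$frames)

frame_dim <- function(x) dim(x$frames[[1]])

#' Read a TIFF time lapse and reduce it to a single-channel, single-Z stack
#'
#' Multi-page TIFFs are interpreted in hyperstack page order (channel fastest,
#' then Z slice, then time), the convention used by ImageJ when saving
#' multi-dimensional stacks. For anything beyond a plain T-series the page
#' layout is ambiguous from the file alone, so `n_channels` and `n_z` must be
#' given explicitly; a page count that is not a multiple of
#' `n_channels * n_z` is an error rather than a guess.
#'
#' @param path Path to a TIFF file.
#' @param channel 1-based channel to keep (required when `n_channels > 1`).
#' @param n_channels,n_z Number of channels and Z slices interleaved in the
#'   page sequence.
#' @param z_policy How to reduce the Z dimension: `"max_projection"` (MIP),
#'   `"mean_projection"`, or `"slice"` together with `z_slice`.
#' @param z_slice 1-based Z slice kept when `z_policy = "slice"`.
#' @param pixel_size_um,frame_interval_min Optional calibration; when omitted
#'   the stack is flagged uncalibrated (see [image_stack()]).
#' @param name Stack identifier; defaults to the file name without extension.
#'
#' @return An [image_stack()].
#' @export
load_stack <- function(path, channel = NULL, n_channels = 1L, n_z = 1L,
                       z_policy = c("max_projection", "mean_projection", "slice"),
                       z_slice = 1L,
                       pixel_size_um = NA_real_, frame_interval_min = NA_real_,
                       name = NULL) {
  z_policy <- match.arg(z_policy)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) abort("TIFF contains zero frames")
  pages <- lapply(pages, collapse_page_channels, channel = channel,
                  n_channels = n_channels)

  per_t <- n_channels * n_z
  if (length(pages) %% per_t != 0L) {
    abort(sprintf(
      "page count %d is not a multiple of n_channels * n_z = %d; specify the stack layout explicitly",
      length(pages), per_t
    ))
  }
  n_t <- length(pages) %/% per_t

  if (n_channels > 1L) {
    if (is.null(channel)) abort("`channel` is required for a multi-channel stack")
    if (channel < 1L || channel > n_channels) abort("channel out of range")
  } else {
    channel <- 1L
  }
  if (z_policy == "slice" && (z_slice < 1L || z_slice > n_z)) {
    abort("z_slice out of range")
  }

  frames <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    # page index (1-based): ((t-1) * n_z + (z-1)) * n_channels + channel
    zs <- lapply(seq_len(n_z), function(z) {
      pages[[((t - 1L) * n_z + (z - 1L)) * n_channels + channel]]
    })
    frames[[t]] <- switch(z_policy,
      max_projection = Reduce(pmax, zs),
      mean_projection = Reduce(`+`, zs) / length(zs),
      slice = zs[[z_slice]]
    )
  }
  image_stack(
    frames,
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min,
    name = name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

# RGB/multi-sample pages carry within-page channels in the 3rd dimension
collapse_page_channels <- function(page, channel, n_channels) {
  if (length(dim(page)) == 3L) {
    nc <- dim(page)[3]
    if (n_channels > 1L) {
      abort("stack has within-page channels; do not also set n_channels > 1")
    }
    ch <- channel %||% 1L
    if (ch < 1L || ch > nc) abort("channel out of range")
    page <- page[, , ch]
  }
  storage.mode(page) <- "double"
  page
}

#' Attach physical calibration to a stack
#'
#' @param stack An [image_stack()] or [mask_stack()].
#' @param pixel_size_um Microns per pixel (> 0).
#' @param frame_interval_min Minutes per frame (> 0).
#'
#' @return The stack with calibration applied; downstream areas are reported
#'   in square microns and speeds in microns per minute.
#' @export
calibrate <- function(stack, pixel_size_um, frame_interval_min) {
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0 ||
      !is.numeric(frame_interval_min) || frame_interval_min <= 0) {
    abort("pixel_size_um and frame_interval_min must be strictly positive")
  }
  stack$pixel_size_um <- as.numeric(pixel_size_um)
  stack$frame_interval_min <- as.numeric(frame_interval_min)
  if (inherits(stack, "image_stack")) stack$calibrated <- TRUE
  stack
}

#' Write a mask stack as an 8-bit binary TIFF
#'
#' Foreground pixels are written as 255, background as 0, one page per frame,
#' so the file round-trips losslessly through [load_stack()] followed by
#' a `> 0` comparison (see [read_mask_stack()]).
#'
#' @param mask A [mask_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask_stack <- function(mask, path) {
  stopifnot(inherits(mask, "mask_stack"))
  pages <- lapply(mask$frames, function(f) {
    m <- matrix(0, nrow(f), ncol(f))
    m[f] <- 1 # writeTIFF scales [0,1] -> 0..255 at 8 bit
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary TIFF back into a mask stack
#'
#' @param path TIFF written by [write_mask_stack()] (or any TIFF in which
#'   foreground is strictly positive).
#' @param compartment Compartment label for the result.
#' @param pixel_size_um,frame_interval_min Calibration.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, compartment, pixel_size_um = 1,
                            frame_interval_min = 8) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mask_stack(lapply(pages, function(p) p > 0), compartment,
             pixel_size_um = pixel_size_um,
             frame_interval_min = frame_interval_min)
}

#' Write an intensity stack as an 8- or 16-bit TIFF
#'
#' @param stack An [image_stack()] with values in `[0, 2^bits - 1]`.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 8L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  pages <- lapply(stack$frames, function(f) pmin(pmax(f, 0), top) / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Per-frame polygon ROIs for one cell
#'
#' The headless replacement for interactively circling the cell body on each
#' frame: a set of closed polygons keyed by 0-based frame index. Frames
#' without a polygon inherit the nearest earlier one, so a single polygon on
#' frame 0 covers a whole movie of a stationary cell.
#'
#' @param polygons Named list mapping frame index (0-based, as character or
#'   integer names) to an n x 2 matrix of `(row, col)` vertices (0-based
#'   pixel coordinates, >= 3 vertices).
#' @param cell_id Text identifier.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons, cell_id = "cell") {
  if (length(polygons) == 0L) abort("no polygons found")
  idx <- as.integer(names(polygons))
  if (anyNA(idx)) abort("polygon list must be named by 0-based frame index")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2L || nrow(p) < 3L) {
      abort("every polygon needs >= 3 (row, col) vertices")
    }
    storage.mode(p) <- "double"
    colnames(p) <- c("row", "col")
    p
  })
  polygons <- polygons[order(idx)]
  structure(list(polygons = polygons, cell_id = cell_id), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set '%s'> polygons on frame(s) %s\n", x$cell_id,
              paste(names(x$polygons), collapse = ", ")))
  invisible(x)
}

#' Load polygon ROIs from the package JSON format
#'
#' The JSON layout is
#' `{"cell_id": "...", "frames": [{"frame": 0, "vertices": [[r, c], ...]}]}`
#' with 0-based frames and 0-based `(row, col)` pixel coordinates. ImageJ
#' binary `.roi`/`.zip` files are not parsed; export such ROIs to this JSON
#' layout (the coordinates are the same pixel grid).
#'
#' @param path Path to a JSON ROI file.
#' @return A [roi_set()].
#' @export
load_rois <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  doc <- tryCatch(jsonlite::read_json(path), error = function(e) {
    abort(paste0("not a valid JSON ROI file: ", conditionMessage(e)))
  })
  frames <- doc$frames
  if (is.null(frames) || length(frames) == 0L) abort("no polygons found")
  polys <- list()
  for (fr in frames) {
    verts <- do.call(rbind, lapply(fr$vertices, function(v) unlist(v)))
    polys[[as.character(fr$frame)]] <- verts
  }
  roi_set(polys, cell_id = doc$cell_id %||% "cell")
}

#' Write a roi_set to the package JSON format
#'
#' @param rois A [roi_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  doc <- list(
    cell_id = rois$cell_id,
    frames = imap(rois$polygons, function(p, nm) {
      list(frame = as.integer(nm),
           vertices = lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ])))
    })
  )
  names(doc$frames) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Polygon for frame t (0-based) under the nearest-earlier inheritance rule.
roi_polygon_for_frame <- function(rois, t) {
  idx <- as.integer(names(rois$polygons))
  cand <- idx[idx <= t]
  if (length(cand) == 0L) {
    abort(sprintf("no ROI defined on or before frame %d for cell '%s'",
                  t, rois$cell_id))
  }
  rois$polygons[[as.character(max(cand))]]
}

# Even-odd polygon rasterization on the pixel grid, boundary-inclusive.
# Pixel (r, c) (0-based) is tested at the point (r, c); points exactly on a
# polygon edge count as inside.
rasterize_polygon <- function(poly, dim) {
  h <- dim[1]; w <- dim[2]
  ry <- poly[, 1]; rx <- poly[, 2]
  if (any(ry < -0.5 | ry > h - 0.5 | rx < -0.5 | rx > w - 0.5)) {
    abort("polygon extends outside image bounds")
  }
  r0 <- max(0L, floor(min(ry))); r1 <- min(h - 1L, ceiling(max(ry)))
  c0 <- max(0L, floor(min(rx))); c1 <- min(w - 1L, ceiling(max(rx)))
  out <- matrix(FALSE, h, w)
  if (r1 < r0 || c1 < c0) return(out)

  rr <- rep(r0:r1, times = c1 - c0 + 1L)
  cc <- rep(c0:c1, each = r1 - r0 + 1L)
  py <- as.numeric(rr); px <- as.numeric(cc)
  inside <- rep(FALSE, length(px))
  boundary <- rep(FALSE, length(px))
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    yi <- ry[i]; xi <- rx[i]; yj <- ry[j]; xj <- rx[j]
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    # distance from point to segment i-j (for boundary inclusion)
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      tt <- pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / len2))
      d2 <- (px - (xi + tt * dx))^2 + (py - (yi + tt * dy))^2
    } else {
      d2 <- (px - xi)^2 + (py - yi)^2
    }
    boundary <- boundary | d2 < 1e-18
    j <- i
  }
  out[cbind(rr + 1L, cc + 1L)] <- inside | boundary
  out
}

#' Rasterize a ROI set into a per-frame binary mask stack
#'
#' Frames without their own polygon inherit the nearest earlier polygon.
#'
#' @param rois A [roi_set()].
#' @param dim Frame dimensions `c(height, width)` in pixels.
#' @param n_frames Number of frames to cover.
#' @param compartment Compartment label for the result (default `cell_body`).
#' @param pixel_size_um,frame_interval_min Calibration.
#' @return A [mask_stack()].
#' @export
rois_to_mask <- function(rois, dim, n_frames, compartment = "cell_body",
                         pixel_size_um = 1, frame_interval_min = 8) {
  idx <- as.integer(names(rois$polygons))
  if (any(idx < 0L | idx >= n_frames)) abort("ROI frame index outside stack range")
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    rasterize_polygon(roi_polygon_for_frame(rois, t), dim)
  })
  mask_stack(frames, compartment,
             pixel_size_um = pixel_size_um,
             frame_interval_min = frame_interval_min)
}

#' Erase background objects inside exclusion ROIs before thresholding
#'
#' The headless analogue of hand-editing the raw movie to erase debris and
#' neighbouring cells: the interior of each exclusion polygon is replaced by
#' the frame's modal intensity (the background level for a fluorescence
#' frame), so the objects inside it cannot influence the threshold.
#'
#' @param stack An [image_stack()].
#' @param exclusions A [roi_set()] of regions to erase, or `NULL` (no-op).
#' @return The edited [image_stack()] (the "tracer" image).
#' @export
apply_exclusions <- function(stack, exclusions = NULL) {
  if (is.null(exclusions)) return(stack)
  d <- frame_dim(stack)
  for (t in seq_along(stack$frames) - 1L) {
    poly <- tryCatch(roi_polygon_for_frame(exclusions, t), error = function(e) NULL)
    if (is.null(poly)) next
    m <- rasterize_polygon(poly, d)
    f <- stack$frames[[t + 1L]]
    f[m] <- modal_value(f)
    stack$frames[[t + 1L]] <- f
  }
  stack
}

modal_value <- function(x) {
  tb <- table(as.vector(x))
  as.numeric(names(tb)[which.max(tb)])
}
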